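test_that("sequence extraction respects bounds and strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTANNGG"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4))
  expect_equal(as.character(extract_sequences(gr, genome)), "ACGT")
  grm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4),
                                strand = "-")
  expect_equal(as.character(extract_sequences(grm, genome)), "ACGT")
  grn <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 7))
  expect_equal(as.character(extract_sequences(grn, genome)), "ANN")
  out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8, 20))
  expect_error(extract_sequences(out, genome), "bounds")
  unk <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 2))
  expect_error(extract_sequences(unk, genome), "unknown")
})

test_that("k-mer presence counts sequences, pools strands, skips Ns", {
  kp <- count_kmer_presence("GGGGGG", k = 6)
  expect_equal(unname(kp$counts["CCCCCC"]), 1L)  # canonical key
  expect_equal(kp$n_sequences, 1L)

  # overlapping windows within one sequence count once per k-mer
  kp2 <- count_kmer_presence("ACGTACGT", k = 6)
  expect_true(all(kp2$counts == 1L))
  expect_setequal(names(kp2$counts), canonical_kmer(c("ACGTAC", "CGTACG")))

  short <- count_kmer_presence(c("ACGTACGT", "ACG"), k = 6)
  expect_equal(short$n_sequences, 2L)
  expect_true(all(short$counts <= 1L))

  withn <- count_kmer_presence("ACGTNNACGT", k = 6)
  expect_length(withn$counts, 0)

  noncan <- count_kmer_presence("GGGGGG", k = 6, canonical = FALSE)
  expect_equal(names(noncan$counts), "GGGGGG")
})

test_that("Fisher p-values match the hypergeometric enumeration oracle", {
  mk <- function(counts, n) {
    structure(list(k = 6L, canonical = TRUE, n_sequences = n,
                   counts = counts), class = "kmer_presence")
  }
  # documented example: (8,2;2,8)
  fg <- mk(c(AAAAAA = 8L), 10L)
  bg <- mk(c(AAAAAA = 2L), 10L)
  res <- fisher_enrichment(fg, bg)
  expect_equal(res$p_value, oracle_fisher_greater(8, 2, 2, 8),
               tolerance = 1e-12)
  expect_equal(res$p_value,
               stats::fisher.test(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)

  # exhaustive scan over tables with n <= 40
  set.seed(11)
  for (i in 1:200) {
    n1 <- sample.int(20, 1); n2 <- sample.int(20, 1)
    a <- sample.int(n1 + 1, 1) - 1; c_ <- sample.int(n2 + 1, 1) - 1
    got <- fisher_enrichment(mk(c(AAAAAA = a), n1),
                             mk(c(AAAAAA = c_), n2))$p_value
    expect_equal(got, oracle_fisher_greater(a, n1 - a, c_, n2 - c_),
                 tolerance = 1e-12)
  }

  # identical sets: unit odds ratio, nothing significant
  same <- fisher_enrichment(fg, fg)
  expect_true(all(!same$significant))
  expect_true(all(same$odds_ratio == 1))

  # monotonicity: more foreground hits never increases the one-sided p
  ps <- vapply(0:10, function(a) {
    fisher_enrichment(mk(c(AAAAAA = a), 10L), bg)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  expect_error(
    fisher_enrichment(fg, structure(list(k = 5L, canonical = TRUE,
                                         n_sequences = 2L, counts = c()),
                                    class = "kmer_presence")),
    "share k")
})

test_that("enrichment is invariant to reverse-complementing every input", {
  set.seed(3)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  fg_seqs <- vapply(rep(60, 25), rand_seq, character(1))
  bg_seqs <- vapply(rep(60, 50), rand_seq, character(1))
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s)))
  r1 <- fisher_enrichment(count_kmer_presence(fg_seqs),
                          count_kmer_presence(bg_seqs))
  r2 <- fisher_enrichment(count_kmer_presence(rc(fg_seqs)),
                          count_kmer_presence(rc(bg_seqs)))
  expect_equal(r1$kmer, r2$kmer)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the planted GC-rich 6-mer ranks first against both backgrounds", {
  sim <- get_sim("noisefree")
  cfg <- sim$cfg
  catalog <- build_consensus(sim$peak_sim$chip$peaks)
  truth <- sim$peak_sim$truth$loci
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$center, truth$center))
  shared <- catalog[IRanges::overlapsAny(
    catalog, tg[truth$class == "shared"])]
  genome <- sim$peak_sim$genome
  fg <- count_kmer_presence(extract_sequences(shared, genome))
  bg_all <- count_kmer_presence(extract_sequences(catalog, genome))
  proms <- promoter_of(sim$genome_sim$genes)
  bg_up <- count_kmer_presence(extract_sequences(proms, genome))
  planted <- canonical_kmer(cfg$motif$planted)
  r_all <- fisher_enrichment(fg, bg_all)
  expect_equal(r_all$kmer[1], planted)
  rep_dual <- dual_background_report(fg, bg_all, bg_up)
  expect_true(all(rep_dual$robust[rep_dual$kmer == planted]))
})

test_that("MEME minimal export writes one motif per significant k-mer", {
  res <- data.frame(kmer = c("GCCGCC", "AAAAAA"), fg_with = c(9, 1),
                    fg_without = c(1, 9), bg_with = c(1, 5),
                    bg_without = c(9, 5), odds_ratio = c(81, 0.1),
                    p_value = c(0.001, 0.9), p_adj = c(0.002, 0.9),
                    significant = c(TRUE, FALSE),
                    background_label = "all_peaks")
  path <- tempfile(fileext = ".meme")
  write_meme_minimal(res, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MOTIF ", lines)), 1)
  expect_true(any(grepl("MOTIF GCCGCC", lines)))
})
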