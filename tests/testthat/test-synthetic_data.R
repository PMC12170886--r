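test_that("configuration merges overrides and validates ranges", {
  cfg <- sim_config(seed = 2, peaks = list(reduction = 0.5))
  expect_equal(cfg$peaks$reduction, 0.5)
  expect_equal(cfg$peaks$peak_width, 400L)  # untouched sibling default
  expect_error(sim_config(peaks = list(reduction = 0)), "reduction")
  expect_error(sim_config(de = list(correlation_target = 1)),
               "correlation_target")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 77, genome = list(chrom_len = 200000L,
                                             n_genes = 20L),
                    peaks = list(n_shared_promoter = 5L,
                                 n_shared_distal = 2L, n_a_specific = 4L,
                                 n_b_specific = 3L, n_stable = 10L))
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- simulate_genome(cfg, d1); g2 <- simulate_genome(cfg, d2)
  expect_equal(unname(tools::md5sum(file.path(d1, "genome.fa"))),
               unname(tools::md5sum(file.path(d2, "genome.fa"))))
  p1 <- simulate_peak_experiment(cfg, g1, d1)
  p2 <- simulate_peak_experiment(cfg, g2, d2)
  for (f in c("ipA_ctrl.bedgraph", "ipB_kdB.bed",
              "truth_peak_classes.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))))
  }
  s1 <- simulate_sensorgrams(cfg, d1); s2 <- simulate_sensorgrams(cfg, d2)
  expect_identical(s1$sensorgrams$data, s2$sensorgrams$data)
})

test_that("simulated genome hits the configured GC fraction", {
  cfg <- sim_config(seed = 55, genome = list(chrom_len = 200000L,
                                             n_genes = 0L,
                                             gc_background = 0.5))
  g <- simulate_genome(cfg)
  expect_length(g$genes, 0)
  freq <- Biostrings::letterFrequency(g$genome, c("G", "C"))
  gc <- sum(freq) / sum(Biostrings::width(g$genome))
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)
})

test_that("generated files pass the package validators", {
  cfg <- sim_config(seed = 42, genome = list(chrom_len = 200000L,
                                             n_genes = 20L),
                    peaks = list(n_shared_promoter = 5L,
                                 n_shared_distal = 2L, n_a_specific = 4L,
                                 n_b_specific = 3L, n_stable = 10L))
  dir <- tempfile()
  g <- simulate_genome(cfg, dir)
  p <- simulate_peak_experiment(cfg, g, dir)
  bed <- read_bed(file.path(dir, "ipA_ctrl.bed"))
  expect_equal(length(bed), nrow(p$truth$loci))
  cov <- read_bedgraph(file.path(dir, "ipA_ctrl.bedgraph"))
  expect_gt(coverage_mass(cov), 0)
  genes <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(length(genes), 20)
  genome <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(names(genome), c("chr1", "chr2"))
})

test_that("planted amplitudes and knockdown reductions are quantifiable", {
  # no per-locus noise and no per-sample scale factor: raw amplitude ratios
  # equal the planted reduction exactly
  cfg <- sim_config(seed = 61, genome = list(chrom_len = 300000L,
                                             n_genes = 30L),
                    peaks = list(n_shared_promoter = 8L,
                                 n_shared_distal = 4L, n_a_specific = 8L,
                                 n_b_specific = 4L, n_stable = 20L,
                                 noise_sdlog = 0, sample_scale_sdlog = 0))
  g <- simulate_genome(cfg)
  p <- simulate_peak_experiment(cfg, g)
  catalog <- build_consensus(p$chip$peaks)
  m <- peak_matrix(catalog, p$chip$coverages, p$chip$read_length)
  truth <- p$truth$loci
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$center, truth$center))
  hit <- GenomicRanges::findOverlaps(tg, catalog)
  ord_truth <- truth[S4Vectors::queryHits(hit), ]
  rows <- match(catalog$peak_id[S4Vectors::subjectHits(hit)],
                rownames(m))
  # shared loci: log2(control/kd) equals log2(1/reduction) in both IPs
  sh <- ord_truth$class == "shared"
  l2 <- log2(m[rows[sh], "ipA_ctrl"] / m[rows[sh], "ipA_kdA"])
  expect_equal(unname(l2), rep(log2(1 / 0.4), sum(sh)), tolerance = 1e-6)
  l2b <- log2(m[rows[sh], "ipB_ctrl"] / m[rows[sh], "ipB_kdB"])
  expect_equal(unname(l2b), rep(log2(1 / 0.4), sum(sh)), tolerance = 1e-6)
  # A-specific loci under B knockdown: unperturbed
  asp <- ord_truth$class == "A_specific"
  l2n <- log2(m[rows[asp], "ipA_ctrl"] / m[rows[asp], "ipA_kdB"])
  expect_equal(unname(l2n), rep(0, sum(asp)), tolerance = 1e-6)
})

test_that("motif planting rate 1 marks every shared locus sequence", {
  cfg <- sim_config(seed = 43, genome = list(chrom_len = 200000L,
                                             n_genes = 20L),
                    peaks = list(n_shared_promoter = 5L,
                                 n_shared_distal = 3L, n_a_specific = 2L,
                                 n_b_specific = 2L, n_stable = 5L),
                    motif = list(planting_rate = 1))
  g <- simulate_genome(cfg)
  p <- simulate_peak_experiment(cfg, g)
  truth <- p$truth$loci
  shared <- truth[truth$class == "shared", ]
  expect_true(all(shared$motif_planted))
  gr <- GenomicRanges::GRanges(shared$chrom,
                               IRanges::IRanges(shared$center - 200,
                                                shared$center + 200))
  seqs <- extract_sequences(gr, p$genome)
  hasm <- vapply(as.character(seqs), function(s) {
    grepl(cfg$motif$planted, s, fixed = TRUE)
  }, logical(1))
  expect_true(all(hasm))
})

test_that("zero-noise blank cycles are identically zero after referencing", {
  cfg <- sim_config(seed = 13, spr = list(noise_sd = 0))
  sim <- simulate_sensorgrams(cfg)
  # reference a second blank-like config: C = kd/ka gives half-max response
  kd_nM <- cfg$spr$kd / cfg$spr$ka * 1e9
  r_inf <- binding_response(1e7, kd_nM, cfg$spr$ka, cfg$spr$kd,
                            cfg$spr$rmax)
  expect_equal(r_inf, cfg$spr$rmax / 2, tolerance = 1e-9)
  expect_equal(sim$truth$kd_nM, 870)
})
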