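mk_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

test_that("consensus building matches the brute-force pairwise oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    df <- random_peaks(n)
    got <- build_consensus(list(s1 = mk_gr(df)))
    want <- oracle_consensus(df)
    expect_equal(length(got), nrow(want))
    expect_equal(GenomicRanges::start(got), want$start)
    expect_equal(GenomicRanges::end(got), want$end)
    expect_equal(as.character(GenomicRanges::seqnames(got)), want$chrom)
  }
})

test_that("consensus handles chains, identical members and sample order", {
  # transitive chain: each neighbour's midpoint falls in the previous span,
  # so the whole chain collapses to one spanning peak
  chain <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 51, 101), c(100, 150, 200)))
  got <- build_consensus(list(s1 = chain))
  expect_length(got, 1)
  expect_equal(GenomicRanges::start(got), 1)
  expect_equal(GenomicRanges::end(got), 200)
  # overlapping but midpoints outside each other's spans: no match
  graze <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 91), c(100, 190)))
  expect_length(build_consensus(list(s1 = graze)), 2)

  same <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1400))
  six <- stats::setNames(rep(list(same), 6), paste0("s", 1:6))
  got6 <- build_consensus(six)
  expect_length(got6, 1)
  expect_equal(got6$n_members, 6)

  far <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 501), c(100, 600)))
  expect_length(build_consensus(list(s1 = far)), 2)

  set.seed(9)
  df1 <- random_peaks(60); df2 <- random_peaks(60)
  a <- build_consensus(list(x = mk_gr(df1), y = mk_gr(df2)))
  b <- build_consensus(list(y = mk_gr(df2), x = mk_gr(df1)))
  expect_equal(length(a), length(b))
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))

  expect_error(build_consensus(list(s1 = mk_gr(df1)), seqlevels = "chrX"),
               "unknown chromosome")
})

test_that("amplitude is summed coverage scaled by read length", {
  cat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
  cat$peak_id <- "p1"
  cov <- read_bedgraph({
    f <- tempfile(); writeLines("chr1\t100\t300\t10", f); f
  }, seqlengths = c(chr1 = 1000))
  expect_equal(quantify(cat, cov, 100), 20)    # 2000 / 100
  expect_equal(quantify(cat, cov, 200), 10)    # doubling read length halves
  zero <- read_bedgraph({
    f <- tempfile(); writeLines("chr1\t500\t600\t4", f); f
  }, seqlengths = c(chr1 = 1000))
  expect_equal(quantify(cat, zero, 100), 0)
  expect_warning(amp <- quantify(
    GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)), cov, 100),
    "missing chromosome")
  expect_equal(amp, 0)
})

test_that("signal/noise flooring drops all-floored rows and records it", {
  m <- matrix(c(5, 5, 15, 40, 25, 30), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  out <- apply_noise_threshold(m, 20)
  expect_equal(rownames(out), c("p2", "p3"))
  expect_equal(out["p2", ], c(a = 20, b = 40))
  expect_equal(out["p3", ], c(a = 25, b = 30))
  expect_equal(attr(out, "dropped_rows"), "p1")
  expect_match(paste(attr(out, "provenance"), collapse = " "), "floor")
  expect_error(apply_noise_threshold(m, 0), "> 0")
  # epsilon threshold: identity on positive matrices
  expect_equal(unclass(apply_noise_threshold(m, 1e-9))[, ], m[, ])
})

test_that("mode scaling recovers a planted global factor", {
  set.seed(1)
  base <- stats::rlnorm(400, log(200), 0.3)
  m <- cbind(ctrl = base, kd = base * 4)
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  out <- scale_to_control_mode(m, c(ctrl = "ctrl", kd = "ctrl"))
  f <- attr(out, "scale_factors")
  expect_equal(unname(f["ctrl"]), 1)
  expect_equal(unname(f["kd"]), 0.25, tolerance = 0.15)
  # after scaling, log2 modes agree within one histogram bin
  mode_of <- function(x) tsppi:::.log2_mode(x)
  expect_lte(abs(mode_of(out[, "kd"]) - mode_of(out[, "ctrl"])), 0.1 + 1e-9)
  ident <- scale_to_control_mode(m[, c("ctrl", "ctrl")],
                                 c(ctrl = "ctrl"))
  expect_equal(unname(attr(ident, "scale_factors")), c(1, 1))
  expect_error(scale_to_control_mode(m, c(ctrl = "ctrl")), "mapped")
})

test_that("disappearing calls use log2(control/kd) with inclusive boundary", {
  m <- matrix(c(40, 20, 30, 30, 20 * 2^0.5, 20), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("ctrl", "kd")))
  calls <- call_disappearing(m, "ctrl", "kd", 0.5)
  expect_equal(calls$log2fc, c(1, 0, 0.5))
  expect_equal(calls$disappearing, c(TRUE, FALSE, TRUE))
})

test_that("co-dependency classes follow the reduced-under-knockdown rule", {
  ids <- c("p1", "p2", "p3", "p4")
  mk <- function(d) data.frame(peak_id = ids, log2fc = ifelse(d, 1, 0),
                               disappearing = d)
  # p1: A only (both IPs); p2: both KDs; p3: B only; p4: neither
  calls <- list(ipA_kdA = mk(c(TRUE, TRUE, FALSE, FALSE)),
                ipA_kdB = mk(c(FALSE, TRUE, FALSE, FALSE)),
                ipB_kdA = mk(c(TRUE, FALSE, FALSE, FALSE)),
                ipB_kdB = mk(c(FALSE, TRUE, TRUE, FALSE)))
  cls <- classify_codependency(calls)
  expect_equal(cls$class, c("A_specific", "shared", "B_specific",
                            "unchanged"))
  none <- lapply(calls, function(x) { x$disappearing <- FALSE; x })
  expect_true(all(classify_codependency(none)$class == "unchanged"))
  bad <- calls
  bad$ipB_kdB$peak_id <- rev(bad$ipB_kdB$peak_id)
  expect_error(classify_codependency(bad), "mismatched")
})

test_that("planted peak classes are recovered exactly without noise", {
  sim <- get_sim("noisefree")
  res <- run_chip_classification(sim$peak_sim)
  tc <- truth_class_per_peak(sim$peak_sim, res$catalog, res$classes)
  expect_equal(nrow(tc), nrow(sim$peak_sim$truth$loci))
  expect_true(all(tc$est == tc$truth))
})

test_that("class recall stays above 0.95 under default noise", {
  sim <- get_sim("default")
  res <- run_chip_classification(sim$peak_sim)
  tc <- truth_class_per_peak(sim$peak_sim, res$catalog, res$classes)
  recall <- vapply(unique(tc$truth),
                   function(k) mean(tc$est[tc$truth == k] == k), numeric(1))
  expect_true(all(recall >= 0.95))
})

test_that("feature annotation applies the inclusive 50% overlap rule", {
  cat <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)))
  cat$peak_id <- c("p1", "p2", "p3")
  tracks <- list(
    exon = GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 250)),
    promoter = GenomicRanges::GRanges("chr1", IRanges::IRanges(351, 400)),
    cpg_island = GenomicRanges::GRanges("chr1", IRanges::IRanges(561, 600)))
  ann <- annotate_peaks(cat, tracks, 0.5)
  expect_equal(ann$label[ann$peak_id == "p1"], "exon")     # fully inside
  expect_equal(ann$label[ann$peak_id == "p2"], "promoter") # exactly 0.5
  expect_false("p3" %in% ann$peak_id)                      # 40% only
})

test_that("gene pairing respects the flank distance presets", {
  cat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
  cat$peak_id <- "p1"
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1701, 7000, 1200), c(2500, 8000, 1300)),
    gene_id = c("near", "far", "inside"))
  p1k <- pair_with_genes(cat, genes, 1000)
  expect_setequal(p1k$gene_id, c("near", "inside"))
  expect_equal(p1k$distance_bp[p1k$gene_id == "near"], 301)
  expect_equal(p1k$distance_bp[p1k$gene_id == "inside"], 0)
  p5k <- pair_with_genes(cat, genes, 5000)
  expect_setequal(p5k$gene_id, c("near", "inside"))  # 'far' is 5.6 kb away
  p0 <- pair_with_genes(cat, genes, 0)
  expect_equal(p0$gene_id, "inside")
})

test_that("TSS profiles are flat on uniform coverage and peak at centre", {
  cov_u <- read_bedgraph({
    f <- tempfile(); writeLines("chr1\t0\t10000\t3", f); f
  }, seqlengths = c(chr1 = 10000))
  anchors <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5001))
  prof <- tss_profile_matrix(list(s1 = cov_u), anchors, halfwidth = 2000,
                             n_bins = 100)
  expect_true(all(abs(prof$profiles$s1 - 3) < 1e-9))

  sim <- get_sim("noisefree")
  loci <- sim$peak_sim$truth$loci
  one <- loci[loci$class == "unchanged", ][1, ]
  anchor <- GenomicRanges::GRanges(one$chrom,
                                   IRanges::IRanges(one$center, one$center))
  # window narrow enough to isolate the single planted locus
  pr <- tss_profile_matrix(sim$peak_sim$chip$coverages["ipA_ctrl"], anchor,
                           halfwidth = 750, n_bins = 100)
  row <- pr$profiles$ipA_ctrl[1, ]
  # maximum at the centre bins (interval jitter shifts it by <= 2 bins)
  expect_true(which.max(row) %in% 48:53)

  # control totals are equalised and factors shared with their KD samples
  cov_h <- read_bedgraph({
    f <- tempfile(); writeLines("chr1\t0\t10000\t6", f); f
  }, seqlengths = c(chr1 = 10000))
  pr2 <- tss_profile_matrix(list(c1 = cov_u, c2 = cov_h, k2 = cov_h),
                            anchors, halfwidth = 2000, n_bins = 100,
                            control_map = c(c1 = "c1", c2 = "c2",
                                            k2 = "c2"))
  expect_equal(sum(pr2$profiles$c1), sum(pr2$profiles$c2))
  expect_equal(unname(pr2$scale_factors["k2"]),
               unname(pr2$scale_factors["c2"]))
})

test_that("quantile normalisation equalises column distributions", {
  m <- matrix(c(1, 3, 10, 20), nrow = 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  qn <- quantile_normalise(m)
  expect_equal(sum(qn[, "a"]), sum(qn[, "b"]))
  set.seed(4)
  m2 <- matrix(stats::rlnorm(300), ncol = 3)
  qn2 <- quantile_normalise(m2)
  expect_equal(sort(qn2[, 1]), sort(qn2[, 2]))
  expect_equal(sort(qn2[, 2]), sort(qn2[, 3]))
  # identical columns unchanged
  m3 <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(unclass(quantile_normalise(m3))[, ], m3[, ])
})

test_that("ATAC accessibility falls at shared promoters only under B-KD", {
  sim <- get_sim("noisefree")
  atac <- sim$peak_sim$atac
  acat <- build_consensus(atac$peaks)
  am <- peak_matrix(acat, atac$coverages, atac$read_length)
  am <- quantile_normalise(am)
  tr <- sim$peak_sim$truth$atac
  anchors <- GenomicRanges::GRanges(tr$chrom[tr$shared_promoter],
    IRanges::IRanges(tr$center[tr$shared_promoter],
                     tr$center[tr$shared_promoter]))
  hit <- IRanges::overlapsAny(acat, anchors)
  chg_b <- accessibility_change(am, "atac_ctrl", "atac_kdB")
  chg_a <- accessibility_change(am, "atac_ctrl", "atac_kdA")
  expect_gt(mean(chg_b$log2fc[hit]), 0.5)
  expect_lt(abs(mean(chg_a$log2fc[hit])), 0.15)
  self <- accessibility_change(am, "atac_ctrl", "atac_ctrl")
  expect_true(all(self$log2fc == 0))
})
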