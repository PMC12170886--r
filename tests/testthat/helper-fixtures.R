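# Shared fixtures. The synthetic study is expensive enough to build that the
# suite caches one noise-free and one default-noise realisation.

.fixture_cache <- new.env(parent = emptyenv())

get_sim <- function(variant = c("noisefree", "default"), seed = 101) {
  variant <- match.arg(variant)
  key <- paste0(variant, "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- if (variant == "noisefree") {
    sim_config(seed = seed, peaks = list(noise_sdlog = 0))
  } else {
    sim_config(seed = seed)
  }
  g <- simulate_genome(cfg)
  p <- simulate_peak_experiment(cfg, g)
  res <- list(cfg = cfg, genome_sim = g, peak_sim = p)
  .fixture_cache[[key]] <- res
  res
}

# run the ChIP arm of the pipeline (consensus -> classes) on a peak sim
run_chip_classification <- function(peak_sim, sn = 20, l2fc = 0.5) {
  catalog <- build_consensus(peak_sim$chip$peaks)
  m <- peak_matrix(catalog, peak_sim$chip$coverages,
                   peak_sim$chip$read_length)
  m <- apply_noise_threshold(m, sn)
  ctrl <- c(ipA_ctrl = "ipA_ctrl", ipA_kdA = "ipA_ctrl",
            ipA_kdB = "ipA_ctrl", ipB_ctrl = "ipB_ctrl",
            ipB_kdA = "ipB_ctrl", ipB_kdB = "ipB_ctrl")
  m <- scale_to_control_mode(m, ctrl)
  calls <- list(
    ipA_kdA = call_disappearing(m, "ipA_ctrl", "ipA_kdA", l2fc),
    ipA_kdB = call_disappearing(m, "ipA_ctrl", "ipA_kdB", l2fc),
    ipB_kdA = call_disappearing(m, "ipB_ctrl", "ipB_kdA", l2fc),
    ipB_kdB = call_disappearing(m, "ipB_ctrl", "ipB_kdB", l2fc))
  list(catalog = catalog, matrix = m, calls = calls,
       classes = classify_codependency(calls))
}

# truth class per consensus peak, matched by planted locus centre
truth_class_per_peak <- function(peak_sim, catalog, classes) {
  truth <- peak_sim$truth$loci
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$center, truth$center))
  hit <- GenomicRanges::findOverlaps(tg, catalog)
  est <- classes$class[match(catalog$peak_id[S4Vectors::subjectHits(hit)],
                             classes$peak_id)]
  data.frame(truth = truth$class[S4Vectors::queryHits(hit)], est = est)
}

toy_run <- function(run_id, group, bait_acc, igg_acc = character(),
                    scores = NULL, peptides = NULL) {
  mk <- function(acc, sc, up) {
    data.frame(accession = acc,
               gene = if (length(acc)) paste0("g_", acc) else character(),
               mascot_score = sc, unique_peptides = up,
               coverage_pct = rep(10, length(acc)))
  }
  n <- length(bait_acc)
  bait <- mk(bait_acc,
             if (is.null(scores)) rep(100, n) else scores,
             if (is.null(peptides)) rep(2L, n) else peptides)
  igg <- mk(igg_acc, rep(50, length(igg_acc)), rep(2L, length(igg_acc)))
  rime_run(run_id, group, bait, igg)
}
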