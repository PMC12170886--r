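# Orchestration: configuration validation and the end-to-end synthetic run
# chaining simulate -> interactome -> peaks -> atac -> motifs -> integrate
# -> spr into one report, with a machine-readable manifest (file hashes,
# parameter snapshot) for reproducibility auditing.

.default_pipeline_params <- function() {
  list(seed = 1L,
       sn_threshold = 20, log2fc_threshold = 0.5,
       min_overlap = 0.5, promoter_bp = 2000,
       flank_bp_methods = 5000, flank_bp_results = 1000,
       k = 6L, alpha = 0.05, shared_policy = "both")
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list; unknown keys are rejected,
#' numeric strings are coerced with a warning, and thresholds are
#' range-checked. An empty file yields the all-defaults configuration
#' (signal/noise 20, log2FC 0.5, overlap 0.5, promoter 2 kb, flanks
#' 5000/1000 bp, k 6, alpha 0.05).
#'
#' @param config Path to a YAML/JSON document, a list, or `NULL` for
#'   defaults.
#' @return A validated parameter list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  defaults <- .default_pipeline_params()
  user <- if (is.null(config)) list()
          else if (is.character(config)) {
            if (!file.exists(config)) stop("config file not found: ", config)
            out <- yaml::read_yaml(config)
            if (is.null(out)) list() else out
          } else if (is.list(config)) config
          else stop("config must be a path, a list, or NULL")
  unknown <- setdiff(names(user), c(names(defaults), "sim"))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  sim_over <- user$sim
  user$sim <- NULL
  numeric_keys <- setdiff(names(defaults), "shared_policy")
  for (k in names(user)) {
    v <- user[[k]]
    if (k %in% numeric_keys && is.character(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      if (is.na(coerced)) stop("config key ", k, ": expected a number, got ",
                               dQuote(v))
      warning("config key ", k, ": coerced ", dQuote(v), " to numeric")
      v <- coerced
    }
    if (k %in% numeric_keys && (!is.numeric(v) || length(v) != 1 ||
                                !is.finite(v))) {
      stop("config key ", k, ": expected a single finite number")
    }
    defaults[[k]] <- v
  }
  with(defaults, {
    if (sn_threshold <= 0) stop("sn_threshold must be > 0")
    if (log2fc_threshold < 0) stop("log2fc_threshold must be >= 0")
    if (min_overlap < 0 || min_overlap > 1) stop("min_overlap in [0, 1]")
    if (alpha <= 0 || alpha >= 1) stop("alpha in (0, 1)")
    if (k < 1) stop("k must be >= 1")
    if (!shared_policy %in% c("both", "either")) {
      stop("shared_policy must be 'both' or 'either'")
    }
  })
  defaults$sim <- do.call(sim_config,
                          c(list(seed = defaults$seed),
                            if (is.list(sim_over)) sim_over))
  structure(defaults, class = "pipeline_config")
}

.hash_files <- function(stage, paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(NULL)
  data.frame(stage = stage, file = basename(paths),
             md5 = unname(tools::md5sum(paths)), row.names = NULL)
}

#' Run the full synthetic-study analysis end to end
#'
#' Generates the synthetic study at the configured seed, then runs every
#' analysis stage: interactome comparison and candidate nomination,
#' consensus ChIP peak analysis through co-dependency classification and
#' annotation, ATAC quantile normalisation and accessibility change, motif
#' enrichment of shared disappearing peaks against dual backgrounds, DE
#' quadrant overlap + trend + ChIP-RNA intersection, and the SPR
#' steady-state fit. All interchange is via files under `out_dir`; a
#' manifest of md5 hashes makes deterministic stages auditable.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param out_dir Output directory (created if needed).
#' @return List of class `tsppi_run` with `report` (headline results per
#'   stage) and `manifest` (stage/file/md5 data frame).
#' @export
run_all <- function(config = NULL, out_dir = tempfile("tsppi_run_")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage <- function(name, expr) {
    message("[tsppi] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim_dir <- file.path(out_dir, "sim")
  gsim <- stage("simulate_genome", simulate_genome(cfg$sim, sim_dir))
  psim <- stage("simulate_peaks",
                simulate_peak_experiment(cfg$sim, gsim, sim_dir))
  dsim <- stage("simulate_de",
                simulate_de_tables(cfg$sim, psim$truth$intersection_genes,
                                   sim_dir))
  isim <- stage("simulate_interactome",
                simulate_interactome_runs(cfg$sim, sim_dir))
  ssim <- stage("simulate_spr", simulate_sensorgrams(cfg$sim, sim_dir))
  manifest[["simulate"]] <- .hash_files("simulate",
                                        list.files(sim_dir,
                                                   full.names = TRUE))

  # interactome
  cmp <- stage("interactome", {
    runs <- isim$runs
    grp <- vapply(runs, function(r) r$group, character(1))
    compare_groups(runs[grp == cfg$sim$interactome$group_a],
                   runs[grp == cfg$sim$interactome$group_b])
  })
  candidates <- nominate_candidates(cmp)
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ChIP peaks
  chip <- psim$chip
  peak_res <- stage("peaks", {
    catalog <- build_consensus(chip$peaks)
    m <- peak_matrix(catalog, chip$coverages, chip$read_length)
    m <- apply_noise_threshold(m, cfg$sn_threshold)
    ctrl_map <- c(ipA_ctrl = "ipA_ctrl", ipA_kdA = "ipA_ctrl",
                  ipA_kdB = "ipA_ctrl", ipB_ctrl = "ipB_ctrl",
                  ipB_kdA = "ipB_ctrl", ipB_kdB = "ipB_ctrl")
    m <- scale_to_control_mode(m, ctrl_map)
    calls <- list(
      ipA_kdA = call_disappearing(m, "ipA_ctrl", "ipA_kdA",
                                  cfg$log2fc_threshold),
      ipA_kdB = call_disappearing(m, "ipA_ctrl", "ipA_kdB",
                                  cfg$log2fc_threshold),
      ipB_kdA = call_disappearing(m, "ipB_ctrl", "ipB_kdA",
                                  cfg$log2fc_threshold),
      ipB_kdB = call_disappearing(m, "ipB_ctrl", "ipB_kdB",
                                  cfg$log2fc_threshold))
    classes <- classify_codependency(calls, cfg$shared_policy)
    ann <- annotate_peaks(catalog, gsim$feature_tracks, cfg$min_overlap)
    pairs5k <- pair_with_genes(catalog, gsim$genes, cfg$flank_bp_methods)
    list(catalog = catalog, matrix = m, classes = classes, ann = ann,
         pairs = pairs5k)
  })
  utils::write.table(peak_res$classes,
                     file.path(out_dir, "peak_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(peak_res$catalog, file.path(out_dir, "consensus_peaks.bed"))

  # ATAC
  atac_res <- stage("atac", {
    acat <- build_consensus(psim$atac$peaks)
    am <- peak_matrix(acat, psim$atac$coverages, psim$atac$read_length)
    am <- quantile_normalise(am)
    list(catalog = acat,
         change = accessibility_change(am, "atac_ctrl", "atac_kdB"))
  })

  # motifs: shared disappearing peaks vs all peaks and promoter background
  motif_res <- stage("motifs", {
    catalog <- peak_res$catalog
    shared_ids <- peak_res$classes$peak_id[peak_res$classes$class ==
                                             "shared"]
    fg_gr <- catalog[catalog$peak_id %in% shared_ids]
    genome <- psim$genome
    fg <- count_kmer_presence(extract_sequences(fg_gr, genome), cfg$k)
    bg_all <- count_kmer_presence(extract_sequences(catalog, genome), cfg$k)
    proms <- promoter_of(gsim$genes, cfg$promoter_bp)
    bg_up <- count_kmer_presence(extract_sequences(proms, genome), cfg$k)
    dual_background_report(fg, bg_all, bg_up, cfg$alpha)
  })
  utils::write.table(motif_res, file.path(out_dir, "motif_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # DE integration
  integ <- stage("integrate", {
    quad <- classify_overlap(dsim$de_a, dsim$de_b, cfg$alpha)
    trend <- fit_trend(quad)
    shared_ids <- peak_res$classes$peak_id[peak_res$classes$class ==
                                             "shared"]
    shared_cat <- peak_res$catalog[peak_res$catalog$peak_id %in% shared_ids]
    pairs1k <- pair_with_genes(shared_cat, gsim$genes, cfg$flank_bp_results)
    list(quad = quad, trend = trend,
         intersection = intersect_chip_rna(quad, pairs1k))
  })
  utils::write.table(integ$quad$table, file.path(out_dir, "quadrants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # SPR
  spr_res <- stage("spr", {
    corrected <- double_reference(ssim$sensorgrams)
    man <- ssim$sensorgrams$manifest
    analyte <- man$cycle_id[man$type == "analyte"]
    req <- vapply(analyte, function(cy) {
      tr <- corrected[corrected$cycle_id == cy, ]
      i <- match(cy, man$cycle_id)
      steady_state_response(tr, man$assoc_start_s[i],
                            man$assoc_end_s[i])$req
    }, numeric(1))
    conc <- vapply(analyte, function(cy) {
      corrected$concentration_nM[match(cy, corrected$cycle_id)]
    }, numeric(1))
    fit_steady_state(conc, req)
  })

  manifest[["results"]] <- .hash_files(
    "results", list.files(out_dir, full.names = TRUE, pattern = "\\.tsv$|\\.bed$"))
  man_tab <- do.call(rbind, manifest)
  rownames(man_tab) <- NULL
  class_counts <- table(peak_res$classes$class)
  report <- list(
    candidate = if (nrow(candidates)) candidates$accession[1] else NA,
    interactome_counts = cmp$counts,
    peak_class_counts = class_counts,
    top_motifs = utils::head(
      motif_res[motif_res$background_label == "all_peaks", "kmer"], 5),
    quadrant_counts = integ$quad$counts,
    trend_r_squared = integ$trend$r_squared,
    intersection_counts = integ$intersection$counts,
    kd_nM = spr_res$kd_nM,
    atac_mean_log2fc_shared = {
      tr <- psim$truth$atac[psim$truth$atac$shared_promoter, ]
      anchors <- GRanges(tr$chrom, IRanges(tr$center, tr$center))
      hit <- IRanges::overlapsAny(atac_res$catalog, anchors)
      mean(atac_res$change$log2fc[hit])
    })
  structure(list(report = report, manifest = man_tab, out_dir = out_dir),
            class = "tsppi_run")
}

#' @export
print.tsppi_run <- function(x, ...) {
  r <- x$report
  cat("tsppi end-to-end run\n")
  cat("  top candidate interactor:", r$candidate, "\n")
  cat("  peak classes:", paste(names(r$peak_class_counts),
                               r$peak_class_counts, collapse = ", "), "\n")
  cat("  DE quadrants:", paste(names(r$quadrant_counts),
                               r$quadrant_counts, collapse = ", "), "\n")
  cat(sprintf("  trend R^2: %.4f\n", r$trend_r_squared))
  cat(sprintf("  steady-state KD: %.1f nM\n", r$kd_nM))
  invisible(x)
}
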