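# Consensus ChIP/ATAC peak analysis.
#
# Pipeline order for ChIP: build_consensus -> peak_matrix (amplitudes scaled
# on read length) -> apply_noise_threshold -> scale_to_control_mode ->
# call_disappearing per (IP, knockdown) -> classify_codependency ->
# annotate / pair_with_genes / tss_profile_matrix.
# ATAC uses quantile_normalise instead of the S/N + mode-scaling steps, then
# accessibility_change.

#' Build consensus peaks across samples by the midpoint-matching rule
#'
#' Two peaks match when the midpoint of either falls within the span of the
#' other. Matching is applied transitively across all samples: connected
#' components of the match graph become one consensus peak spanning the
#' minimum start to maximum end of its members.
#'
#' @param peak_sets Named list (sample id -> `GRanges`) of per-sample peaks.
#' @param seqlevels Optional character vector of known chromosomes; peaks on
#'   other chromosomes raise an error.
#' @return A `GRanges` of consensus peaks sorted by coordinate, with
#'   `peak_id` and `n_members` columns and a `membership` data frame
#'   (peak_id, sample_id, member start/end) attached as
#'   `metadata(x)$membership`.
#' @export
build_consensus <- function(peak_sets, seqlevels = NULL) {
  stopifnot(length(peak_sets) >= 1, !is.null(names(peak_sets)))
  pool <- suppressWarnings(do.call(c, lapply(names(peak_sets), function(s) {
    g <- peak_sets[[s]]
    mcols(g) <- NULL
    g$sample_id <- rep(s, length(g))
    g
  })))
  if (!is.null(seqlevels)) {
    bad <- setdiff(unique(as.character(seqnames(pool))), seqlevels)
    if (length(bad)) stop("peaks on unknown chromosome(s): ",
                          paste(bad, collapse = ", "))
  }
  strand(pool) <- "*"
  if (!length(pool)) {
    out <- GRanges()
    S4Vectors::metadata(out)$membership <- data.frame()
    return(out)
  }
  hits <- findOverlaps(pool, pool, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  mid <- midpoint(pool)
  ok <- (mid[q] >= start(pool)[s] & mid[q] <= end(pool)[s]) |
        (mid[s] >= start(pool)[q] & mid[s] <= end(pool)[q])
  g <- igraph::graph_from_edgelist(cbind(q[ok], s[ok]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(pool) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  chrom <- as.character(seqnames(pool))
  cs <- tapply(start(pool), comp, min)
  ce <- tapply(end(pool), comp, max)
  cchr <- tapply(chrom, comp, function(x) x[[1L]])
  comp_ids <- as.integer(names(cs))
  out <- GRanges(as.character(cchr), IRanges(as.integer(cs), as.integer(ce)))
  if (!is.null(seqlevels)) seqlevels(out) <- seqlevels
  ord <- order(as.character(seqnames(out)), start(out), end(out))
  out <- out[ord]
  comp_ids <- comp_ids[ord]
  out$peak_id <- sprintf("peak_%05d", seq_along(out))
  sizes <- table(comp)
  out$n_members <- as.integer(sizes[as.character(comp_ids)])
  S4Vectors::metadata(out)$membership <- data.frame(
    peak_id = out$peak_id[match(comp, comp_ids)],
    sample_id = pool$sample_id,
    member_start = start(pool), member_end = end(pool))
  out
}

#' Quantify peak amplitude from a coverage track
#'
#' Amplitude is the summed per-base depth within the consensus interval,
#' divided by the read length: an estimated fragment count ("scaled on the
#' read length"). Chromosomes absent from the coverage yield amplitude 0
#' with a warning.
#'
#' @param catalog Consensus peak `GRanges`.
#' @param cov Per-chromosome `RleList` of depths.
#' @param read_length Read length in bp (> 0).
#' @return Numeric vector of amplitudes, one per peak.
#' @export
quantify <- function(catalog, cov, read_length) {
  stopifnot(read_length > 0)
  amp <- numeric(length(catalog))
  chroms <- as.character(seqnames(catalog))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    if (!ch %in% names(cov)) {
      warning("coverage missing chromosome ", ch, "; amplitude set to 0")
      next
    }
    r <- cov[[ch]]
    s <- pmax(start(catalog)[idx], 1L)
    e <- pmin(end(catalog)[idx], length(r))
    ok <- s <= e
    if (any(ok)) {
      v <- Views(r, s[ok], e[ok])
      amp[idx[ok]] <- viewSums(v) / read_length
    }
  }
  amp
}

#' Build the peak-by-sample amplitude matrix
#'
#' @param catalog Consensus peak `GRanges` with `peak_id`.
#' @param coverages Named list (sample id -> `RleList`) of coverage tracks.
#' @param read_length Read length in bp.
#' @return Numeric matrix (rows = peak ids, columns = samples) with a
#'   `provenance` attribute recording the scaling state.
#' @export
peak_matrix <- function(catalog, coverages, read_length) {
  stopifnot(length(coverages) >= 1, !is.null(names(coverages)))
  m <- vapply(coverages, function(cov) quantify(catalog, cov, read_length),
              numeric(length(catalog)))
  m <- matrix(m, nrow = length(catalog),
              dimnames = list(catalog$peak_id, names(coverages)))
  attr(m, "provenance") <- sprintf("raw amplitudes, read_length=%d",
                                   as.integer(read_length))
  m
}

.add_provenance <- function(m, note) {
  attr(m, "provenance") <- c(attr(m, "provenance"), note)
  m
}

#' Apply the signal/noise threshold
#'
#' Values below `threshold` are floored to `threshold` (noise floor); rows
#' floored in every sample are dropped as noise-only. Both actions are
#' recorded in the matrix provenance.
#'
#' @param m Amplitude matrix.
#' @param threshold Signal/noise threshold (default 20).
#' @param drop_all_floored Drop rows floored in all samples (default TRUE).
#' @return Filtered, floored matrix.
#' @export
apply_noise_threshold <- function(m, threshold = 20, drop_all_floored = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0")
  }
  floored <- m < threshold
  m2 <- pmax(m, threshold)
  dropped <- character()
  if (drop_all_floored) {
    all_fl <- rowSums(!floored) == 0
    dropped <- rownames(m)[all_fl]
    m2 <- m2[!all_fl, , drop = FALSE]
  }
  m2 <- .add_provenance(m2, sprintf(
    "S/N floor %g applied; %d values floored; %d all-floored rows dropped",
    threshold, sum(floored), length(dropped)))
  attr(m2, "dropped_rows") <- dropped
  m2
}

# Mode of log2 amplitudes via a fixed-width histogram (bin 0.1); ties take
# the lowest bin. Deterministic and robust to the heavy right tail.
.log2_mode <- function(x, bin = 0.1) {
  lx <- log2(x[x > 0])
  lo <- floor(min(lx) / bin) * bin
  idx <- floor((lx - lo) / bin + 1e-9)
  tab <- table(idx)
  best <- min(as.integer(names(tab)[tab == max(tab)]))
  lo + (best + 0.5) * bin
}

#' Scale samples to the mode of their control's amplitude distribution
#'
#' Each sample is multiplied by `2^(mode_control - mode_sample)`, where the
#' mode is the centre of the maximal 0.1-wide bin of the log2 amplitude
#' histogram. Each knockdown sample is scaled to its own IP's control
#' sample, making distributions comparable across samples.
#'
#' @param m Floored amplitude matrix.
#' @param control_map Named character vector mapping every sample (column) to
#'   its control sample.
#' @param bin Histogram bin width in log2 units (default 0.1).
#' @return Scaled matrix; per-sample factors in attribute `scale_factors`.
#' @export
scale_to_control_mode <- function(m, control_map, bin = 0.1) {
  if (!all(colnames(m) %in% names(control_map))) {
    stop("every sample must be mapped to a control")
  }
  if (!all(control_map[colnames(m)] %in% colnames(m))) {
    stop("control sample(s) missing from matrix")
  }
  modes <- vapply(colnames(m), function(s) .log2_mode(m[, s], bin),
                  numeric(1))
  factors <- 2^(modes[control_map[colnames(m)]] - modes)
  names(factors) <- colnames(m)
  out <- sweep(m, 2, factors, "*")
  out <- .add_provenance(out, sprintf(
    "mode-scaled to controls (bin %g); factors: %s", bin,
    paste(sprintf("%s=%.4g", names(factors), factors), collapse = ", ")))
  attr(out, "scale_factors") <- factors
  out
}

#' Call disappearing peaks for one knockdown-vs-control contrast
#'
#' A peak disappears when `log2(control / knockdown) >= log2fc_threshold`
#' (boundary inclusive); the S/N floor guarantees finite ratios.
#'
#' @param m Scaled amplitude matrix.
#' @param control_col,kd_col Column names of the control and knockdown
#'   samples (same IP).
#' @param log2fc_threshold Reduction threshold in log2 units (default 0.5).
#' @return Data frame `peak_id`, `log2fc`, `disappearing`.
#' @export
call_disappearing <- function(m, control_col, kd_col, log2fc_threshold = 0.5) {
  stopifnot(control_col %in% colnames(m), kd_col %in% colnames(m))
  l2 <- log2(m[, control_col] / m[, kd_col])
  data.frame(peak_id = rownames(m), log2fc = as.numeric(l2),
             disappearing = as.numeric(l2) >= log2fc_threshold,
             row.names = NULL)
}

#' Classify knockdown co-dependency of consensus peaks
#'
#' Takes the four disappearing-peak calls — IP of protein A and IP of
#' protein B, each under knockdown of A and of B — over one shared catalog.
#' A peak is "reduced under a knockdown" when it disappears in at least one
#' IP under that knockdown. Classes: reduced under A only -> `A_specific`;
#' under B only -> `B_specific`; under both (`policy = "both"`, default) ->
#' `shared`; neither -> `unchanged`. With `policy = "either"`, `shared`
#' instead requires disappearance in at least one IP-A track and one IP-B
#' track (signal lost from both proteins' IPs) under any knockdown.
#'
#' @param calls Named list of four [call_disappearing()] data frames with
#'   names `ipA_kdA`, `ipA_kdB`, `ipB_kdA`, `ipB_kdB`.
#' @param policy `"both"` or `"either"` (see above).
#' @return Data frame `peak_id`, `class`, plus the four log2FC columns.
#' @export
classify_codependency <- function(calls, policy = c("both", "either")) {
  policy <- match.arg(policy)
  need <- c("ipA_kdA", "ipA_kdB", "ipB_kdA", "ipB_kdB")
  if (!all(need %in% names(calls))) {
    stop("calls must be named ", paste(need, collapse = ", "))
  }
  ids <- calls[[1]]$peak_id
  for (nm in need) {
    if (!identical(calls[[nm]]$peak_id, ids)) {
      stop("mismatched peak catalogs between disappearing-call sets")
    }
  }
  d <- lapply(calls[need], function(x) x$disappearing)
  red_a <- d$ipA_kdA | d$ipB_kdA  # reduced under A knockdown
  red_b <- d$ipA_kdB | d$ipB_kdB  # reduced under B knockdown
  if (policy == "both") {
    cls <- ifelse(red_a & red_b, "shared",
           ifelse(red_a, "A_specific",
           ifelse(red_b, "B_specific", "unchanged")))
  } else {
    in_ipa <- d$ipA_kdA | d$ipA_kdB
    in_ipb <- d$ipB_kdA | d$ipB_kdB
    cls <- ifelse(in_ipa & in_ipb, "shared",
           ifelse(red_a & !red_b, "A_specific",
           ifelse(red_b & !red_a, "B_specific",
           ifelse(red_a | red_b, "shared", "unchanged"))))
  }
  data.frame(peak_id = ids, class = cls,
             log2fc_ipA_kdA = calls$ipA_kdA$log2fc,
             log2fc_ipA_kdB = calls$ipA_kdB$log2fc,
             log2fc_ipB_kdA = calls$ipB_kdA$log2fc,
             log2fc_ipB_kdB = calls$ipB_kdB$log2fc,
             row.names = NULL)
}

#' Annotate peaks by genomic feature overlap
#'
#' A feature label is assigned when at least `min_overlap` of the peak is
#' covered by the union of that feature track's intervals (boundary
#' inclusive). Multiple labels per peak are allowed.
#'
#' @param catalog Consensus peak `GRanges` with `peak_id`.
#' @param feature_tracks Named list (label -> `GRanges`) of feature tracks,
#'   e.g. exon, intron, promoter, utr3, utr5, enhancer, cpg_island, tfbs,
#'   ctcf.
#' @param min_overlap Minimum covered fraction of the peak (default 0.5).
#' @return Data frame `peak_id`, `label` (one row per assigned label).
#' @export
annotate_peaks <- function(catalog, feature_tracks, min_overlap = 0.5) {
  stopifnot(!is.null(names(feature_tracks)))
  out <- list()
  for (lab in names(feature_tracks)) {
    track <- GenomicRanges::reduce(feature_tracks[[lab]], ignore.strand = TRUE)
    hits <- findOverlaps(catalog, track, ignore.strand = TRUE)
    if (!length(hits)) next
    ov <- pmin(end(catalog)[queryHits(hits)], end(track)[subjectHits(hits)]) -
          pmax(start(catalog)[queryHits(hits)], start(track)[subjectHits(hits)]) + 1L
    covered <- tapply(ov, queryHits(hits), sum)
    frac <- as.numeric(covered) / width(catalog)[as.integer(names(covered))]
    keep <- frac >= min_overlap
    if (any(keep)) {
      out[[lab]] <- data.frame(
        peak_id = catalog$peak_id[as.integer(names(covered))[keep]],
        label = lab, row.names = NULL)
    }
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(), label = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$peak_id, res$label), , drop = FALSE]
}

#' Pair peaks with genes within a flanking distance
#'
#' A (peak, gene) pair is emitted when the gene interval intersects the peak
#' interval extended by `flank_bp` on both sides. Distance is 0 for
#' overlapping pairs, else the gap in bp. Presets: 5000 bp (the ChIP
#' methods-mode default) and 1000 bp (the results-mode vicinity).
#'
#' @param catalog Consensus peak `GRanges` with `peak_id`.
#' @param genes Gene `GRanges` with `gene_id`.
#' @param flank_bp Flank in bp (default 5000).
#' @return Data frame `peak_id`, `gene_id`, `distance_bp`.
#' @export
pair_with_genes <- function(catalog, genes, flank_bp = 5000) {
  stopifnot(flank_bp >= 0)
  ext <- catalog
  GenomicRanges::ranges(ext) <- IRanges(pmax(1L, start(catalog) - flank_bp),
                                        end(catalog) + flank_bp)
  hits <- findOverlaps(ext, genes, ignore.strand = TRUE)
  if (!length(hits)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance_bp = integer()))
  }
  q <- queryHits(hits); s <- subjectHits(hits)
  gap <- pmax(start(genes)[s] - end(catalog)[q],
              start(catalog)[q] - end(genes)[s], 0L)
  data.frame(peak_id = catalog$peak_id[q], gene_id = genes$gene_id[s],
             distance_bp = as.integer(gap), row.names = NULL)
}

#' Binned coverage profiles around anchor positions
#'
#' Mean depth per bin over `[anchor - halfwidth, anchor + halfwidth)` for
#' each sample. Sample-level scale factors are chosen so all control
#' matrices sum to the same total (their mean), and each knockdown sample
#' inherits its control's factor. Anchors near chromosome edges are
#' zero-padded and flagged.
#'
#' @param coverages Named list (sample id -> `RleList`).
#' @param anchors `GRanges` of anchor positions (midpoints are used).
#' @param halfwidth Half-window in bp (default 2000).
#' @param n_bins Number of bins across the window (default 100).
#' @param control_map Named character vector mapping each sample to its
#'   control (controls map to themselves). If `NULL`, no scaling.
#' @return List with `profiles` (sample -> anchors x bins matrix),
#'   `scale_factors`, and logical `edge_flag` per anchor.
#' @export
tss_profile_matrix <- function(coverages, anchors, halfwidth = 2000,
                               n_bins = 100, control_map = NULL) {
  stopifnot((2 * halfwidth) %% n_bins == 0)
  binw <- (2 * halfwidth) / n_bins
  mids <- midpoint(anchors)
  chroms <- as.character(seqnames(anchors))
  edge_flag <- logical(length(anchors))
  profiles <- lapply(coverages, function(cov) {
    m <- matrix(0, nrow = length(anchors), ncol = n_bins)
    for (i in seq_along(anchors)) {
      ch <- chroms[i]
      if (!ch %in% names(cov)) { edge_flag[i] <<- TRUE; next }
      r <- cov[[ch]]
      from <- mids[i] - halfwidth
      to <- mids[i] + halfwidth - 1L
      if (from < 1L || to > length(r)) edge_flag[i] <<- TRUE
      lo <- max(1L, from); hi <- min(length(r), to)
      if (lo > hi) next
      vals <- numeric(2 * halfwidth)
      vals[(lo - from + 1L):(hi - from + 1L)] <- as.numeric(r[lo:hi])
      m[i, ] <- colMeans(matrix(vals, nrow = binw))
    }
    m
  })
  names(profiles) <- names(coverages)
  factors <- stats::setNames(rep(1, length(coverages)), names(coverages))
  if (!is.null(control_map)) {
    ctrls <- unique(control_map[names(coverages)])
    totals <- vapply(ctrls, function(s) sum(profiles[[s]]), numeric(1))
    target <- mean(totals[totals > 0])
    cf <- ifelse(totals > 0, target / totals, 1)
    names(cf) <- ctrls
    factors[names(coverages)] <- cf[control_map[names(coverages)]]
    profiles <- Map(function(p, f) p * f, profiles, factors)
  }
  list(profiles = profiles, scale_factors = factors, edge_flag = edge_flag)
}

#' Quantile-normalise an amplitude matrix
#'
#' Classic quantile normalisation (each column's order statistics replaced by
#' the across-column means; ties receive the mean of their rank positions),
#' via [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix with at least two columns.
#' @return Normalised matrix with provenance updated.
#' @export
quantile_normalise <- function(m) {
  stopifnot(ncol(m) >= 2)
  out <- limma::normalizeQuantiles(as.matrix(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  attr(out, "provenance") <- c(attr(m, "provenance"), "quantile normalised")
  out
}

#' Per-peak accessibility change between ATAC samples
#'
#' @param m Quantile-normalised ATAC amplitude matrix.
#' @param control_col,kd_col Column names to contrast.
#' @return Data frame `peak_id`, `log2fc` where
#'   `log2fc = log2(control / knockdown)`.
#' @export
accessibility_change <- function(m, control_col, kd_col) {
  stopifnot(control_col %in% colnames(m), kd_col %in% colnames(m))
  data.frame(peak_id = rownames(m),
             log2fc = as.numeric(log2(m[, control_col] / m[, kd_col])),
             row.names = NULL)
}
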