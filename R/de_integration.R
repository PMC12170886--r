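# Differential-expression overlap quadrants, trend regression, ChIP-RNA
# intersection, and delta-delta Ct quantification.
#
# Sign vocabulary: log2fc is always knockdown-vs-control, so log2fc < 0
# means the transcript falls when the protein is removed (the gene is
# positively regulated by the protein). DE significance is consumed, not
# computed: input tables must carry adjusted p-values.

#' Read a DE result table (TSV: gene_id, log2fc, p_adj)
#' @param path TSV path.
#' @return Data frame.
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% names(tab))) {
    stop("DE table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  tab
}

#' Classify the overlap of two knockdown DE tables into quadrants
#'
#' Shared genes are significant in both tables (`p_adj < alpha`). Within
#' shared: `co_down` when both log2FCs are negative, `co_up` when both are
#' positive, `discordant` when the signs differ. Genes significant in
#' exactly one table fall into `a_only` / `b_only`.
#'
#' @param de_a,de_b Data frames with `gene_id`, `log2fc`, `p_adj`; duplicate
#'   gene ids are an error.
#' @param alpha Shared adjusted-p threshold (default 0.05).
#' @return List of class `quadrant_classification` with the five gene-id
#'   sets, `shared` (their union), a per-gene `table`, and `counts`.
#' @export
classify_overlap <- function(de_a, de_b, alpha = 0.05) {
  for (tab in list(de_a, de_b)) {
    if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids in DE table")
    if (any(tab$p_adj < 0 | tab$p_adj > 1, na.rm = TRUE)) {
      stop("p_adj outside [0, 1]")
    }
  }
  sig_a <- de_a$gene_id[de_a$p_adj < alpha]
  sig_b <- de_b$gene_id[de_b$p_adj < alpha]
  shared <- intersect(sig_a, sig_b)
  fa <- de_a$log2fc[match(shared, de_a$gene_id)]
  fb <- de_b$log2fc[match(shared, de_b$gene_id)]
  co_down <- shared[fa < 0 & fb < 0]
  co_up <- shared[fa > 0 & fb > 0]
  discordant <- shared[fa * fb < 0]
  a_only <- setdiff(sig_a, shared)
  b_only <- setdiff(sig_b, shared)
  tab <- data.frame(
    gene_id = shared, log2fc_a = fa, log2fc_b = fb,
    class = ifelse(fa < 0 & fb < 0, "co_down",
            ifelse(fa > 0 & fb > 0, "co_up", "discordant")),
    row.names = NULL)
  structure(list(
    co_down = co_down, co_up = co_up, discordant = discordant,
    a_only = a_only, b_only = b_only, shared = shared, table = tab,
    counts = c(shared = length(shared), co_down = length(co_down),
               co_up = length(co_up), discordant = length(discordant),
               a_only = length(a_only), b_only = length(b_only))
  ), class = "quadrant_classification")
}

#' @export
print.quadrant_classification <- function(x, ...) {
  cat("DE overlap quadrants\n")
  cat(sprintf("  shared: %d (co-down %d, co-up %d, discordant %d)\n",
              x$counts[["shared"]], x$counts[["co_down"]],
              x$counts[["co_up"]], x$counts[["discordant"]]))
  cat(sprintf("  A only: %d, B only: %d\n",
              x$counts[["a_only"]], x$counts[["b_only"]]))
  invisible(x)
}

#' Fit the shared-effect trend line
#'
#' Ordinary least squares of the B-knockdown log2FC on the A-knockdown
#' log2FC over the shared gene set.
#'
#' @param log2fc_a,log2fc_b Numeric vectors of equal length (n >= 2); or a
#'   `quadrant_classification` as the first argument.
#' @return List of class `trend_fit` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_trend <- function(log2fc_a, log2fc_b = NULL) {
  if (inherits(log2fc_a, "quadrant_classification")) {
    tab <- log2fc_a$table
    log2fc_b <- tab$log2fc_b
    log2fc_a <- tab$log2fc_a
  }
  stopifnot(length(log2fc_a) == length(log2fc_b))
  if (length(log2fc_a) < 2) stop("need at least 2 points")
  if (stats::var(log2fc_a) == 0) stop("all x values equal: slope undefined")
  fit <- stats::lm(log2fc_b ~ log2fc_a)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log2fc_b - mean(log2fc_b))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = length(log2fc_a)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit: slope %.4f, intercept %.4f, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Intersect shared DE genes with genes paired to shared peaks
#'
#' Reports the genes that are both co-regulated at the transcript level
#' (shared DE quadrants) and lie near shared (co-dependent) binding sites,
#' with their quadrant direction.
#'
#' @param quadrants A [classify_overlap()] result.
#' @param peak_gene_pairs A [pair_with_genes()] table restricted to
#'   shared-class peaks.
#' @return List with `table` (gene_id, class) and `counts` (down, up,
#'   discordant, total).
#' @export
intersect_chip_rna <- function(quadrants, peak_gene_pairs) {
  stopifnot(inherits(quadrants, "quadrant_classification"))
  near <- unique(peak_gene_pairs$gene_id)
  genes <- intersect(quadrants$shared, near)
  cls <- quadrants$table$class[match(genes, quadrants$table$gene_id)]
  tab <- data.frame(gene_id = genes, class = cls, row.names = NULL)
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       counts = c(down = sum(cls == "co_down"), up = sum(cls == "co_up"),
                  discordant = sum(cls == "discordant"),
                  total = length(genes)))
}

#' Relative expression by the delta-delta Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt - mean dCt` of
#' the control group; fold change `2^(-ddCt)` relative to control. Samples
#' missing either Ct are excluded with a warning.
#'
#' @param ct_table Data frame with columns `sample`, `group`, `gene`, `ct`.
#' @param target Target gene name.
#' @param reference Reference (housekeeping) gene name, default `"GAPDH"`.
#' @param control_group Label of the control group (default `"control"`).
#' @return Data frame `sample`, `group`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
delta_delta_ct <- function(ct_table, target, reference = "GAPDH",
                           control_group = "control") {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  }
  t_tab <- ct_table[ct_table$gene == target, ]
  r_tab <- ct_table[ct_table$gene == reference, ]
  if (!nrow(r_tab)) stop("reference gene ", reference, " not found")
  samples <- union(t_tab$sample, r_tab$sample)
  ct_t <- t_tab$ct[match(samples, t_tab$sample)]
  ct_r <- r_tab$ct[match(samples, r_tab$sample)]
  ok <- !is.na(ct_t) & !is.na(ct_r)
  if (any(!ok)) {
    warning("excluding sample(s) with missing Ct: ",
            paste(samples[!ok], collapse = ", "))
  }
  samples <- samples[ok]
  dct <- ct_t[ok] - ct_r[ok]
  grp <- ct_table$group[match(samples, ct_table$sample)]
  if (!any(grp == control_group)) stop("no control-group sample")
  ddct <- dct - mean(dct[grp == control_group])
  data.frame(sample = samples, group = grp, delta_ct = dct,
             delta_delta_ct = ddct, fold_change = 2^(-ddct),
             row.names = NULL)
}
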