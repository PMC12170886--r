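# Differential bait-IP interactome comparison.
#
# A "run" is one bait immunoprecipitation with its matched IgG isotype
# control, each a table of protein identifications. Contaminant subtraction
# is per run (bait minus its own IgG), after which group-level unions,
# intersections and the all-A-runs-not-in-B candidate rule are pure set
# algebra on accessions.

#' Construct a bait-IP run
#'
#' @param run_id Unique run identifier.
#' @param group Group label, one of `"TNBC"`, `"BCELL"`, `"BRAIN"`, `"other"`.
#' @param bait_hits,igg_hits Data frames with columns `accession`, `gene`,
#'   `mascot_score`, `unique_peptides` (and optionally `coverage_pct`).
#' @return A list of class `rime_run`.
#' @export
rime_run <- function(run_id, group, bait_hits, igg_hits) {
  group <- match.arg(group, c("TNBC", "BCELL", "BRAIN", "other"))
  for (tab in list(bait_hits, igg_hits)) {
    need <- c("accession", "gene", "mascot_score", "unique_peptides")
    if (!all(need %in% names(tab))) {
      stop("hit table must have columns: ", paste(need, collapse = ", "))
    }
    if (anyNA(tab$accession) || any(!nzchar(tab$accession))) {
      stop("empty accession in hit table")
    }
    if (any(!is.finite(tab$mascot_score)) || any(tab$mascot_score < 0)) {
      stop("mascot_score must be finite and >= 0")
    }
  }
  structure(list(run_id = run_id, group = group,
                 bait_hits = bait_hits, igg_hits = igg_hits),
            class = "rime_run")
}

#' Read a protein hit table (TSV)
#'
#' Columns: `accession`, `gene`, `mascot_score`, `unique_peptides`,
#' optionally `coverage_pct`.
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "gene", "mascot_score", "unique_peptides")
  if (!all(need %in% names(tab))) {
    stop("hit table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  tab
}

#' Read a run manifest and its hit tables
#'
#' The manifest TSV has columns `run_id`, `group`, `bait_path`, `igg_path`;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return A list of [rime_run()] objects.
#' @export
read_run_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    rime_run(man$run_id[i], man$group[i],
             read_hit_table(resolve(man$bait_path[i])),
             read_hit_table(resolve(man$igg_path[i])))
  })
}

#' Run-specific interactors after IgG subtraction and peptide filtering
#'
#' Bait accessions also present in the run's matched IgG control are
#' subtracted; identifications with fewer than `min_unique_peptides` unique
#' peptides are excluded.
#'
#' @param run A [rime_run()].
#' @param min_unique_peptides Minimum unique peptide count (default 1).
#' @return Character vector of accessions (possibly empty).
#' @export
filter_run <- function(run, min_unique_peptides = 1) {
  stopifnot(inherits(run, "rime_run"))
  bait <- run$bait_hits
  keep <- bait$unique_peptides >= min_unique_peptides
  setdiff(unique(bait$accession[keep]), unique(run$igg_hits$accession))
}

#' Cumulative Mascot scores across filtered runs
#'
#' For each accession surviving [filter_run()] in at least one run, sums its
#' Mascot score over the runs where it survives (absence contributes 0).
#' These are the word-cloud weights.
#'
#' @param runs List of [rime_run()] objects.
#' @param min_unique_peptides Passed to [filter_run()].
#' @return Named numeric vector, accession -> summed score.
#' @export
cumulative_scores <- function(runs, min_unique_peptides = 1) {
  acc <- character()
  val <- numeric()
  for (run in runs) {
    keep_acc <- filter_run(run, min_unique_peptides)
    b <- run$bait_hits[run$bait_hits$accession %in% keep_acc, ]
    s <- tapply(b$mascot_score, b$accession, sum)
    acc <- c(acc, names(s))
    val <- c(val, as.numeric(s))
  }
  out <- tapply(val, acc, sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res[order(names(res))]
}

#' Compare bait interactomes between two sample groups
#'
#' Computes per-group unions of run-specific interactors, their
#' intersection, the group-A-only set, and the candidate set of accessions
#' found in every filtered group-A run but in no group-B run. The identity
#' `|A_only| = |A_union| - |A intersect B|` holds by construction.
#'
#' @param runs_a,runs_b Non-empty lists of [rime_run()] objects.
#' @param min_unique_peptides Passed to [filter_run()].
#' @return A list of class `interactome_comparison` with elements `a_union`,
#'   `b_union`, `shared`, `a_only`, `candidates`, `scores` (cumulative
#'   group-A scores) and the size summary `counts`.
#' @export
compare_groups <- function(runs_a, runs_b, min_unique_peptides = 1) {
  if (!length(runs_a) || !length(runs_b)) {
    stop("each group needs at least one run")
  }
  fa <- lapply(runs_a, filter_run, min_unique_peptides = min_unique_peptides)
  fb <- lapply(runs_b, filter_run, min_unique_peptides = min_unique_peptides)
  a_union <- sort(unique(unlist(fa)))
  b_union <- sort(unique(unlist(fb)))
  shared <- intersect(a_union, b_union)
  a_only <- setdiff(a_union, shared)
  in_all_a <- Reduce(intersect, fa)
  candidates <- sort(setdiff(in_all_a, b_union))
  structure(list(
    a_union = a_union, b_union = b_union, shared = shared, a_only = a_only,
    candidates = candidates,
    scores = cumulative_scores(runs_a, min_unique_peptides),
    counts = c(a_union = length(a_union), b_union = length(b_union),
               shared = length(shared), a_only = length(a_only),
               candidates = length(candidates))
  ), class = "interactome_comparison")
}

#' @export
print.interactome_comparison <- function(x, ...) {
  cat("Interactome comparison\n")
  cat(sprintf("  group A union: %d\n  group B union: %d\n  shared: %d\n",
              x$counts[["a_union"]], x$counts[["b_union"]],
              x$counts[["shared"]]))
  cat(sprintf("  A only: %d\n  candidates (all A runs, absent from B): %d\n",
              x$counts[["a_only"]], x$counts[["candidates"]]))
  invisible(x)
}

#' Rank candidate tumour-specific interactors
#'
#' Candidates (present in every group-A run, absent from group B) ranked by
#' descending cumulative Mascot score; ties broken lexicographically by
#' accession.
#'
#' @param comparison An [compare_groups()] result.
#' @return Data frame with `accession` and `cumulative_score`.
#' @export
nominate_candidates <- function(comparison) {
  stopifnot(inherits(comparison, "interactome_comparison"))
  acc <- comparison$candidates
  score <- comparison$scores[acc]
  score[is.na(score)] <- 0
  ord <- order(-score, acc)
  data.frame(accession = acc[ord], cumulative_score = as.numeric(score[ord]),
             row.names = NULL)
}
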