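# k-mer presence counting and Fisher-exact enrichment of peak sequence sets.
#
# "Frequency" here is per-sequence presence (does the sequence contain the
# k-mer at least once), not occurrence counts: presence avoids confounding
# by sequence length. ChIP peaks are unstranded, so a k-mer and its reverse
# complement are pooled under the lexicographically smaller (canonical) key
# by default.

#' Extract peak sequences from a genome
#'
#' Uppercased sequence per interval; minus-strand intervals are
#' reverse-complemented. Out-of-bounds intervals raise an error.
#'
#' @param intervals `GRanges`.
#' @param genome `DNAStringSet` keyed by chromosome name.
#' @return A `DNAStringSet`, one sequence per interval.
#' @export
extract_sequences <- function(intervals, genome) {
  chroms <- as.character(seqnames(intervals))
  bad <- !chroms %in% names(genome)
  if (any(bad)) stop("unknown chromosome(s): ",
                     paste(unique(chroms[bad]), collapse = ", "))
  lens <- Biostrings::width(genome)[match(chroms, names(genome))]
  if (any(start(intervals) < 1L) || any(end(intervals) > lens)) {
    stop("interval(s) out of genome bounds")
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(intervals), function(i) {
    s <- Biostrings::subseq(genome[[chroms[i]]], start(intervals)[i],
                            end(intervals)[i])
    if (as.character(strand(intervals)[i]) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    s
  }))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Canonical (strand-collapsed) form of k-mers
#'
#' @param kmers Character vector over the A/C/G/T alphabet.
#' @return The lexicographically smaller of each k-mer and its reverse
#'   complement.
#' @export
canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

#' Count per-sequence k-mer presence
#'
#' For each k-mer, the number of sequences containing at least one
#' occurrence (overlapping windows within one sequence count once). k-mers
#' containing N (or any non-ACGT base) are skipped. With `canonical = TRUE`
#' a k-mer and its reverse complement are pooled.
#'
#' @param seqs `DNAStringSet` or character vector of sequences.
#' @param k Motif length (default 6).
#' @param canonical Pool reverse complements (default TRUE).
#' @return A list of class `kmer_presence` with `k`, `canonical`,
#'   `n_sequences` and named integer vector `counts`.
#' @export
count_kmer_presence <- function(seqs, k = 6, canonical = TRUE) {
  stopifnot(k >= 1, length(seqs) > 0)
  seqs <- toupper(as.character(seqs))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, seq_len(n - k + 1L),
                              seq_len(n - k + 1L) + k - 1L))
    kmers <- kmers[grepl("^[ACGT]+$", kmers)]
    if (!length(kmers)) next
    if (canonical) kmers <- unique(canonical_kmer(kmers))
    for (km in kmers) {
      counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
    }
  }
  keys <- sort(ls(counts))
  vals <- vapply(keys, function(x) counts[[x]], integer(1))
  structure(list(k = as.integer(k), canonical = canonical,
                 n_sequences = length(seqs),
                 counts = stats::setNames(vals, keys)),
            class = "kmer_presence")
}

#' Fisher-exact k-mer enrichment of a foreground against a background
#'
#' For each k-mer present in either set, builds the 2x2 table
#' `[fg_with, fg_without; bg_with, bg_without]` and computes the one-sided
#' (greater) Fisher exact p-value via the hypergeometric tail. The odds
#' ratio uses a 0.5 Haldane correction when any cell is zero. Significance
#' is flagged at raw `p < alpha`; Benjamini-Hochberg adjusted p-values are
#' reported alongside.
#'
#' @param fg,bg [count_kmer_presence()] results with identical `k` and
#'   `canonical` settings.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param background_label Label recorded in the output (default
#'   `"all_peaks"`).
#' @return Data frame, one row per k-mer, ordered by p-value then k-mer:
#'   `kmer, fg_with, fg_without, bg_with, bg_without, odds_ratio, p_value,
#'   p_adj, significant, background_label`.
#' @export
fisher_enrichment <- function(fg, bg, alpha = 0.05,
                              background_label = "all_peaks") {
  stopifnot(inherits(fg, "kmer_presence"), inherits(bg, "kmer_presence"))
  if (fg$k != bg$k || fg$canonical != bg$canonical) {
    stop("foreground and background must share k and canonical settings")
  }
  kmers <- sort(union(names(fg$counts), names(bg$counts)))
  a <- unname(ifelse(is.na(fg$counts[kmers]), 0L, fg$counts[kmers]))
  c_ <- unname(ifelse(is.na(bg$counts[kmers]), 0L, bg$counts[kmers]))
  b <- fg$n_sequences - a
  d <- bg$n_sequences - c_
  # one-sided Fisher (greater) == hypergeometric upper tail
  p <- stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  h <- ifelse(zero, 0.5, 0)
  or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  res <- data.frame(kmer = kmers, fg_with = a, fg_without = b,
                    bg_with = c_, bg_without = d,
                    odds_ratio = or, p_value = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    significant = p < alpha,
                    background_label = background_label,
                    row.names = NULL)
  res[order(res$p_value, res$kmer), , drop = FALSE]
}

#' Enrichment against two backgrounds, with a robustness flag
#'
#' Runs [fisher_enrichment()] of the foreground against the all-peaks
#' background and against the upstream-regions (promoter) background, and
#' flags k-mers significant in both as `robust`.
#'
#' @param fg Foreground [count_kmer_presence()].
#' @param bg_all_peaks,bg_upstream The two backgrounds.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per k-mer per background plus a logical
#'   `robust` column.
#' @export
dual_background_report <- function(fg, bg_all_peaks, bg_upstream,
                                   alpha = 0.05) {
  r1 <- fisher_enrichment(fg, bg_all_peaks, alpha, "all_peaks")
  r2 <- fisher_enrichment(fg, bg_upstream, alpha, "upstream_regions")
  sig_both <- intersect(r1$kmer[r1$significant], r2$kmer[r2$significant])
  out <- rbind(r1, r2)
  out$robust <- out$kmer %in% sig_both
  rownames(out) <- NULL
  out
}

#' Export significant k-mers in MEME minimal motif format
#'
#' Each significant k-mer becomes a one-hot position weight matrix (for
#' downstream matching against known TF motif databases).
#'
#' @param results A [fisher_enrichment()] result.
#' @param path Output path.
#' @param background Background base frequencies (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(results, path,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  sig <- results[results$significant, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", names(background), background),
                     collapse = " "), ""), con)
  for (i in seq_len(nrow(sig))) {
    km <- sig$kmer[i]
    writeLines(sprintf("MOTIF %s", km), con)
    writeLines(sprintf(
      "letter-probability matrix: alphlen= 4 w= %d nsites= %d E= %.3g",
      nchar(km), sig$fg_with[i], sig$p_value[i]), con)
    for (ch in strsplit(km, "")[[1]]) {
      row <- stats::setNames(rep(0.001, 4), c("A", "C", "G", "T"))
      row[ch] <- 0.997
      writeLines(paste(sprintf("%.3f", row), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
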