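#' @import methods
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   promoters pintersect findOverlaps coverage trim mcols mcols<- strand<-
#' @importFrom IRanges IRanges Views viewSums subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqnames<-
NULL

# Interval conventions: GRanges, 1-based closed, throughout. BED and bedGraph
# are 0-based half-open on disk; rtracklayer converts on read/write, so a BED
# record chr1 100 200 becomes GRanges chr1:101-200 and round-trips verbatim.

#' Read a BED3/BED6 file of genomic intervals
#'
#' Thin validating wrapper around [rtracklayer::import()]. Each record must
#' have at least three tab-separated fields with `0 <= start < end`; columns
#' 4-6, when present, populate `name`, `score` and `strand`.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] (1-based closed coordinates).
#' @export
read_bed <- function(path) {
  .validate_interval_file(path, min_fields = 3L)
  rtracklayer::import(path, format = "BED")
}

#' Write intervals to BED
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Shared line-level validation for BED-family files: rtracklayer's errors do
# not name offending lines, which matters for synthetic-data debugging.
.validate_interval_file <- function(path, min_fields) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < min_fields) {
      stop("malformed line ", i, " in ", path, ": expected >= ", min_fields,
           " tab-separated fields, got ", length(f))
    }
    s <- suppressWarnings(as.numeric(f[[2L]]))
    e <- suppressWarnings(as.numeric(f[[3L]]))
    if (is.na(s) || is.na(e)) {
      stop("malformed line ", i, " in ", path, ": non-numeric coordinates")
    }
    if (s < 0 || s >= e) {
      stop("invalid interval at line ", i, " in ", path,
           ": require 0 <= start < end, got [", s, ", ", e, ")")
    }
  }
  invisible(TRUE)
}

#' Read a 4-column bedGraph coverage track
#'
#' Runs must not overlap; uncovered bases are implicitly depth 0. Adjacent
#' equal-depth runs may be coalesced by the run-length encoding; total
#' coverage mass (sum of depth x length) is conserved.
#'
#' @param path Path to a bedGraph file.
#' @param seqlengths Optional named integer vector of chromosome lengths; when
#'   supplied the returned coverage extends to these lengths.
#' @return A per-chromosome [S4Vectors::Rle] list of depths
#'   (`SimpleRleList`).
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  .validate_interval_file(path, min_fields = 4L)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && any(gr$score < 0)) stop("negative depth in ", path)
  if (!GenomicRanges::isDisjoint(gr)) {
    stop("overlapping coverage runs in ", path)
  }
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- union(seqlevels(gr), names(seqlengths))
    seqlengths(gr)[names(seqlengths)] <- seqlengths
  }
  if (!length(gr)) return(coverage(gr))
  coverage(gr, weight = gr$score)
}

#' Write a coverage track to bedGraph
#'
#' Zero-depth runs are omitted, matching the implicit-zero convention.
#'
#' @param cov An `RleList` of per-chromosome depths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  gr <- as(cov, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Total coverage mass of a track
#'
#' Sum of depth times run length over all chromosomes; invariant across
#' read/merge/write round trips.
#'
#' @param cov An `RleList` of depths.
#' @return A single number.
#' @export
coverage_mass <- function(cov) {
  sum(vapply(cov, function(r) sum(as.numeric(runValue(r)) * runLength(r)),
             numeric(1)))
}

#' Read gene models from a TSV table or GFF3 subset
#'
#' The TSV format has columns `gene_id, name, chrom, start, end, strand,
#' biotype` with 1-based closed coordinates (GFF convention). GFF3 input is
#' parsed by [rtracklayer::import()] and restricted to `gene` features, with
#' `ID` and `biotype`/`gene_biotype` attributes.
#'
#' The transcription start site is the 5' end: `start` on `+`, `end` on `-`.
#'
#' @param path Path to the gene table.
#' @param format `"tsv"` or `"gff3"`.
#' @return A `GRanges` with metadata columns `gene_id`, `name`, `biotype` and
#'   a computed `tss` position.
#' @export
read_gene_models <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "name", "chrom", "start", "end", "strand", "biotype")
    if (!all(need %in% names(tab))) {
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    }
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand,
                  gene_id = tab$gene_id, name = tab$name,
                  biotype = tab$biotype)
  } else {
    g <- rtracklayer::import(path, format = "gff3")
    g <- g[g$type == "gene"]
    bio <- if ("biotype" %in% names(mcols(g))) g$biotype else
      if ("gene_biotype" %in% names(mcols(g))) g$gene_biotype else
        rep("protein_coding", length(g))
    gr <- GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g),
                  gene_id = g$ID,
                  name = if ("Name" %in% names(mcols(g))) g$Name else g$ID,
                  biotype = bio)
  }
  if (any(width(gr) < 1)) stop("gene with non-positive width")
  gr$tss <- gene_tss(gr)
  gr
}

#' Write gene models to the TSV format consumed by [read_gene_models()]
#' @param genes Gene `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  tab <- data.frame(gene_id = genes$gene_id, name = genes$name,
                    chrom = as.character(seqnames(genes)),
                    start = start(genes), end = end(genes),
                    strand = as.character(strand(genes)),
                    biotype = genes$biotype)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcription start sites of gene models
#' @param genes Gene `GRanges`.
#' @return Integer vector of TSS positions (1-based).
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Promoter regions upstream of protein-coding gene TSS
#'
#' The promoter is the `width_bp` region strictly upstream of the TSS
#' (excluding the TSS base itself), clipped at chromosome bounds.
#' Non-protein-coding genes are dropped, not errored.
#'
#' @param genes Gene `GRanges` with a `biotype` column.
#' @param width_bp Promoter width in bp upstream of the TSS (default 2000).
#' @return A `GRanges` of promoters carrying the source `gene_id`.
#' @export
promoter_of <- function(genes, width_bp = 2000) {
  stopifnot(width_bp > 0)
  keep <- genes$biotype == "protein_coding"
  g <- genes[keep]
  p <- suppressWarnings(promoters(g, upstream = width_bp, downstream = 0))
  # clip at chromosome edges rather than reject (small genomes hit them often)
  s <- pmax(start(p), 1L)
  e <- end(p)
  sl <- seqlengths(p)[as.character(seqnames(p))]
  e <- ifelse(is.na(sl), e, pmin(e, sl))
  keep <- s <= e
  p <- p[keep]
  GenomicRanges::ranges(p) <- IRanges(s[keep], e[keep])
  p
}

#' Fraction of interval `a` covered by interval `b`
#'
#' Asymmetric by design: `|a intersect b| / |a|`, zero when the intervals lie
#' on different chromosomes. Vectorised over pairs.
#'
#' @param a,b Parallel `GRanges` of equal length.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ifelse(same, ov / width(a), 0)
}

#' Midpoint of genomic intervals
#'
#' Even-length intervals floor to the lower central base, a deterministic
#' tie-break used by the consensus peak-matching rule.
#'
#' @param gr A `GRanges`.
#' @return Integer vector of midpoint positions (1-based).
#' @export
midpoint <- function(gr) {
  as.integer(floor((start(gr) + end(gr)) / 2))
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome to FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
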