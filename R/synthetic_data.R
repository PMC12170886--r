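# Seeded synthetic-data generator.
#
# Produces every input the pipeline consumes -- genome FASTA, gene models,
# feature tracks, per-sample peak BEDs and coverage bedGraphs for the
# 2-IP x 3-shRNA ChIP design and 3-sample ATAC design, DE tables with a
# planted quadrant structure, bait/IgG interactome hit tables with a planted
# all-A-runs candidate, and multi-cycle SPR sensorgrams from the 1:1 model --
# together with the planted ground truth used by the truth-recovery tests.
#
# Coverage is simulated directly as expected fragment pileup: each planted
# locus contributes a stepped-triangle depth profile whose total per-base
# mass equals amplitude x read_length exactly, so read-length-scaled
# quantification recovers the planted amplitude. Noise models: lognormal
# multiplicative on amplitudes, Gaussian additive (RU) on sensorgrams.

#' Default synthetic-study configuration
#'
#' Defaults encode the study design this generator emulates: two bait IPs
#' (proteins A and B) under control/A-knockdown/B-knockdown shRNA, three
#' ATAC samples, 8 tumour-group and 2 reference-group bait-IP runs, a
#' 600 s / 300 s SPR cycle with an 8-point 1:3 dilution series, and a DE
#' overlap plan of 237 co-up + 130 co-down + 1 discordant shared genes with
#' per-knockdown totals 624 and 820, of which 40 + 38 lie near shared
#' binding sites.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param ... Named overrides of any nested default (lists are merged).
#' @return A nested configuration list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(
      n_chroms = 2L, chrom_len = 1000000L, gc_background = 0.45,
      n_genes = 200L, gene_width = 4000L, frac_protein_coding = 0.95,
      n_enhancers = 50L, enhancer_width = 500L,
      n_cpg_islands = 50L, cpg_width = 300L,
      n_tfbs = 200L, tfbs_width = 12L,
      n_ctcf = 60L, ctcf_width = 200L),
    peaks = list(
      n_shared_promoter = 78L, n_shared_distal = 22L,
      n_a_specific = 80L, n_b_specific = 40L, n_stable = 250L,
      peak_width = 400L, read_length = 100L,
      amplitude_meanlog = log(200), amplitude_sdlog = 0.25,
      reduction = 0.4, noise_sdlog = 0.05, jitter_bp = 30L,
      sample_scale_sdlog = 0.2,
      atac_amplitude_meanlog = log(100), atac_reduction = 0.4),
    motif = list(planted = "GCCGCC", planting_rate = 0.8),
    de = list(
      n_co_up = 237L, n_co_down = 130L, n_discordant = 1L,
      n_a_only_up = 158L, n_a_only_down = 98L,
      n_b_only_up = 266L, n_b_only_down = 186L,
      n_null = 800L, effect_meanlog = 0.3, effect_sdlog = 0.4,
      correlation_target = 0.95, alpha = 0.05,
      n_intersect_up = 40L, n_intersect_down = 38L),
    interactome = list(
      n_runs_a = 8L, n_runs_b = 2L, group_a = "TNBC", group_b = "BCELL",
      planted_accession = "CAND0001", planted_gene = "CandidateX",
      n_background = 300L, inclusion_prob = 0.6,
      n_contaminants = 40L),
    spr = list(
      ka = 1e4, kd = 8.7e-3, rmax = 250, noise_sd = 1,
      top_nM = 5737.5, dilution_factor = 3, n_points = 8L,
      assoc_s = 600, diss_s = 300, hz = 1,
      drift_ru_per_s = 0.01, bulk_ru = 20, artefact_ru = 2))
  over <- list(...)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, over)
  stopifnot(cfg$peaks$reduction > 0, cfg$peaks$reduction <= 1)
  if (abs(cfg$de$correlation_target) >= 1) {
    stop("correlation_target must be inside (-1, 1)")
  }
  structure(cfg, class = "sim_config")
}

.rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Non-overlapping random intervals of a given width on the simulated genome.
.place_intervals <- function(n, width, chrom_lens, occupied = NULL,
                             min_gap = 100L, max_tries = 50L) {
  empty <- GRanges()
  seqlevels(empty) <- names(chrom_lens)
  seqlengths(empty) <- chrom_lens
  if (n == 0L) return(empty)
  out <- empty
  taken <- if (is.null(occupied) || !length(occupied)) empty else occupied
  for (tries in seq_len(max_tries)) {
    need <- n - length(out)
    if (need <= 0L) break
    ch <- sample(names(chrom_lens), need, replace = TRUE)
    st <- vapply(ch, function(c_) {
      sample.int(chrom_lens[[c_]] - width - 2000L, 1L) + 1000L
    }, integer(1))
    cand <- GRanges(ch, IRanges(st, width = width))
    seqlevels(cand) <- names(chrom_lens)
    seqlengths(cand) <- chrom_lens
    cand <- cand[!IRanges::overlapsAny(cand + min_gap, taken)]
    # drop mutual overlaps within the candidate batch
    if (length(cand) > 1) {
      keep <- rep(TRUE, length(cand))
      h <- findOverlaps(cand + min_gap, drop.self = TRUE,
                        drop.redundant = TRUE)
      keep[subjectHits(h)] <- FALSE
      cand <- cand[keep]
    }
    if (length(cand) > need) cand <- cand[seq_len(need)]
    out <- c(out, cand)
    taken <- c(taken, cand)
  }
  if (length(out) < n) stop("could not place ", n, " intervals without ",
                            "overlap; genome too small")
  out
}

#' Simulate a genome with gene models and feature tracks
#'
#' Random nucleotide sequence at the configured GC background, genes tiled
#' with regular spacing and alternating strand, three exons per gene, and
#' enhancer/CpG-island/TFBS/CTCF tracks placed uniformly at the configured
#' counts. Exon/intron/promoter/UTR tracks are derived from the gene
#' models.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genes.tsv` and one BED per feature track.
#' @return List with `genome` (`DNAStringSet`), `genes` (`GRanges`),
#'   `feature_tracks` (named list of `GRanges`) and `chrom_lens`.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  g <- config$genome
  set.seed(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(g$n_chroms))
  chrom_lens <- stats::setNames(rep(g$chrom_len, g$n_chroms), chrom_names)
  genome <- Biostrings::DNAStringSet(
    vapply(chrom_names, function(ch) .rand_seq(g$chrom_len, g$gc_background),
           character(1)))
  names(genome) <- chrom_names

  genes <- GRanges()
  if (g$n_genes > 0L) {
    per_chrom <- ceiling(g$n_genes / g$n_chroms)
    spacing <- floor((g$chrom_len - 20000L) / per_chrom)
    if (spacing < g$gene_width + 5000L) {
      stop("genome too small for ", g$n_genes, " genes")
    }
    rows <- list()
    k <- 0L
    for (ch in chrom_names) {
      for (i in seq_len(per_chrom)) {
        if (k >= g$n_genes) break
        k <- k + 1L
        st <- 10000L + (i - 1L) * spacing
        rows[[k]] <- data.frame(
          gene_id = sprintf("G%04d", k), name = sprintf("Gene%04d", k),
          chrom = ch, start = st, end = st + g$gene_width - 1L,
          strand = if (k %% 2L == 0L) "-" else "+")
      }
    }
    tab <- do.call(rbind, rows)
    bio <- rep("protein_coding", nrow(tab))
    n_nc <- round((1 - g$frac_protein_coding) * nrow(tab))
    if (n_nc > 0) bio[sample.int(nrow(tab), n_nc)] <- "lincRNA"
    genes <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                     strand = tab$strand, gene_id = tab$gene_id,
                     name = tab$name, biotype = bio)
    seqlevels(genes) <- chrom_names
    seqlengths(genes) <- chrom_lens
    genes$tss <- gene_tss(genes)
  }

  # exon/intron structure: three exons at fixed relative offsets
  w <- g$gene_width
  exon_off <- rbind(c(0, 0.2), c(0.4, 0.6), c(0.8, 1.0))
  exons <- GRanges(); introns <- GRanges(); utr5 <- GRanges(); utr3 <- GRanges()
  if (length(genes)) {
    ex <- do.call(c, lapply(seq_len(nrow(exon_off)), function(j) {
      GRanges(seqnames(genes),
              IRanges(start(genes) + round(exon_off[j, 1] * (w - 1)),
                      start(genes) + round(exon_off[j, 2] * (w - 1))))
    }))
    exons <- GenomicRanges::reduce(ex)
    introns <- GenomicRanges::setdiff(
      GRanges(seqnames(genes), IRanges(start(genes), end(genes))), exons)
    plus <- as.character(strand(genes)) == "+"
    utr5 <- GRanges(seqnames(genes),
                    IRanges(ifelse(plus, start(genes), end(genes) - 199L),
                            ifelse(plus, start(genes) + 199L, end(genes))))
    utr3 <- GRanges(seqnames(genes),
                    IRanges(ifelse(plus, end(genes) - 199L, start(genes)),
                            ifelse(plus, end(genes), start(genes) + 199L)))
  }
  occupied <- GRanges()
  seqlevels(occupied) <- chrom_names
  seqlengths(occupied) <- chrom_lens
  if (length(genes)) {
    occupied <- GRanges(seqnames(genes),
                        IRanges(pmax(start(genes) - 3000L, 1L), end(genes)),
                        seqlengths = chrom_lens)
  }
  enh <- .place_intervals(g$n_enhancers, g$enhancer_width, chrom_lens,
                          occupied)
  cpg <- .place_intervals(g$n_cpg_islands, g$cpg_width, chrom_lens,
                          c(occupied, enh))
  tfbs <- .place_intervals(g$n_tfbs, g$tfbs_width, chrom_lens,
                           c(occupied, enh, cpg))
  ctcf <- .place_intervals(g$n_ctcf, g$ctcf_width, chrom_lens,
                           c(occupied, enh, cpg, tfbs))
  tracks <- list(exon = exons, intron = introns, utr5 = utr5, utr3 = utr3,
                 promoter = if (length(genes)) promoter_of(genes) else
                   GRanges(),
                 enhancer = enh, cpg_island = cpg, tfbs = tfbs, ctcf = ctcf)
  res <- list(genome = genome, genes = genes, feature_tracks = tracks,
              chrom_lens = chrom_lens)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(out_dir, "genome.fa"))
    if (length(genes)) write_gene_models(genes, file.path(out_dir,
                                                          "genes.tsv"))
    for (nm in names(tracks)) {
      if (length(tracks[[nm]])) {
        write_bed(tracks[[nm]], file.path(out_dir, paste0(nm, ".bed")))
      }
    }
  }
  res
}

# Stepped-triangle depth profile per peak: L nested rectangles whose total
# mass is exactly amplitude x read_length (unique maximum at the centre).
.coverage_from_loci <- function(loci_df, chrom_lens, read_length,
                                levels = 8L) {
  n <- nrow(loci_df)
  hw <- lapply(seq_len(n), function(i) {
    round(loci_df$width[i] * (levels:1) / levels / 2)
  })
  hw <- matrix(unlist(hw), nrow = levels)
  mass_units <- colSums(2 * hw + 1)
  h <- rep(loci_df$amplitude * read_length / mass_units, each = levels)
  centers <- rep(loci_df$center, each = levels)
  chroms <- rep(loci_df$chrom, each = levels)
  segs <- GRanges(chroms, IRanges(centers - as.vector(hw),
                                  centers + as.vector(hw)))
  seqlevels(segs) <- names(chrom_lens)
  seqlengths(segs) <- chrom_lens
  coverage(segs, weight = h)
}

#' Simulate the ChIP and ATAC peak experiment with planted truth
#'
#' Plants five locus classes: shared co-dependent peaks at the promoters of
#' designated genes plus distal shared peaks (both IPs reduced under either
#' knockdown), A-specific peaks (IP-A signal reduced only under A
#' knockdown), B-specific peaks (symmetric), and stable background peaks.
#' ATAC accessibility at the shared promoters is reduced only under the B
#' knockdown. A GC-rich 6-mer is written into the genome sequence at shared
#' loci at the configured planting rate.
#'
#' @param config A [sim_config()].
#' @param genome_sim A [simulate_genome()] result.
#' @param out_dir Optional directory for per-sample BED/bedGraph files and
#'   the motif-planted `genome.fa`.
#' @return List with `chip` (`$peaks`, `$coverages` per sample), `atac`
#'   (idem), `genome` (motif-planted `DNAStringSet`), `truth` (locus
#'   classes, intersection genes, motif flags) and `samples`.
#' @export
simulate_peak_experiment <- function(config, genome_sim, out_dir = NULL) {
  p <- config$peaks
  set.seed(config$seed + 1L)
  genes <- genome_sim$genes
  chrom_lens <- genome_sim$chrom_lens
  genome <- genome_sim$genome

  pc <- genes[genes$biotype == "protein_coding"]
  if (length(pc) < p$n_shared_promoter) {
    stop("not enough protein-coding genes for shared promoter peaks")
  }
  host <- sort(sample(seq_along(pc), p$n_shared_promoter))
  host_genes <- pc[host]
  prom <- promoter_of(host_genes)
  shared_prom_centers <- midpoint(prom)
  shared_prom <- data.frame(chrom = as.character(seqnames(prom)),
                            center = shared_prom_centers,
                            class = "shared", host_gene = host_genes$gene_id)

  # distal and background loci at deterministic intergenic slots: two per
  # gene, far enough from every gene that a 1 kb flank never pairs them
  n_free <- p$n_shared_distal + p$n_a_specific + p$n_b_specific + p$n_stable
  slot_chrom <- rep(as.character(seqnames(genes)), each = 2L)
  slot_center <- as.vector(rbind(end(genes) + 2600L, end(genes) + 4200L))
  ok <- slot_center + p$peak_width < chrom_lens[slot_chrom] - 1000L
  slot_chrom <- slot_chrom[ok]; slot_center <- slot_center[ok]
  if (length(slot_center) < n_free) {
    stop("genome too small: ", n_free, " intergenic loci requested, ",
         length(slot_center), " slots available")
  }
  pick <- sort(sample.int(length(slot_center), n_free))
  pick <- pick[sample.int(n_free)]
  cls <- c(rep("shared", p$n_shared_distal),
           rep("A_specific", p$n_a_specific),
           rep("B_specific", p$n_b_specific),
           rep("unchanged", p$n_stable))
  free_df <- data.frame(chrom = slot_chrom[pick],
                        center = slot_center[pick], class = cls,
                        host_gene = NA_character_)
  loci <- rbind(shared_prom, free_df)
  loci <- loci[order(loci$chrom, loci$center), ]
  rownames(loci) <- NULL
  loci$locus_id <- sprintf("locus_%04d", seq_len(nrow(loci)))
  loci$width <- p$peak_width
  loci$base_amplitude <- stats::rlnorm(nrow(loci), p$amplitude_meanlog,
                                       p$amplitude_sdlog)

  # plant the GC-rich motif into shared-locus genome sequence
  is_shared <- loci$class == "shared"
  plant <- is_shared & stats::runif(nrow(loci)) < config$motif$planting_rate
  motif <- config$motif$planted
  if (any(plant)) {
    pos <- loci$center[plant] + sample.int(100L, sum(plant),
                                           replace = TRUE) - 50L
    for (ch in unique(loci$chrom[plant])) {
      sel <- loci$chrom[plant] == ch
      chrom_seq <- as.character(genome[[ch]])
      for (p_ in pos[sel]) {
        substr(chrom_seq, p_, p_ + nchar(motif) - 1L) <- motif
      }
      genome[[ch]] <- Biostrings::DNAString(chrom_seq)
    }
  }
  loci$motif_planted <- plant

  chip_samples <- c("ipA_ctrl", "ipA_kdA", "ipA_kdB",
                    "ipB_ctrl", "ipB_kdA", "ipB_kdB")
  cond_of <- c(ipA_ctrl = "ctrl", ipA_kdA = "kdA", ipA_kdB = "kdB",
               ipB_ctrl = "ctrl", ipB_kdA = "kdA", ipB_kdB = "kdB")
  ip_of <- c(ipA_ctrl = "A", ipA_kdA = "A", ipA_kdB = "A",
             ipB_ctrl = "B", ipB_kdA = "B", ipB_kdB = "B")
  class_factor <- function(class, ip, cond, reduction) {
    f <- rep(1, length(class))
    f[class == "shared" & cond != "ctrl"] <- reduction
    f[class == "A_specific" & ip == "A" & cond == "kdA"] <- reduction
    f[class == "B_specific" & ip == "B" & cond == "kdB"] <- reduction
    f
  }
  scale_f <- stats::setNames(
    stats::rlnorm(length(chip_samples), 0, p$sample_scale_sdlog),
    chip_samples)
  chip_peaks <- list(); chip_cov <- list()
  for (s in chip_samples) {
    fac <- class_factor(loci$class, ip_of[[s]], cond_of[[s]], p$reduction)
    noise <- if (p$noise_sdlog > 0) {
      stats::rlnorm(nrow(loci), 0, p$noise_sdlog)
    } else rep(1, nrow(loci))
    amp <- loci$base_amplitude * fac * noise * scale_f[[s]]
    jit <- if (p$jitter_bp > 0) {
      sample.int(2L * p$jitter_bp + 1L, nrow(loci), replace = TRUE) -
        p$jitter_bp - 1L
    } else rep(0L, nrow(loci))
    df <- data.frame(chrom = loci$chrom, center = loci$center + jit,
                     width = loci$width, amplitude = amp)
    chip_cov[[s]] <- .coverage_from_loci(df, chrom_lens, p$read_length)
    gr <- GRanges(df$chrom, IRanges(df$center - loci$width %/% 2L,
                                    df$center + loci$width %/% 2L))
    seqlevels(gr) <- names(chrom_lens); seqlengths(gr) <- chrom_lens
    chip_peaks[[s]] <- sort(gr)
  }

  # ATAC: accessibility peaks at every protein-coding promoter plus the
  # intergenic loci (generic accessible sites); shared promoters lose
  # accessibility only under the B knockdown
  atac_samples <- c("atac_ctrl", "atac_kdA", "atac_kdB")
  aprom <- promoter_of(pc)
  atac_loci <- rbind(
    data.frame(chrom = as.character(seqnames(aprom)),
               center = midpoint(aprom), width = p$peak_width,
               gene_id = aprom$gene_id),
    data.frame(chrom = free_df$chrom, center = free_df$center,
               width = p$peak_width, gene_id = NA_character_))
  atac_loci <- atac_loci[order(atac_loci$chrom, atac_loci$center), ]
  rownames(atac_loci) <- NULL
  atac_loci$shared_promoter <- !is.na(atac_loci$gene_id) &
    atac_loci$gene_id %in% shared_prom$host_gene
  atac_loci$base_amplitude <- stats::rlnorm(nrow(atac_loci),
                                            p$atac_amplitude_meanlog,
                                            p$amplitude_sdlog)
  atac_peaks <- list(); atac_cov <- list()
  for (s in atac_samples) {
    fac <- ifelse(atac_loci$shared_promoter & s == "atac_kdB",
                  p$atac_reduction, 1)
    noise <- if (p$noise_sdlog > 0) {
      stats::rlnorm(nrow(atac_loci), 0, p$noise_sdlog)
    } else rep(1, nrow(atac_loci))
    df <- data.frame(chrom = atac_loci$chrom, center = atac_loci$center,
                     width = atac_loci$width,
                     amplitude = atac_loci$base_amplitude * fac * noise)
    atac_cov[[s]] <- .coverage_from_loci(df, chrom_lens, p$read_length)
    gr <- GRanges(df$chrom, IRanges(df$center - p$peak_width %/% 2L,
                                    df$center + p$peak_width %/% 2L))
    seqlevels(gr) <- names(chrom_lens); seqlengths(gr) <- chrom_lens
    atac_peaks[[s]] <- sort(gr)
  }

  truth <- list(loci = loci,
                intersection_genes = shared_prom$host_gene,
                atac = atac_loci)
  res <- list(chip = list(peaks = chip_peaks, coverages = chip_cov,
                          samples = chip_samples, condition = cond_of,
                          ip = ip_of, read_length = p$read_length),
              atac = list(peaks = atac_peaks, coverages = atac_cov,
                          samples = atac_samples,
                          read_length = p$read_length),
              genome = genome, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(out_dir, "genome.fa"))
    for (s in chip_samples) {
      write_bed(chip_peaks[[s]], file.path(out_dir, paste0(s, ".bed")))
      write_bedgraph(chip_cov[[s]],
                     file.path(out_dir, paste0(s, ".bedgraph")))
    }
    for (s in atac_samples) {
      write_bed(atac_peaks[[s]], file.path(out_dir, paste0(s, ".bed")))
      write_bedgraph(atac_cov[[s]],
                     file.path(out_dir, paste0(s, ".bedgraph")))
    }
    utils::write.table(loci, file.path(out_dir, "truth_peak_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Simulate the two knockdown DE tables with a planted quadrant structure
#'
#' Shared genes receive a common effect plus independent per-knockdown
#' noise calibrated so the correlation of the two log2FC vectors over the
#' shared set matches the configured target; signs are clamped so planted
#' classes are recovered exactly at the configured alpha. Null genes get
#' near-zero effects and non-significant adjusted p-values.
#'
#' @param config A [sim_config()].
#' @param intersection_genes Optional character vector of genome gene ids
#'   near shared peaks; the first `n_intersect_up` become co-up and the next
#'   `n_intersect_down` co-down shared genes, tying the DE tables to the
#'   peak experiment.
#' @param out_dir Optional directory for `de_A.tsv`, `de_B.tsv` and the
#'   truth table.
#' @return List with `de_a`, `de_b` (data frames) and `truth`.
#' @export
simulate_de_tables <- function(config, intersection_genes = NULL,
                               out_dir = NULL) {
  d <- config$de
  set.seed(config$seed + 2L)
  n_shared <- d$n_co_up + d$n_co_down + d$n_discordant
  need_int <- d$n_intersect_up + d$n_intersect_down
  if (!is.null(intersection_genes) &&
      length(intersection_genes) < need_int) {
    stop("need at least ", need_int, " intersection genes")
  }
  ids_up <- sprintf("DEGU%04d", seq_len(d$n_co_up))
  ids_down <- sprintf("DEGD%04d", seq_len(d$n_co_down))
  if (!is.null(intersection_genes)) {
    ids_up[seq_len(d$n_intersect_up)] <-
      intersection_genes[seq_len(d$n_intersect_up)]
    ids_down[seq_len(d$n_intersect_down)] <-
      intersection_genes[d$n_intersect_up + seq_len(d$n_intersect_down)]
  }
  ids_disc <- if (d$n_discordant > 0) {
    sprintf("DEGX%04d", seq_len(d$n_discordant))
  } else character()

  sign_vec <- c(rep(1, d$n_co_up), rep(-1, d$n_co_down))
  m <- stats::rlnorm(n_shared, d$effect_meanlog, d$effect_sdlog)
  common <- c(m[seq_len(d$n_co_up + d$n_co_down)] * sign_vec,
              if (d$n_discordant > 0) {
                m[d$n_co_up + d$n_co_down + seq_len(d$n_discordant)]
              })
  rho <- d$correlation_target
  eps_sd <- if (rho > 0) stats::sd(common) * sqrt((1 - rho) / rho) else 0
  # clamp to the planted sign (minimum magnitude 0.02) so class recovery is
  # exact; the clamp rarely fires at the default noise level
  clamp <- function(x, s) s * pmax(s * x, 0.02)
  conc_idx <- seq_len(d$n_co_up + d$n_co_down)
  fa_shared <- common + stats::rnorm(n_shared, 0, eps_sd)
  fb_shared <- common + stats::rnorm(n_shared, 0, eps_sd)
  fa_shared[conc_idx] <- clamp(fa_shared[conc_idx], sign_vec)
  fb_shared[conc_idx] <- clamp(fb_shared[conc_idx], sign_vec)
  if (d$n_discordant > 0) {
    disc_idx <- d$n_co_up + d$n_co_down + seq_len(d$n_discordant)
    fa_shared[disc_idx] <- -abs(fa_shared[disc_idx])  # down in A
    fb_shared[disc_idx] <- abs(fb_shared[disc_idx])   # up in B
  }
  shared_ids <- c(ids_up, ids_down, ids_disc)

  mk_only <- function(prefix, n_up, n_down) {
    n <- n_up + n_down
    if (n == 0) return(NULL)
    data.frame(
      gene_id = sprintf("%s%04d", prefix, seq_len(n)),
      log2fc = c(stats::rlnorm(n_up, d$effect_meanlog, d$effect_sdlog),
                 -stats::rlnorm(n_down, d$effect_meanlog, d$effect_sdlog)),
      p_adj = stats::runif(n, 0, d$alpha / 10))
  }
  a_only <- mk_only("DEGA", d$n_a_only_up, d$n_a_only_down)
  b_only <- mk_only("DEGB", d$n_b_only_up, d$n_b_only_down)
  nulls <- data.frame(gene_id = sprintf("NULL%04d", seq_len(d$n_null)),
                      log2fc = stats::rnorm(d$n_null, 0, 0.1),
                      p_adj = stats::runif(d$n_null, 5 * d$alpha, 1))

  sig_p <- function(n) stats::runif(n, 0, d$alpha / 10)
  de_a <- rbind(
    data.frame(gene_id = shared_ids, log2fc = fa_shared,
               p_adj = sig_p(n_shared)),
    a_only,
    data.frame(gene_id = b_only$gene_id,
               log2fc = stats::rnorm(nrow(b_only), 0, 0.1),
               p_adj = stats::runif(nrow(b_only), 5 * d$alpha, 1)),
    nulls)
  de_b <- rbind(
    data.frame(gene_id = shared_ids, log2fc = fb_shared,
               p_adj = sig_p(n_shared)),
    data.frame(gene_id = a_only$gene_id,
               log2fc = stats::rnorm(nrow(a_only), 0, 0.1),
               p_adj = stats::runif(nrow(a_only), 5 * d$alpha, 1)),
    b_only,
    nulls)
  rownames(de_a) <- rownames(de_b) <- NULL
  truth <- list(co_up = ids_up, co_down = ids_down, discordant = ids_disc,
                a_only = a_only$gene_id, b_only = b_only$gene_id,
                intersect_up = if (!is.null(intersection_genes)) {
                  ids_up[seq_len(d$n_intersect_up)]
                } else character(),
                intersect_down = if (!is.null(intersection_genes)) {
                  ids_down[seq_len(d$n_intersect_down)]
                } else character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(de_a, file.path(out_dir, "de_A.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(de_b, file.path(out_dir, "de_B.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(de_a = de_a, de_b = de_b, truth = truth)
}

#' Simulate bait-IP interactome runs with a planted candidate
#'
#' The planted candidate appears in every group-A bait run (never in group
#' B nor in any IgG control); contaminants appear in both bait and IgG
#' lists of every run; background proteins are sampled per run. Any
#' background protein that would by chance satisfy the candidate rule is
#' deterministically removed from one group-A run, so the planted accession
#' is the unique candidate.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for per-run hit tables and a manifest.
#' @return List with `runs` (list of [rime_run()]), `truth`.
#' @export
simulate_interactome_runs <- function(config, out_dir = NULL) {
  ic <- config$interactome
  set.seed(config$seed + 3L)
  bg_acc <- sprintf("BG%05d", seq_len(ic$n_background))
  cont_acc <- sprintf("CONT%03d", seq_len(ic$n_contaminants))
  mk_hits <- function(acc, score_mean = 200) {
    n <- length(acc)
    data.frame(accession = acc, gene = paste0("gene_", acc),
               mascot_score = round(stats::rlnorm(n, log(score_mean), 0.6), 1),
               unique_peptides = 1L + stats::rpois(n, 3),
               coverage_pct = round(stats::runif(n, 1, 60), 1))
  }
  n_a <- ic$n_runs_a; n_b <- ic$n_runs_b
  inc_a <- matrix(stats::runif(n_a * ic$n_background) < ic$inclusion_prob,
                  nrow = ic$n_background)
  inc_b <- matrix(stats::runif(n_b * ic$n_background) < ic$inclusion_prob,
                  nrow = ic$n_background)
  # break accidental candidates: background proteins in all A runs but no B run
  accidental <- rowSums(inc_a) == n_a & rowSums(inc_b) == 0
  inc_a[accidental, 1L] <- FALSE
  runs <- list()
  for (i in seq_len(n_a)) {
    bait <- mk_hits(c(ic$planted_accession, bg_acc[inc_a[, i]], cont_acc))
    bait$gene[bait$accession == ic$planted_accession] <- ic$planted_gene
    igg <- mk_hits(cont_acc, score_mean = 120)
    runs[[length(runs) + 1L]] <- rime_run(
      sprintf("%s_run%d", ic$group_a, i), ic$group_a, bait, igg)
  }
  for (i in seq_len(n_b)) {
    bait <- mk_hits(c(bg_acc[inc_b[, i]], cont_acc))
    igg <- mk_hits(cont_acc, score_mean = 120)
    runs[[length(runs) + 1L]] <- rime_run(
      sprintf("%s_run%d", ic$group_b, i), ic$group_b, bait, igg)
  }
  truth <- list(planted_accession = ic$planted_accession,
                planted_gene = ic$planted_gene,
                contaminants = cont_acc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    man <- data.frame(run_id = character(), group = character(),
                      bait_path = character(), igg_path = character())
    for (r in runs) {
      bp <- paste0(r$run_id, "_bait.tsv"); gp <- paste0(r$run_id, "_igg.tsv")
      utils::write.table(r$bait_hits, file.path(out_dir, bp), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(r$igg_hits, file.path(out_dir, gp), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      man <- rbind(man, data.frame(run_id = r$run_id, group = r$group,
                                   bait_path = bp, igg_path = gp))
    }
    utils::write.table(man, file.path(out_dir, "run_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(runs = runs, truth = truth)
}

#' Simulate multi-cycle SPR sensorgrams from the 1:1 binding model
#'
#' One cycle per concentration of the configured dilution series plus a
#' zero-concentration blank. Active and reference flow cells share a linear
#' baseline drift and a bulk refractive-index jump during the injection;
#' the active cell additionally carries a small systematic injection
#' artefact that the blank cycle captures, so double referencing removes
#' all three. Gaussian noise of the configured sd is added to every trace.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for `sensorgrams.csv` and
#'   `cycle_manifest.tsv`.
#' @return List with `sensorgrams` (`$data`, `$manifest`) and `truth`
#'   (`kd_nM = kd/ka` in nM, plus `ka`, `kd`, `rmax`).
#' @export
simulate_sensorgrams <- function(config, out_dir = NULL) {
  sp <- config$spr
  stopifnot(sp$ka > 0, sp$kd > 0, sp$rmax > 0)
  set.seed(config$seed + 4L)
  conc <- sort(serial_dilution(sp$top_nM, sp$dilution_factor, sp$n_points))
  conc <- c(0, conc)
  pre_s <- 30
  t_all <- seq(0, pre_s + sp$assoc_s + sp$diss_s, by = 1 / sp$hz)
  rows <- list(); man <- list()
  for (i in seq_along(conc)) {
    cy <- sprintf("cycle%02d", i)
    C <- conc[i]
    assoc_sel <- t_all >= pre_s & t_all < pre_s + sp$assoc_s
    diss_sel <- t_all >= pre_s + sp$assoc_s
    sig <- numeric(length(t_all))
    if (C > 0) {
      sig[assoc_sel] <- binding_response(t_all[assoc_sel] - pre_s, C,
                                         sp$ka, sp$kd, sp$rmax)
      r_end <- binding_response(sp$assoc_s, C, sp$ka, sp$kd, sp$rmax)
      sig[diss_sel] <- binding_response(
        t_all[diss_sel] - pre_s - sp$assoc_s, C, sp$ka, sp$kd, sp$rmax,
        r0 = r_end, phase = "dissociation")
    }
    drift <- sp$drift_ru_per_s * t_all
    bulk <- ifelse(assoc_sel, sp$bulk_ru, 0)
    artefact <- ifelse(assoc_sel,
                       sp$artefact_ru * exp(-(t_all - pre_s) / 50), 0)
    noise <- function() if (sp$noise_sd > 0) {
      stats::rnorm(length(t_all), 0, sp$noise_sd)
    } else 0
    active <- sig + drift + bulk + artefact + noise()
    reference <- drift + bulk + noise()
    rows[[length(rows) + 1L]] <- data.frame(
      cycle_id = cy, flow_cell = "active", concentration_nM = C,
      time_s = t_all, response_RU = active)
    rows[[length(rows) + 1L]] <- data.frame(
      cycle_id = cy, flow_cell = "reference", concentration_nM = C,
      time_s = t_all, response_RU = reference)
    man[[length(man) + 1L]] <- data.frame(
      cycle_id = cy, type = if (C == 0) "blank" else "analyte",
      assoc_start_s = pre_s, assoc_end_s = pre_s + sp$assoc_s,
      diss_end_s = pre_s + sp$assoc_s + sp$diss_s)
  }
  dat <- do.call(rbind, rows)
  manifest <- do.call(rbind, man)
  truth <- list(kd_nM = sp$kd / sp$ka * 1e9, ka = sp$ka, kd = sp$kd,
                rmax = sp$rmax)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dat, file.path(out_dir, "sensorgrams.csv"),
                     row.names = FALSE)
    utils::write.table(manifest, file.path(out_dir, "cycle_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sensorgrams = list(data = dat, manifest = manifest), truth = truth)
}
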