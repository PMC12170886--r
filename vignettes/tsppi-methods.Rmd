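---
title: "Methods: tumour-specific interactome, peak co-dependency and binding analysis"
author: "tsppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour-specific interactome, peak co-dependency and binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsppi)
```

# Scope and data model

`tsppi` analyses the three experimental axes by which a tumour-specific
protein–protein interaction (TSPPI) is established and characterised:
differential bait-IP mass spectrometry across sample groups, genomic
co-dependency of the two partners' chromatin binding under reciprocal
knockdown, and direct biophysical binding by surface plasmon resonance
(SPR). Intervals live in `GRanges` (1-based closed; BED and bedGraph files
are converted on read/write by rtracklayer), coverage in run-length-encoded
per-chromosome vectors, genomes in `DNAStringSet`, and tabular data in plain
data frames read from TSV/CSV.

# Interactome comparison

Each bait-IP run carries a matched IgG isotype control. Filtering is
per-run: accessions present in the run's IgG list are subtracted, and
identifications with fewer than one unique peptide are discarded. Group
unions, the cross-group intersection and the group-A-only set are then pure
set algebra, so `|A_only| = |A_union| − |A ∩ B|` holds identically. The
candidate rule is intentionally strict — present in *every* filtered
tumour-group run, absent from *every* reference-group bait run — because a
TSPPI claim rests on reproducible presence, not on abundance. Cumulative
Mascot scores (summed over runs, absence contributing zero) order the
candidate table; ties break lexicographically so output is deterministic.
Protein identity is keyed on accession throughout; cross-species comparisons
should map accessions to symbols before building runs.

# Consensus peaks and co-dependency

**Matching rule.** Two peaks match when the midpoint of either falls within
the span of the other. This is stricter than mere overlap — a ~10% graze
does not match — and is applied transitively: connected components of the
match graph become single consensus peaks spanning the member extremes. The
midpoint of an even-length interval floors to the lower base, a documented
tie-break. `build_consensus` is verified against a brute-force O(n²)
pairwise oracle in the test suite.

**Amplitude.** The amplitude of a consensus peak in a sample is the summed
per-base depth over the consensus interval divided by the read length — an
estimated fragment count. This is the only dimensionally coherent reading of
"scaled on the read length", and it is isolated in `quantify` so an
alternative statistic could be swapped in.

**Signal/noise floor.** Amplitudes below 20 are floored to 20, and rows
floored in every sample are dropped as noise-only loci. Both actions are
recorded in the matrix provenance and can be disabled
(`drop_all_floored = FALSE`).

**Mode scaling.** Sample distributions are aligned by the mode of their
log2 amplitudes, estimated from a fixed-width histogram (bin 0.1, maximal
bin, ties to the lowest bin), each sample being multiplied by
`2^(mode_control − mode_sample)` for its own IP's control. The estimator is
deterministic and robust to the heavy right tail, but it is a *mode*
estimator: it assumes the majority of loci are unperturbed. Its stability
degrades when the log2 distribution is broad and flat-topped; the synthetic
generator's amplitude spread (sdlog 0.25) keeps the histogram peaked, which
is what a deeply sequenced, well-behaved library looks like after peak
calling.

**Disappearing peaks and classes.** A peak disappears in a contrast when
`log2(control/kd) ≥ 0.5`, boundary inclusive; the S/N floor guarantees
finite ratios. A peak is *reduced under a knockdown* when it disappears in
at least one IP under that knockdown. Classes: reduced under A only →
A-specific; B only → B-specific; both → shared (co-dependent); neither →
unchanged. Whether "reduced by either knockdown" should mean *both* (the
default here, matching the co-reduction the experiment demonstrates) or *at
least one* is genuinely open; `classify_codependency(policy = "either")`
implements the alternative reading (signal lost from both proteins' IPs
under any knockdown) so the choice is explicit rather than buried.

**Annotation and pairing.** Feature labels require ≥50% of the peak covered
by the feature track (inclusive). Gene pairing extends peaks by a flank on
both sides; two presets are provided because the source analyses used both
5 kb (methods-wide pairing) and ±1 kb (the stricter vicinity used for the
ChIP–RNA intersection). ATAC matrices are quantile normalised
(limma's order-statistic means, ties averaged) instead of mode-scaled, and
accessibility change is the same `log2(control/kd)`.

# Motif enrichment

Enrichment uses per-sequence *presence* of 6-mers, not occurrence counts:
presence is insensitive to peak length differences between foreground and
background. ChIP peaks are unstranded, so a 6-mer and its reverse complement
are pooled under the lexicographically smaller key (canonical form);
enrichment results are invariant to reverse-complementing all inputs, and
k-mers containing N are skipped. Each 2×2 table (foreground with/without ×
background with/without) gets a one-sided (greater) Fisher exact p — computed
as the hypergeometric upper tail and checked against an exhaustive
enumeration oracle to 10⁻¹² — an odds ratio with 0.5 Haldane correction when
any cell is zero, and a Benjamini–Hochberg adjusted p alongside the raw
`p < 0.05` significance flag. Two backgrounds are supported (all consensus
peaks; 2-kb upstream promoter regions), with a `robust` flag for k-mers
significant against both. Note that a one-sided Fisher p is not 1 when
foreground and background rates are equal — the upper tail includes the
observed table — so "no enrichment" is asserted through the odds ratio and
the significance flag, not through `p == 1`.

# DE overlap and integration

Significance is consumed, not computed: DE tables must carry adjusted
p-values (model fitting belongs to edgeR/DESeq2 upstream). Shared genes are
significant in both knockdowns at one shared alpha (0.05 default); the sign
quadrants are `co_down` (both log2FC < 0), `co_up` (both > 0) and
`discordant`. All log2FCs are knockdown-versus-control, so a `co_up` gene
*rises* when either protein is removed, i.e. the proteins repress it. The
trend over the shared set is ordinary least squares of B on A; with the
generator's shared-effect correlation target of 0.95 the expected R² is
≈0.90. The ChIP–RNA intersection takes shared DE genes paired (±1 kb) with
shared-class peaks and reports direction counts. `delta_delta_ct` implements
ΔCt = Ct_target − Ct_reference, ΔΔCt against the control-group mean, and
fold change `2^(−ΔΔCt)`.

# SPR steady-state analysis

Sensorgrams are long tables (cycle, flow cell, concentration, time,
response) with a cycle manifest for phase boundaries. Double referencing
subtracts the reference flow cell, then the reference-subtracted
zero-concentration blank cycle, then the pre-injection baseline; this
removes linear drift, bulk refractive-index jumps common to both cells, and
systematic injection artefacts carried by the blank. The steady-state
reading averages the last 5 s of the association phase and flags readings
still rising faster than 0.01 RU/s — for slow kinetics (small `ka·C + kd`)
the 600-s reading underestimates equilibrium monotonically, which the
closed-form `R(t) = Req(1 − e^{−(ka·C+kd)t})` makes explicit. The 1:1
isotherm `Req(C) = Rmax·C/(KD + C)` is fitted by bounded
Levenberg–Marquardt least squares (start: `Rmax₀ = 1.1·max(Req)`, `KD₀` at
the concentration nearest half-max; bounds `KD ≤ 100·Cmax`,
`Rmax ≤ 10·max(Req)`). Curvature-free data (responses proportional to
concentration) pin a parameter to its upper bound and are reported as
non-converged with the KD lower-bound censored. Because the
half-maximum reading is itself a common instrument convention, a model-free
`kd_half_max` (concentration interpolated at `Rmax/2` in log-concentration)
is reported beside the fitted KD; on clean 1:1 data the two coincide.
Inverse kinetic (ka, kd) fitting is deliberately not offered: the study
system's kinetics are too slow to constrain it, and the generator's forward
closed form covers simulation needs. Percent inhibition is
`100·(1 − with/alone)`, with negative values reported as enhancement.

# The synthetic study

The generator emulates the study design at desk scale: 2 chromosomes × 1 Mb
at GC 0.45; 200 genes (4 kb, three exons, alternating strand, ~9.8 kb
spacing); 470 binding loci — 78 shared co-dependent peaks at the promoters
of designated genes, 22 distal shared, 80 A-specific, 40 B-specific, 250
stable — with 400-bp stepped-triangle coverage profiles whose total mass
equals amplitude × read length exactly, ±30 bp per-sample interval jitter,
lognormal per-locus amplitudes (meanlog log 200, sdlog 0.25), per-sample
scale factors (sdlog 0.2) for the mode-scaler to remove, and multiplicative
per-sample noise (sdlog 0.05). Knockdown reduces affected amplitudes to 0.4
of baseline (log2FC 1.32, comfortably past the 0.5 threshold). The ChIP
design is 2 IPs × {control, A-KD, B-KD}; ATAC has three samples with
accessibility at shared promoters reduced only under the B knockdown. A
GC-rich 6-mer (canonical `GCCGCC`) is written into shared-locus sequence at
rate 0.8. DE tables plant 237 co-up, 130 co-down and 1 discordant shared
gene (totals 624 and 820 significant per knockdown, split 395/229 and
504/316), with 40 + 38 of the shared genes being the genome genes hosting
shared promoter peaks — these are the 78 genes the ChIP–RNA intersection
recovers. Interactome runs (8 tumour, 2 reference) plant one candidate in
all tumour baits and none elsewhere, with 40 contaminants in every bait and
IgG list; accidental background candidates are deterministically broken.
Sensorgrams use ka = 10⁴ M⁻¹s⁻¹, kd = 8.7×10⁻³ s⁻¹ (KD = 870 nM),
Rmax = 250 RU, 600 s/300 s phases at 1 Hz, an 8-point 1:3 series from
5737.5 nM, drift 0.01 RU/s, a 20 RU bulk jump, a 2 RU injection artefact and
1 RU Gaussian noise.

What the generator does *not* emulate: read-level sequencing error,
GC-dependent coverage bias, replicate structure, peak-calling artefacts,
mass-spectral noise (hits are simulated at the identification-table level),
or non-1:1 binding. Passing truth-recovery tests therefore demonstrates the
*bookkeeping and estimation machinery* is correct under the stated noise
models, not that the thresholds would be optimal on any particular real
dataset.

Noise defaults were chosen once for the synthetic study: the amplitude
spread and per-sample noise are set so that the histogram-mode scaler — whose
accuracy is limited by its 0.1-bin resolution on a few hundred loci — stays
within a fraction of a bin of the true per-sample scale, keeping planted
class recovery exact in the noise-free setting and recall above 0.95 with
noise. The sensorgram noise (1 RU ≈ 0.4% Rmax) is typical of a
well-maintained instrument.

# Numerical choices and degenerate inputs

* Even-length interval midpoints floor to the lower base; consensus output
  is coordinate-sorted with sequential peak ids.
* Promoters are clipped at chromosome edges, not rejected (small synthetic
  genomes hit edges often); non-protein-coding genes are skipped silently.
* The S/N floor guards `log2(control/kd)` against division by zero; an
  epsilon threshold makes the operation the identity on positive matrices.
* Quantile normalisation with all-identical columns is the identity; mode
  scaling of a degenerate (single-bin) sample scales by that bin's offset.
* Fisher tables with a zero cell get the Haldane 0.5 correction for the
  odds ratio only; the p-value is exact regardless.
* All-zero steady-state responses, and responses without curvature, return
  explicit non-converged fits rather than arbitrary numbers.
* Problem sizes throughout (1 Mb chromosomes, hundreds of loci, 100 fit
  replicates) are the package's chosen desk scale: every stage runs in
  seconds and the full suite in about a minute, while leaving each planted
  structure statistically unambiguous.

# Known limitations

* The consensus match graph is quadratic in local peak density through the
  overlap pre-filter; fine for desk-scale catalogs, untested at
  genome-wide scale.
* Mode scaling assumes most loci are unperturbed; designs where a majority
  of peaks respond to treatment violate it and would need spike-in or
  housekeeping-locus normalisation instead.
* Quantile normalisation compresses fold changes when a large fraction of
  regions truly change (the usual caveat, visible in the ATAC arm if the
  affected fraction is pushed up).
* The interactome module performs no abundance modelling; it is set
  algebra over identification lists, as the candidate-nomination rule
  requires.
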