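# tsppi

Multi-omics analysis of **tumour-specific protein–protein interactions
(TSPPIs)** — protein complexes detected in tumour cells but absent from a
reference tissue. The package re-implements, as tested reusable R functions,
the analysis arc of a TSPPI study built around a chromatin-bound oncogenic
transcription factor and its tumour-specific chromatin-remodeller partner:

1. **Interactome comparison** (`compare_groups`, `nominate_candidates`) —
   bait-IP mass-spectrometry runs (RIME-style) are filtered per run
   (IgG-control subtraction, ≥1 unique peptide), then compared across sample
   groups by set algebra. A *candidate* TSPPI partner is an accession found
   in **every** tumour-group run and in **no** reference-group run, ranked by
   cumulative Mascot score.
2. **Consensus peak co-dependency** (`build_consensus`, `peak_matrix`,
   `apply_noise_threshold`, `scale_to_control_mode`, `call_disappearing`,
   `classify_codependency`) — ChIP peaks from 2 IPs × {control, A-knockdown,
   B-knockdown} are merged by the *midpoint rule* (two peaks match when the
   midpoint of either lies within the span of the other; matching is
   transitive). Amplitudes are summed coverage scaled by read length, floored
   at a signal/noise threshold of 20, and mode-scaled to each IP's control.
   A peak *disappears* when `log2(control/kd) ≥ 0.5`; peaks reduced under
   both knockdowns are *shared* (co-dependent), under one only are
   protein-specific.
3. **Annotation and integration** (`annotate_peaks`, `pair_with_genes`,
   `quantile_normalise`, `accessibility_change`) — feature annotation at
   ≥50% peak overlap, gene pairing within 5 kb (methods preset) or ±1 kb
   (results preset), ATAC quantile normalisation and accessibility change.
4. **Motif enrichment** (`count_kmer_presence`, `fisher_enrichment`,
   `dual_background_report`) — per-sequence presence of strand-collapsed
   6-mers, one-sided Fisher exact tests of disappearing-peak sets against an
   all-peaks and a promoter background.
5. **DE overlap** (`classify_overlap`, `fit_trend`, `intersect_chip_rna`,
   `delta_delta_ct`) — quadrant classification of two knockdown DE tables,
   OLS trend on the shared set, intersection with genes near shared peaks,
   and ΔΔCt qPCR quantification.
6. **SPR binding** (`double_reference`, `steady_state_response`,
   `fit_steady_state`, `percent_inhibition`, `serial_dilution`) — double
   referencing of multi-cycle sensorgrams, steady-state 1:1 Langmuir fit
   `Req(C) = Rmax·C/(KD + C)`, and fragment inhibition scoring
   `100·(1 − with/alone)`.

A fully seeded **synthetic-data generator** (`sim_config`, `simulate_*`)
produces every input with planted ground truth — peak classes, shared DE
genes, a planted all-tumour-runs interactor, a planted GC-rich 6-mer, and a
true 1:1 affinity — so every stage is validated by truth recovery.
`run_all()` chains everything into one report.

## Worked example

```r
library(tsppi)
res <- run_all(list(seed = 3))
print(res)
```

```
tsppi end-to-end run
  top candidate interactor: CAND0001
  peak classes: A_specific 92, B_specific 41, shared 101, unchanged 236
  DE quadrants: shared 368, co_down 130, co_up 237, discordant 1, a_only 256, b_only 452
  trend R^2: 0.8956
  steady-state KD: 860.3 nM
```

Reading the output: the planted tumour-specific interactor (`CAND0001`) is
the unique accession present in all 8 tumour bait runs and absent from both
reference runs. The co-dependency classifier recovers the planted peak
classes (100 shared loci planted; 101 called at this seed's noise). The DE
quadrants reproduce the planted 237 + 130 + 1 = 368 shared genes with an OLS
R² near the generator's 0.95 correlation target, and the steady-state fit
recovers the planted 870 nM affinity from noisy sensorgrams.

A thin CLI wrapper is included:

```sh
Rscript inst/scripts/tsppi.R run-all --seed 3 --out out_dir
```

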