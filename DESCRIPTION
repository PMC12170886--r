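Package: tsppi
Title: Tumour-Specific Protein-Protein Interaction Multi-Omics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying and characterising tumour-specific
    protein-protein interactions from multi-omics experiments. Implements
    differential bait-IP (RIME-style) interactome comparison with IgG
    contaminant subtraction and cross-group set algebra; consensus ChIP/ATAC
    peak summarisation by the midpoint-matching rule with read-length-scaled
    amplitude quantification, signal/noise flooring, control-mode scaling and
    knockdown co-dependency classification; 6-mer Fisher-exact motif
    enrichment against dual backgrounds; RNA-seq differential-expression
    overlap quadrants, trend regression and ChIP-RNA integration; delta-delta
    Ct quantification; and SPR steady-state 1:1 binding affinity fitting with
    double referencing and fragment inhibition scoring. A fully seeded
    synthetic-data generator emulates every input with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    limma,
    minpack.lm,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
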