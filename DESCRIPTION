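Package: tfab
Title: Benchmarking Differential Transcription-Factor Activity Inference from ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-simulation engine and scoring toolkit for benchmarking
    differential transcription-factor (TF) motif activity inference from bulk
    ATAC-seq. Perturbations of a single TF are introduced into baseline
    fragment cohorts by peak-level fragment downsampling driven by reference
    ChIP-seq fold-change distributions, optionally with injected GC-content or
    fragment-length technical biases. The package implements bias-corrected
    chromVAR-style deviations with GC/accessibility-matched background peaks,
    an insertion-profile activity model, a footprint-depth plus flanking
    accessibility test, GC smooth quantile normalization with a fast
    multivariate motif model, univariate log-fold-change models,
    empirical-Bayes moderated t-statistics, p-value combination utilities,
    motif scanning with exact dynamic-programming p-values, motif archetype
    clustering and merging, and an evaluation-metric suite (true-motif rank,
    network/archetype AUC scores, precision/recall, rank transformation and
    cross-method ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    optparse
Config/testthat/edition: 3
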