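Package: spnpipe
Title: Sustained Processing Negativity Analysis for Source-Space Auditory MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for sustained processing negativity
    (SPN) evoked by vowel-like sounds in source-space MEG and its linkage to
    words-in-noise perception. Provides parametric synthesis of vowel-like
    stimuli (damped-sinusoid formant pulse trains with periodicity and formant
    randomization), pink-noise maskers for a words-in-noise task, a synthetic
    two-group cohort generator for source-space evoked responses, polarity
    alignment and resampling of source timecourses, spatiotemporal
    threshold-free cluster enhancement (TFCE) with sign-flip and group-shuffle
    permutation tests, most-significant-source timecourse analysis, adjusted
    SPN and P3a-like peak measures, and subject-level statistics (partial
    correlations, Fisher Z comparisons, Benjamini-Hochberg FDR).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
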