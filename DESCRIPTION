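Package: nrcobind
Title: Dual Nuclear-Receptor Cistrome Overlap and Cooperativity Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of paired transcription-factor
    cistromes from replicated ChIP-seq experiments: consensus peak building
    from replicate summit calls, classification of two cistromes into
    exclusive and common (dominance-clustered) binding regions, nearest-gene
    and TSS-window annotation with observed/expected enrichment, a
    differential-expression gate and cooperative-induction caller for
    four-condition RNA-seq designs, replicate-aware differential occupancy
    and cooperative coactivator (MED1) recruitment tests, chromatin
    accessibility overlap categories, and a direct/inverted-repeat
    position-weight-matrix toolkit with false-positive-rate calibrated
    score thresholds. Includes a fully deterministic synthetic-study
    generator with ground-truth labels for validating every caller.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
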