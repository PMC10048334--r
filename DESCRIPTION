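Package: TrioDNM
Title: Trio-Based De Novo Mutation Rate Estimation, Spectrum Analysis and
    Molecular-Clock Dating
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the per-site per-generation single-nucleotide
    mutation rate from parents-progeny (trio) whole-genome sequencing.
    Implements a five-rule hard filter for candidate de novo mutations on a
    multi-sample trio site table, callable-site denominators stratified by
    genomic region and reference base class, per-offspring rate estimation
    with percentile bootstrap confidence intervals, mutation-spectrum
    summaries (transition/transversion ratio, six strand-collapsed
    substitution classes, CpG-island association, flanking-sequence context),
    false-negative calibration by binomial read spike-in, and conversion of
    per-generation rates into per-year rates, effective population size and
    divergence (domestication) time through coalescent parameters. A
    synthetic full-sib family simulator with known ground truth makes the
    whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
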