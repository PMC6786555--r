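Package: bloodconcord
Title: Concordance Analysis of Blood RNA Preservation Platforms on
    Two-Color Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how well a blood-collection/RNA-preservation
    platform preserves between-individual transcriptomic signal on
    two-color expression microarrays. Implements the M-A transform,
    within-array loess and across-array quantile normalization with
    duplicate-probe averaging, a within-donor versus across-donor
    correlation signal-to-noise statistic per platform, sample-level PCA,
    per-probe variability metrics (within-donor variance, donor-effect
    ANOVA p-value, absolute fold difference) and their Pearson
    correlations with probe physical properties (GC percent, transcript
    and gene size, distance to transcript ends), variance-based gene
    selection, and a local hypergeometric gene-set over-representation
    test with Benjamini-Hochberg FDR. A synthetic two-color experiment
    generator with known donor, platform, dye-bias and GC-linked noise
    structure provides ground truth for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
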