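Package: spikequant
Title: Spike-In Based Absolute Quantification for Amplicon Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts read counts of exogenous spike-in bacterial DNA into
    absolute 16S rRNA gene copy loads per gram of sample for amplicon
    (16S) microbiome count tables. Provides dose accounting from DNA mass
    to molecule copies, per-sample back-normalization factors, spike-read
    fraction quality control, multi-spike pooling diagnostics, gene-copy-
    number correction to cell counts, qPCR standard-curve bridging,
    normality-gated hypothesis testing, relative-versus-absolute
    downstream analyses (top-N genus rankings, differential abundance,
    alpha diversity, Bray-Curtis PCoA, PERMANOVA), and a synthetic
    spike-in experiment simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    vegan,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
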