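Package: ChIPRx
Title: Spike-In Normalised Differential Histone-Mark Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative ChIP-Rx (reference-exogenous spike-in ChIP-seq)
    analysis: spike-in scaling-factor computation and seeded downsampling,
    depth-invariant global histone-mark quantification, sliding-window
    negative-binomial differential testing with Benjamini-Hochberg
    correction and region merging, replicate consensus peaks and
    minimum-overlap interval algebra, exclusive differential-peak sets,
    scaled coverage tracks and TSS profiles, PWM motif scanning with exact
    dynamic-programming p-values and hypergeometric known-motif enrichment,
    ChIP-qPCR percent-input quantification, and seeded synthetic-data
    generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ChIPRx-package.R'
    'io-bed.R'
    'io-fragments.R'
    'io-meme.R'
    'spikein.R'
    'windows.R'
    'nbtest.R'
    'peak-algebra.R'
    'motifs.R'
    'simulate.R'
    'utils.R'
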