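Package: groscore
Title: Corepressor Occupancy Scoring and Direct-Target Calling from
    ChIP-seq and Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates temporally staged ChIP-seq peak calls with
    differential-expression tables to identify direct repression targets
    of the Drosophila corepressor Groucho. Provides replicate-reproducible
    peak derivation, temporal binding-dynamics classification, nearest-gene
    assignment with a Monte Carlo interval-placement null, a per-gene
    occupancy score built from a logistic distance-decay weight, response
    curves against randomized gene-set baselines with piecewise-linear
    breakpoint detection for target calling, promoter-proximal pausing
    analysis of chromatin-associated RNA coverage, and a parameterized
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
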