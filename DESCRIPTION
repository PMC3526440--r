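Package: bindingloci
Title: Prediction of Transcription Factor Binding Loci from Ancestral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies binding loci: genomic windows that have preserved
    their count of predicted transcription factor binding sites (TFBS) over
    evolutionary time to a degree that is unexpected given their sequence
    divergence, allowing for binding-site turnover within the window.
    Provides position weight matrix (PWM) readers (TRANSFAC, JASPAR),
    log-likelihood-ratio scanning with sampling-based threshold calibration,
    an empirical neutral model of TFBS-count transitions along branches of a
    phylogeny with inferred ancestral sequences, per-branch conditional
    p-values, a convolution-based null distribution of the combined locus
    score, a sequence-evolution simulator with count-level selection and
    turnover for fully synthetic test data, and an evaluation module
    computing positive-predictive-value curves against bound-region
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
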