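Package: lrquant
Title: Coverage-Aware Transcript Quantification from Long-Read RNA-Seq
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates transcript abundances from long-read RNA-seq
    alignments to a transcriptome using a fragment-level likelihood
    without an effective-length term. Multimapping reads are resolved by
    expectation-maximization over conditional alignment probabilities
    that combine an exponential alignment-score model with a logistic
    transcript-coverage-uniformity model. Includes a synthetic long-read
    alignment simulator, an evaluation panel of correlation and error
    metrics for comparing estimates against reference abundances, and
    broom-style tidiers and ggplot2 visualisations for fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
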