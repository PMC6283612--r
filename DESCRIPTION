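Package: ngdmap
Title: Mapping and Modelling of No-Go Decay Cleavage Fragments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of endonucleolytic cleavage during no-go decay (NGD) on
    stalling reporter mRNAs. Maps fragment 3' ends from 3'-RACE sequencing
    reads onto a reporter (adapter trimming plus ungapped alignment), builds
    stall-relative cleavage profiles with Savitzky-Golay smoothing and
    quantile-thresholded peak labelling, computes inter-peak spacing and
    periodicity statistics, and quantifies reporter half-lives from
    transcriptional-shutoff time courses and lag times from growth-curve
    derivatives. Includes generative models of queued-ribosome cleavage,
    RACE read synthesis, decay courses and logistic growth curves for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    ggplot2,
    generics,
    optparse,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    withr
Config/testthat/edition: 3
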