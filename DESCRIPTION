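Package: txstress
Title: Transcription Stress, Survival and Stereology Toolkit for Progeroid Mouse Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription stress -- the preferential loss of expression
    of long genes caused by stochastic transcription-blocking DNA lesions -- in
    bulk expression data, and provides the companion statistics used in
    progeroid-mouse intervention studies: differential expression with a
    transparent empirical-Bayes moderated t test, gene-length kernel-density
    comparison with Wilcoxon-Mann-Whitney tests, lesion-rate estimation from the
    length dependence of expression loss, principal-component variance summaries,
    Kaplan-Meier / (stratified) log-rank / log hazard-ratio survival analysis,
    a Grubbs-screened trapezoid body-weight AUC ledger, and optical-fractionator
    stereology. A synthetic-data module generates expression matrices with
    group-specific lesion rates, Gompertz lifespans, sigmoid growth-then-decline
    weight trajectories and 3D tissue point clouds so every stage is testable
    without external data.
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
    survival,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    flexsurv,
    limma,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
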