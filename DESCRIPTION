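Package: commonsig
Title: Diagnosing Common-Signal Artifacts in Power, Coherence and Spectral
    Granger Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how common signals (a non-silent reference
    electrode, volume conduction) distort power, coherence and spectral
    Granger causality in multichannel electrophysiology. Provides analytic
    spectra for bivariate autoregressive models, non-parametric spectral
    Granger causality through Wilson's spectral-matrix factorization, the
    coherence / directed-causality / instantaneous-interaction decomposition,
    neural-to-common-signal-ratio (NCR) estimation from high-frequency
    coherence, bipolar re-referencing, a multitaper analysis pipeline for
    linear-array local field potentials, and a synthetic LFP generator with
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
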