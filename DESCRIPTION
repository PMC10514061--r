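Package: latentdyn
Title: Latent-Space Dynamics of Functional Connectivity in Stroke-Like Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying low-dimensional latent representations of
    regional BOLD time series and the dynamical signatures of functional
    connectivity they preserve. Provides a vector-autoregressive synthetic
    cohort generator with stroke-like lesions (reduced homotopic coupling,
    lowered modularity, elevated temporal asymmetry, longitudinal recovery),
    a dense autoencoder trained with Adam and early stopping plus a PCA
    baseline, edge co-fluctuation time series with circular-shift null event
    detection, functional connectivity dynamics (FCD), edge metastability,
    signed constant-Potts modularity via Louvain, functional complexity,
    pairwise signal-irreversibility matrices from forward versus time-reversed
    lagged correlations, recovery outcome metrics (FC distance, SC-FC
    coupling, behavioral recovery), and random-forest classification with
    AUC reporting. Results are returned as tibbles with broom-style tidiers
    and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    ranger,
    pROC,
    Rtsne,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
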