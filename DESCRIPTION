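Package: latenzy
Title: Binning-Free Estimation of Neural Response Latencies from Spike Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Non-parametric, binning-free estimators of neural response
    latency from spike times. Implements a one-sample estimator of response
    onset based on cumulative-deviation statistics with an event-jitter null
    and Gumbel p-value approximation, a two-sample estimator of the onset of
    condition-specific spiking divergence with a trial-swap permutation null,
    bin-based comparator methods (half-max and SD-threshold latencies on
    peri-event time histograms), population-level benchmark statistics
    (monotonicity and latency dominance scores, trial-subsampling
    variability, paired bootstrap tests, Monte Carlo power analysis), and
    seeded inhomogeneous-Poisson simulators with known ground-truth onsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
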