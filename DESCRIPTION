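Package: tfanet
Title: Time-Frequency Analysis of Responsiveness and Noise Suppression in
    Gene Regulatory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generalized time-frequency analysis (TFA) toolkit for
    quantifying the trade-off between responsiveness and noise suppression
    in nonlinear biomolecular networks.  Random noisy stimuli (piecewise
    constant "block", piecewise linear "saw", and sinusoidal families) are
    fed through kinetic models of gene circuits -- the yeast galactose
    (GAL) dual-feedback network, the yeast oleate (OLE) feed-forward
    network with its topology variants, and an LPS-induced innate-immune
    network with delayed activation -- and the input and output signals are
    compared through their short-time Fourier transform spectrograms.  Two
    summary statistics are computed per stimulus/response pair: noise
    suppression (the ratio of spectrogram mean frequencies) and
    responsiveness (the inverse symmetric Kullback-Leibler divergence
    between normalized per-band total-variation distributions), together
    with Kolmogorov-Smirnov based alternatives.  Loop-strength parameter
    sweeps produce heat-map "portraits" of circuit behavior, including
    response-amplitude maps, non-physiological response screening and
    wild-type tolerance regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
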