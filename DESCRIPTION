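Package: eiconn
Title: Envelope of the Imaginary Coherence and Volume-Conduction-Robust
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain functional connectivity estimation for
    multi-trial M/EEG-style recordings, centred on the envelope of the
    imaginary coherence (EIC): the magnitude of the analytic signal of the
    imaginary-coherence curve regarded as a function of frequency, which
    recovers coupling that plain imaginary-part measures lose at zero- or
    pi-phase lags while staying insensitive to instantaneous volume
    conduction. Implements the full comparison family (coherence, PLV,
    two imaginary-coherence normalisations, PLI, wPLI, lagged coherence,
    two EIC variants), trial-shuffling surrogate significance thresholds,
    ground-truth simulators (delayed multivariate autoregression, a delayed
    stochastic Jansen-Rit neural-mass model integrated by Euler-Maruyama,
    and band-limited noise pairs), a synthetic sensor layout with
    distance-falloff gains, background/measurement noise mixing, and a
    nearest-sensor-ROI ROC/AUC evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
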