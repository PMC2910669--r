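Package: betaSift
Title: Single-Trial Extraction of Post-Movement Beta Oscillations from
    Multichannel EEG by Empirical Mode Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts non-phase-locked sensorimotor beta-band activity from
    single-trial multichannel EEG epochs. The channel of interest is
    decomposed into intrinsic mode functions by empirical mode decomposition
    (sifting with natural cubic-spline envelopes); task-relevant modes are
    selected by matching each mode's cross-channel spatial map against a
    spatial template using exact one-dimensional 3-means clustering;
    noise-suppressed activity is reconstructed, a trial-specific beta band
    is detected from the post-movement versus reference differential
    amplitude spectrum, and the post-movement beta rebound is quantified
    from zero-phase band-passed Hilbert amplitude envelopes. Includes the
    conventional event-related-synchronization template builder and a
    synthetic event-locked EEG simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
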