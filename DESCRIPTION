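Package: glycophot
Title: Joint Analysis of Fiber Photometry and Continuous Glucose Monitoring
    Around an Oral Glucose Challenge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of paired 1 Hz fiber-photometry
    (signal and isosbestic reference channels) and continuous arterial
    glucose time series recorded around an oral glucose gavage. Provides
    robust signal-processing primitives (MAD despiking, median and causal
    smoothing, zero-phase Butterworth filtering, reference-channel
    regression, baseline z-scoring), glycemic-excursion metrics with a
    sustained two-threshold onset detector, photometry response metrics
    including a band-power spectral onset detector with jittered nulls and
    an aperiodic 1/f spectral slope, a lagged template-regression model
    that decomposes the neural response into an anticipatory early phase
    and a residual second phase, lagged Spearman cross-correlation against
    circular-shift pseudosession nulls with Benjamini-Hochberg control,
    cohort-level statistics with subject fixed effects and robust standard
    errors, and a seeded generator of synthetic coupled sessions with a
    ground-truth manifest for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    sandwich,
    lmtest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
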