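Package: boldslope
Title: Lifespan Analysis of the Resting-State BOLD Spectral Slope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A config-driven pipeline for studying how the spectral slope of
    resting-state BOLD fluctuations changes across the adult lifespan.
    Estimates per-parcel power spectra from motion-censored timeseries via a
    lag-tapered autocovariance and cosine transform (Wiener-Khinchin route),
    fits the semilog spectral slope in the 0.015-0.145 Hz band, models
    per-parcel age trajectories with penalized-spline generalized additive
    models and FDR control, clusters trajectories with fuzzy c-means,
    assesses spatial association with metabolic maps by quaternion spin
    permutation, and computes a per-subject Spectral Slope Youthful Index
    with robust (scaled-MAD) outlier detection and white-matter T2w
    correlates. Includes a fully seeded synthetic cohort generator that
    emulates the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    cluster,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
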