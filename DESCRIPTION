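Package: ecoseasons
Title: Delineating Seasonal Space-Use States from GPS Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying animal-defined ecological seasons
    ("seasonal space use states") from GPS collar telemetry. Raw tracks are
    filtered, resampled to a target relocation interval, annotated with step
    metrics and landscape covariates, and reduced to a daily population-level
    space-use matrix. Seasons are delineated by k-means clustering of ordinal
    days with noisy-variable screening (HINoV), bootstrap cluster-stability
    assessment (Jaccard), moving-window smoothing, and run-based transition
    dating, then characterized by principal components. A simplified
    per-individual, per-season resource selection stage estimates habitat
    selection at core (50%) and home-range (95%) utilization-distribution
    levels with AICc-weighted population pooling. A regime-switching
    habitat-weighted random-walk simulator with known ground-truth season
    calendars supports testing and power analysis without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
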