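Package: cloudsens
Title: Sensitivity of Vegetation Photosynthesis to Cloud Cover Across
    Hydroclimate Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying how gross primary
    productivity (GPP) responds to cloud fraction across hydroclimate
    gradients. Provides calendar-period anomaly standardization
    (detrending plus Z-scoring of gridded or site time series),
    univariate, partial, cloud-type and time-lagged sensitivity
    regression with collinearity diagnostics, annual-scale attribution
    via year-to-year differences with spatial moving-window pooling and
    incremental variance explained, and projection of cloud-driven GPP
    change with area-weighted regional series. Includes a seeded
    synthetic-world generator with known hydroclimate-dependent ground
    truth so every stage is testable by parameter recovery, plus
    humidity-index, Penman-Monteith potential evapotranspiration and
    active-season utilities, ISCCP cloud-type reclassification, and
    self-describing gridded text input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
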