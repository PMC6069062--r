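Package: lurtools
Title: Land Use Regression Exposure Modelling with Temporal Adjustment
    and Sign-Constrained Forward Selection
Version: 0.1.0
Authors@R:
    person("LUR", "Tools Developers", email = "lurtools@example.org",
           role = c("aut", "cre"))
Description: An end-to-end land use regression (LUR) workflow for
    small-area air-pollution exposure assessment: synthetic study
    generation (GIS layers, an NDVI-like raster, stratified monitoring
    sites, a gappy hourly reference-station record, and scheduled weekly
    passive-sampler measurements), buffer-based GIS predictor extraction
    (counts, clipped lengths and areas, nearest distances, inverse
    distance transforms, raster buffer means), temporal adjustment of
    asynchronous weekly measurements to a continuous reference monitor,
    ESCAPE-style supervised forward selection with direction-of-effect
    vetoes and VIF, p-value and Cook's distance diagnostics,
    leave-one-out cross-validation with RMSE, normalized mean bias and
    Moran's I residual autocorrelation, and exposure-surface prediction
    over grids and receptor points. All geometry is planar Euclidean in
    metres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
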