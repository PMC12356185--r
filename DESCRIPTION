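Package: grasslue
Title: Light-Use-Efficiency Modelling of Grassland Gross Primary Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a light-use-efficiency (LUE) model of gross primary
    productivity (GPP) for 30 m bimonthly raster time series: NDVI, LSWI and
    fAPAR spectral indices, temperature and water down-regulation scalars,
    uncalibrated GPP with deferred biome calibration via metadata scale
    factors, annual accumulation, tiling and mosaicking, plus the
    eddy-covariance flux-tower validation protocol (gap-fill screening,
    day-time/night-time partitioning consistency filtering, bimonthly
    medians, footprint extraction and accuracy statistics). A synthetic-scene
    module generates reflectance, land-surface-temperature, radiation,
    grassland-mask and tower inputs with the statistical structure the
    pipeline assumes, so the whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tiff, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
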