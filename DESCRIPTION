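Package: forestdeg
Title: Forest Structure, Biomass and Degradation Mapping from Canopy Height Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for regional forest carbon accounting from airborne
    lidar canopy height models and field inventories: hectare-scale canopy metrics
    (mean top canopy height, percent cover, large-tree canopy area), a wood-density
    aware power-law height-biomass model fitted by nonlinear least squares,
    wall-to-wall height extrapolation with a random-forest regressor over satellite
    predictor layers with linear bias correction, conversion to aboveground biomass
    through a class wood-density map, a composite forest degradation index with
    severity classification and biomass-loss accounting, and spatially explicit
    uncertainty propagation (per-pixel error composition, semivariogram-based
    class variances, scene-level jackknife and bootstrap cross-validation). A
    synthetic-landscape generator with known ground truth makes every stage
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
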