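Package: reefgrid
Title: Spatial Interpolation of Benthic Percent Cover by Kriging and
    Inverse Distance Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the percent cover of habitat-forming benthic
    organisms (hard corals, octocorals, macroalgae, sponges, zoantharians)
    from photo-transect samples. Implements empirical semivariogram
    estimation with weighted least-squares model fitting, ordinary kriging
    and inverse distance weighting with an elliptical search neighbourhood,
    leave-one-out cross-validation with mean absolute error and r-squared
    accuracy metrics, and synthesis of per-taxon prediction rasters into
    presence/absence layers and a habitat-former richness map. Includes a
    synthetic-data module that simulates patchy, zero-inflated cover
    surfaces by Gaussian random fields (dense Cholesky or circulant
    embedding), samples them along photo-transects, and degrades them with
    point-count observation noise, so that interpolator accuracy can be
    studied under controlled sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
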