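Package: platymorph
Title: Landmark-Based Geometric Morphometrics of Platyrrhine Lower Molars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional landmark-based geometric morphometric
    analysis of primate lower molar crowns. Reads TPS and coordinate-table
    landmark files, standardizes tooth side and image scale, performs
    generalized Procrustes analysis (partial Procrustes superimposition with
    tangent-space projection), principal component analysis of shape with
    thin-plate-spline deformation grids, and linear discriminant
    classification of unknown (fossil) specimens against extant taxa at
    several taxonomic levels, with leave-one-out cross-validation and
    Mahalanobis posterior probabilities. Includes a repeated-digitization
    measurement-error toolkit (paired Procrustes distances, Mantel matrix
    correlation, permutational MANOVA) and a hierarchical synthetic-data
    generator emulating a multi-level platyrrhine taxonomy for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan,
    jsonlite
Config/testthat/edition: 3
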