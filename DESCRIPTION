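Package: elasurf
Title: Elastic Shape Analysis of Genus-Zero Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Elastic shape analysis of closed genus-zero surfaces such as
    subcortical brain structures. Surfaces are represented as embeddings of the
    unit sphere sampled on a regular colatitude-longitude grid, compared through
    the square-root normal field (SRNF) transform, and registered by optimizing
    jointly over rotations and sphere reparameterizations. On top of the elastic
    metric the package provides geodesic deformation paths, Karcher means, shape
    PCA with invertible principal scores, spherical parameterization of
    triangulated meshes (Tuette and conformal mapping), synthetic surface and
    clinical-covariate generators for validation studies, and the principal-score
    regression layer (interaction designs, stepwise selection, distance matrices,
    classical MDS) used to relate shape to clinical outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    cluster,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
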