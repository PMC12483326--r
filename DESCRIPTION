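Package: hexpack
Title: Hexagonal Packing, Orientational Order, and Junctional Tension
    Inference in Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the packing geometry and mechanics of
    confluent epithelial monolayers such as the hexagonally packed
    meridional row cells of the vertebrate lens. Builds polygonal tissue
    meshes from segmented label images or synthetic generators, counts
    neighbor numbers and classifies dislocation and disclination
    topological defects, computes hexatic and nematic order parameters and
    per-cell shape anisotropy, classifies edges into anterior-posterior
    versus equatorial orientation classes, quantifies junctional marker
    intensity along edges, and infers relative edge tensions and cell
    pressures from geometry alone by Bayesian force inference with
    ABIC-based regularization. A synthetic-tissue generator with known
    ground-truth tensions provides an oracle for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    igraph,
    jsonlite,
    Matrix,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
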