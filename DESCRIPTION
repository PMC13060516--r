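Package: fieldmorph
Title: Landmark-Driven Morphing and Cross-Mesh Projection of Body-Surface
    Sensation Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing projected-field annotations recorded on 3D
    body meshes by sensory neuroprosthesis users. Provides triangle-mesh and
    landmark I/O (OBJ, GLB, JSON), whole-model and hierarchically segmented
    Procrustes alignment of a 3D body part onto 2D reference illustrations,
    flattening and rasterization of mesh annotations into binary pixel masks
    with Jaccard overlap and obliqueness scoring, and projection of
    annotations between arbitrary meshes through a sparse proportional-
    coverage transfer matrix. Includes seeded generators for articulated
    synthetic hand meshes, landmark sets and patch annotations, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    RANN,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
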