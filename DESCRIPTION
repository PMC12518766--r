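Package: spineforge
Title: Automated Lumbar-Spine Finite-Element Model Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds complete patient-specific lumbar-spine finite-element
    models from labeled vertebra and intervertebral-disc surface meshes.
    Provides triangle-mesh data structures and operators (normals, Laplacian
    smoothing, hole filling, containment queries, isotropic remeshing,
    tetrahedralization), a deterministic synthetic spine generator, inward
    offsetting of each vertebra into cortical shell and cancellous core,
    PCA-driven separation of each disc into nucleus pulposus and annulus
    fibrosus, geometric endplate extraction, spherical-coordinate ligament
    attachment with linear spring elements, cartilage construction at every
    vertebra-disc interface, and assembly with material cards, contacts,
    boundary conditions and load cases exported to FEBio-format XML and
    legacy VTK.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
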