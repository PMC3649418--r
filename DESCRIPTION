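Package: orthofuse
Title: Multi-Body Orthodontic Models from Optical Surface Scans and CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-tooth manipulable 3D orthodontic models by fusing two
    independent imaging modalities. Structured-light surface scanning is
    simulated (binary stripe coding, ray-plane triangulation, turntable view
    composition), impression- and cast-mode scans are registered by iterative
    closest point and merged, and tooth crowns are separated from gingiva
    using covariance-eigenanalysis surface variation and margin-line splines.
    Cone-beam computed tomography (CBCT) volumes are segmented slice by slice
    with distance-regularized level-set evolution (DRLSE) initialized from the
    optically scanned crowns, after an alignment stage that selects the
    iso-surface threshold minimizing crown discrepancy. Optical crowns and
    CBCT roots are fused into individual tooth bodies within a multi-body
    model of teeth, gingiva and socketed alveolar bone. All stages are
    exercised on deterministic synthetic jaw phantoms with analytic ground
    truth, so no clinical data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
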