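Package: wallshear
Title: Wall Shear Stress, Oscillatory Shear and Shear Gradient Analysis at
    Arterial Bifurcations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and case-control statistics for haemodynamic
    wall parameters at cerebral artery bifurcations. Computes per-vertex
    time-averaged wall shear stress (WSS), oscillatory shear index (OSI)
    and the directional wall shear stress gradient (WSSG) on triangulated
    vessel-wall surface meshes; extracts apex-centred patches and
    high-WSS regions; digitizes spectral-Doppler (TCCS) images into inlet
    velocity waveforms; and runs the full case-control statistical
    pipeline (group comparisons, Fisher exact contingency analysis,
    correlation screening, variable selection, logistic regression and
    ROC analysis). Includes analytic Womersley-flow oracles and synthetic
    bifurcation-field, spectrogram and cohort generators so every stage
    is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
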