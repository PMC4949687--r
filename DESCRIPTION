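Package: cortimap
Title: Surface-Based Phase-Encoded Mapping, Cluster Correction and
    Reading-Activation Overlap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for surface-based functional MRI mapping
    studies: Fourier statistics for phase-encoded (traveling-wave)
    retinotopic, tonotopic and somatomotor mapping with harmonic
    exclusion; cross-subject complex vector averaging on a shared
    cortical mesh; Monte-Carlo surface cluster-size correction;
    block-design GLM analysis with a double-gamma haemodynamic response
    and temporal derivatives; and vertex-area overlap quantification
    between task activation and topological map masks. Includes a
    synthetic-cortex generator (icosphere meshes, ground-truth maps,
    phase-encoded and block-design time series, multi-subject cohorts)
    for calibration and recovery testing, plus minimal ASCII GIFTI and
    label-file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
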