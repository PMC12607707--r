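Package: GantryInspect
Title: Digital Twin of a Gantry-Based Livestock Inspection System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable digital twin of an overhead gantry inspection system for
    caged-rabbit houses. Implements depth-assisted pinhole registration of
    near-infrared (NIR) images onto the thermal-infrared (TIR) camera frame with
    z-buffered forward warping and NIR-TIR fusion, a banded dual-drive
    deviation-correction controller with a closed-loop plant simulator, inspection
    session orchestration over a cage coordinate grid (route tables, multi-modal
    capture, naming convention, completeness verification, dataset manifests and
    splits), environmental telemetry with welfare-threshold compliance and
    measurement-uncertainty statistics, and a synthetic scene generator producing
    geometrically consistent NIR/TIR/depth frames with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
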