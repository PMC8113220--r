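Package: stonevol
Title: Semi-Automated CT Volumetry of Renal Stones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring renal stone burden on non-contrast CT
    (CT KUB): Hounsfield-unit threshold segmentation with 3D connected
    component labelling, voxel-count volumetry and axis/area morphometry,
    manual ellipsoid volume estimators (scalene, oblate, prolate), a
    three-way shockwave-lithotripsy outcome classification with a
    clinically-insignificant-residual-fragment (CIRF) size rule, and a
    statistical layer (Pearson correlation; univariable binary logistic
    regression with Wald intervals and Cox-Snell/Nagelkerke pseudo
    R-squared). Includes a synthetic CT phantom generator with stones of
    analytically known ellipsoidal geometry, a minimal single-frame CT
    DICOM reader/writer, and a treatment-cohort simulator, so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
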