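Package: painface
Title: Dynamic Facial Representation for Automatic Infant Pain Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic assessment of procedural pain in infants from
    facial video. Implements frame-level geometric deformation and head-pose
    distance parameters from 68-point facial landmarks, patch-based gradient
    texture and LBP-TOP (Local Binary Patterns on Three Orthogonal Planes)
    appearance dynamics, a 16-parameter temporal descriptor scheme over
    smoothed signals and their derivatives, Supervised Locality Preserving
    Projections (SLPP) for dimensionality reduction, per-stream support vector
    machine classification with majority-vote decision fusion, NIPS-based
    ground-truth labelling, and leave-one-subject-out evaluation. Includes a
    synthetic cohort generator with controllable pain dynamics so the full
    pipeline can be exercised without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
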