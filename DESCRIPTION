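Package: laryngometry
Title: Laser-Calibrated Morphometry and Mucosal Feature Analysis for
    Quantitative Laryngoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for computer-aided quantitative laryngoscopy with
    laser fiducial calibration. Detects projected laser dot and line
    fiducials in endoscopic still images to convert pixel measurements
    to millimetres, recovers retropalatal depth from a tilted laser
    line by triangulation, computes per-region colour (RGB means,
    CIELab) and gray-level co-occurrence texture features from
    annotated mucosal regions, derives the calibrated morphometric
    parameters of the glottis and oropharyngeal inlet, scores
    post-intubation mucosal inflammation with a weighted function
    index, and evaluates discrimination with ROC analysis. Includes a
    deterministic synthetic phantom generator with known ground truth
    so every stage is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
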