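Package: ivcpulse
Title: Semi-Automated Inferior Vena Cava Edge Tracking and Right Atrial
    Pressure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify inferior vena cava (IVC) size and cardiac
    pulsatility from short B-mode ultrasound cine loops and to estimate
    right atrial pressure (RAP) from echocardiographic features.  The
    pipeline covers semi-automated edge tracking of the vessel borders
    with motion compensation, computation of the cardiac caval index
    (CCI) and mean diameter, three RAP estimators (the guidelines
    size/collapse rule, a normalized linear model, and a one-vs-all
    radial-basis support vector machine), backward feature selection
    driven by cross-validated accuracy, leave-one-out evaluation, and
    the associated agreement and classification metrics.  Synthetic
    generators for speckle vessel videos and patient cohorts provide
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
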