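Package: gaparea3d
Title: 3D Gap Area Measurement of Tibial Plateau Fracture Displacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies initial intra-articular displacement of tibial plateau
    fractures on CT as the "3D gap area": the surface area (mm^2) spanning all
    fracture lines between bone fragments at the articular level. Provides the
    full measurement pipeline (Hounsfield thresholding, fragment labelling,
    iso-surface mesh extraction with volume-preserving smoothing, articular
    delineation, fracture-line trimming, loop closure and spanning-surface
    triangulation), the prognostic layer built on it (four-group
    classification with 150/550/1000 mm^2 boundaries, ROC and Youden-J cut-off
    selection, Kaplan-Meier native-knee survivorship, log-rank and Cox
    proportional-hazards analysis of conversion to total knee arthroplasty),
    and synthetic fracture phantoms and cohorts with analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    survival,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
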