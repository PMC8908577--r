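Package: octcomp
Title: Ocular-Factor Compensation and Diagnostic Evaluation of
    Circumpapillary RNFL Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for removing the contribution of ocular anatomical
    factors from circumpapillary retinal nerve fiber layer (cpRNFL)
    thickness profiles measured by optical coherence tomography, and for
    evaluating the diagnostic value of the compensated profiles.  The
    package fits per-sector multivariate linear regressions of measured
    thickness on optic disc geometry, fovea position, peripapillary
    vessel density, refractive error, age, ethnicity and scan quality,
    with exhaustive AIC subset selection, and subtracts the selected
    centered covariate effects.  It also provides the feature-extraction
    steps the model consumes (disc ellipse morphometry, fovea geometry,
    annular 256-sector vessel density, ETDRS macular composites), a
    diagnostic-comparison framework (logistic score models, ROC/AUC,
    sensitivity at fixed specificity, paired DeLong tests,
    subject-clustered bootstrap, post-hoc power), and a synthetic cohort
    and en-face image generator emulating the covariate structure,
    two-eyes-per-subject clustering and vessel-density confounding of a
    neurodegeneration OCT study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
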