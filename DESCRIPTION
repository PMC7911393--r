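Package: petmtv
Title: Metabolic Tumour Volume Segmentation Reproducibility on Synthetic PET Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-body-like FDG-PET standardised-uptake-value (SUV)
    phantoms with focal and infiltrative lymphoma-like lesions, measures the
    metabolic tumour volume (MTV) with eight lesion-delineation methods (three
    absolute SUV thresholds, the 41% SUVmax percentage threshold, and the
    adaptive Daisne, Nestle, Fitting and Black algorithms) under a two-observer
    region-of-interest model, and quantifies inter-observer agreement
    (intraclass correlation, Kendall's tau-b, BCa bootstrap comparison,
    Bland-Altman limits of agreement) together with prognostic cut-off and
    survival analysis (ROC/Youden, Kaplan-Meier, log-rank, Cox proportional
    hazards) of the resulting cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
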