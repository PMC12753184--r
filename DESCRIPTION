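Package: cpathtil
Title: Computational Pathology Scoring of Tumour-Infiltrating Lymphocytes
    in Ductal Carcinoma In Situ
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumour-infiltrating lymphocyte (TIL) density in the
    periductal stromal microenvironment of annotated ductal carcinoma in situ
    (DCIS) regions on H&E images and evaluates the resulting CPath TIL
    biomarker. Provides a classical image-analysis chain (optical-density
    conversion, H&E stain deconvolution, watershed nuclei segmentation,
    morphometric lymphocyte classification, stroma masking), periductal
    ring geometry via Euclidean distance transforms, patch-based TIL
    scoring with median dichotomisation, survival analysis with
    radiotherapy-interaction tests, matched nested case-control conditional
    logistic regression, and fully ground-truthed synthetic histology and
    survival-cohort generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    mgcv,
    png,
    stats,
    survival,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
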