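Package: tfivolume
Title: Tumor-Fat Interface Volume Quantification from Multiphase Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the tumor-fat interface volume, an imaging biomarker
    for predicting pathologic complete response to neoadjuvant chemotherapy
    in breast cancer, from multiphase dynamic contrast-enhanced breast MRI.
    Provides a seeded synthetic phantom generator with known ground-truth
    tissue labels, chest-wall surface interpolation from sparse contours,
    two-stage k-means tissue clustering (fat versus non-fat on the
    pre-contrast image, tumor versus fibroglandular on the subtraction
    image), 6-adjacency interface voxel counting, and the full downstream
    statistical pipeline: Youden's J dichotomization, univariable and
    multivariable logistic regression with variance-inflation screening,
    DeLong comparison of correlated ROC curves, continuous net
    reclassification and integrated discrimination improvement, AIC model
    comparison, and two-way random-effects intraclass correlation for
    interobserver agreement.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    pROC,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
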