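Package: nslt
Title: Neutrosophic-Slantlet Texture Features for Brain Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Texture-based classification of brain MRI slices built on a
    composite neutrosophic-Slantlet representation. Grayscale images are
    mapped to true/indeterminate/false (T/I/F) membership maps, each map is
    decomposed with the orthonormal Slantlet filter bank, and statistical
    texture descriptors (gray-level co-occurrence, run-length, and
    difference statistics) are computed per map and aggregated. One-way
    ANOVA ranks the descriptors, and standard classifiers (SVM, decision
    tree, k-nearest neighbours, naive Bayes) are evaluated with stratified
    cross-validation, confusion metrics, and ROC/AUC. A seeded two-class
    texture phantom generator makes the whole pipeline runnable without any
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    rpart,
    data.table,
    png,
    tiff,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
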