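Package: perirad
Title: Peritumoral Radiomics Pipeline for Mammographic Mass Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the diagnostic value of peritumoral tissue in
    mammographic mass classification. Provides a synthetic mammogram phantom
    generator with controllable texture signal in the mass core and a
    peritumoral rim, physical-unit ring/combined region construction on top of
    an Otsu body mask, a from-scratch 2D radiomics feature engine (first-order,
    shape, GLCM, GLRLM, GLSZM, GLDM), correlation-filtered L1-penalised
    logistic regression classifiers, patient-stratified five-fold 3:1:1
    cross-validation with ROI- and patient-level scoring, DeLong comparisons
    of paired AUCs, a reduced-scale convolutional classifier with class
    activation maps, and clinical contingency-table statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    glmnet,
    igraph,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
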