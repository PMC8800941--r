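Package: petrad
Title: Co-Clinical FDG-PET Radiomics: Robust Features and Response Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative FDG-PET analysis of tumors in co-clinical
    (preclinical PDX + clinical) imaging studies. Extracts a 131-feature panel
    (SUV metrics, volumes, first-order intensity statistics, and IBSI-style
    GLCM/GLRLM/GLSZM/GLDZM/NGTDM/GLDM texture features) from 3D SUV volumes
    with binary tumor masks; screens features for test-retest reproducibility
    (Lin's concordance), mutual redundancy (Spearman correlation pruning and
    clustering), and tumor-volume dependency (AIC/BIC model selection); ranks
    robust features with ReliefF to assemble compact radiomic signatures; and
    benchmarks CART, RBF-SVM, and Gaussian naive Bayes classifiers of therapy
    response against SUVmean/SUVmax/SULpeak under stratified 10-fold
    cross-validation. Includes a digital phantom generator for synthetic
    co-clinical cohorts with known ground truth and the packaged clinical
    lesion-level SUV table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    igraph,
    jsonlite,
    minpack.lm,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
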