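Package: hepannot
Title: Automated Liver Tumor Annotation from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for automated annotation of liver tumors
    in CT volumes: tumor segmentation with a multi-residual attention U-Net
    (squeeze-and-excitation channel attention plus pixel-wise attention
    gates), tri-planar morphological post-processing with a plane-vote rule,
    an eight-model Couinaud-style liver partition with an overlap rule for
    tumor location, a linear pixel-to-centimeter size regression on the
    longest border-point distance, and radiomics-based multi-label
    recognition of tumor characteristics. A built-in synthetic CT phantom
    generator with known liver geometry, segment partition, tumor sizes and
    characteristic labels makes every stage testable without external data.
    Networks are trained with a small pure-R reverse-mode automatic
    differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    EBImage,
    e1071,
    randomForest,
    stats,
    utils,
    grDevices
Suggests:
    MASS,
    nnet,
    xgboost,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
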