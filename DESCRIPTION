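Package: glcmrad
Title: Masked GLCM Texture Radiomics with Core and Margin ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for grey-level co-occurrence matrix (GLCM) texture
    radiomics on masked 2D image stacks such as T2-weighted breast MRI.
    Builds tumor-core and dilated peritumoral-margin regions of interest,
    quantizes in-ROI intensities, computes direction-averaged slice-pooled
    GLCMs and eleven Haralick-style texture features, and evaluates four
    classifier families (Fisher linear discriminant, linear and RBF support
    vector machines, k-nearest neighbors) under leave-one-out
    cross-validation with exhaustive small-subset feature selection and
    balanced subsampling for class-imbalanced cohorts. Includes a synthetic
    tumor-phantom cohort generator with class-dependent Gaussian-random-field
    texture and Rician-like noise so the full analysis is testable without
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    RNifti,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
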