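Package: lpcsononet
Title: Lightweight Pyramid Convolution Networks for Fetal Ultrasound
    Standard-Plane Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building, training and interpreting compact
    convolutional networks that classify fetal ultrasound standard planes.
    Implements the light pyramid convolution (LPC) block and the
    LPC-SonoNet architecture alongside a SonoNet64 reference, exact
    closed-form parameter accounting, an imbalance-correcting data
    pipeline (stratified 8:1:1 splitting and deterministic augmentation
    to per-category target counts), a seeded training loop with stepped
    learning-rate decay and Adam, one-vs-rest evaluation metrics, and
    gradient-weighted class activation maps (GradCAM). A seeded synthetic
    ultrasound-phantom generator with category-discriminative geometry
    and multiplicative speckle makes the whole stack testable without any
    external imaging data. The network engine is implemented in C++
    (single-precision im2col convolutions through BLAS) so that training
    small models is practical on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
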