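Package: neurofusion
Title: Multimodal Brain-Tumor MRI Classification with Deep Feature
    Fusion and Hybrid Grey Wolf-Jaya Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for classifying the four structural
    MRI modalities of multimodal brain-tumor studies (FLAIR, T1, T1CE,
    T2). Deep features are extracted from two trainable networks - a
    modified ResNet-50 with three appended residual blocks and a
    stacked convolutional autoencoder - fused by a parallel 1-D pooling
    operator, and pruned by a hybrid wrapper selector that runs Grey
    Wolf Optimization followed by Jaya refinement with an extreme
    learning machine as the fitness function. Includes preset
    neural-network classifiers with a confusion-matrix metric suite,
    Grad-CAM class-activation maps, a paired Student's t comparison of
    classifiers across experiment stages, and seeded synthetic
    generators (modality-like image sets and class-conditional Gaussian
    feature tables) so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
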