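Package: vitad
Title: Vision-Transformer Pipeline for Slice-Based Multi-Stage Dementia
    Classification of Brain MRI and fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline for predicting
    Alzheimer's disease stages (AD, MCI, healthy control) from volumetric
    brain images by two-dimensional slice decomposition and vision
    transformer classification.  Provides a synthetic NIfTI cohort
    generator emulating preprocessed rs-fMRI (45x54x45xT) and structural
    grey-matter (91x109x91) geometry; lossless volume-to-PNG slice
    decomposition with empty-slice filtering; stratified subject-level
    train/validation/test splitting with label-merging experiment schemes
    and a healthy-control noise challenge; a family of vision transformer
    classifiers (vanilla multi-head self-attention, DeepViT re-attention,
    CaIT class-attention, and an optimized reduced-input variant) with
    exact trainable-parameter accounting; slice-level training with Adam
    and step learning-rate decay; subject-level vote-for-majority
    aggregation; classification reports with repetition statistics; and
    per-head/per-depth attention-map and global attention feature map
    visualization.  Tensor operations, reverse-mode differentiation,
    NIfTI-1 and PNG input/output are implemented natively so the package
    runs on a plain R installation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    glmnet,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
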