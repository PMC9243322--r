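Package: FusionOCT
Title: Fusion Networks for Retinal OCT Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classifier-fusion toolkit for multiclass retinal optical
    coherence tomography (OCT) image classification. Provides three fusion
    strategies over pluggable convolutional base classifiers: fixed late
    fusion with validation-F1-derived weights, trainable-weight late fusion
    with analytically derived gradients, and feature-concatenation early
    fusion trained under a four-part multi-head loss. Includes a
    convolutional block attention module (CBAM) appended to each base
    classifier, a two-phase transfer/fine-tune training protocol, a full
    multiclass evaluation formalism (confusion matrix, per-class and
    support-weighted metrics, one-vs-rest ROC/AUC), Grad-CAM localization
    maps, and a seeded synthetic OCT-like image generator so the whole
    pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, EBImage, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), pROC, png, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'FusionOCT-package.R'
    'RcppExports.R'
    'backbone.R'
    'cbam.R'
    'checkpoint.R'
    'data_io.R'
    'evaluation.R'
    'explain.R'
    'fusion_auto.R'
    'fusion_f1.R'
    'fusion_weight.R'
    'nn_layers.R'
    'synthetic.R'
    'training.R'
    'zzz.R'
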