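Package: postureVAE
Title: Variational Autoencoder Augmentation for 3-D Spinal Posture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for augmenting surface-topography spinal posture datasets
    (54 static parameters: 3 pelvic angles plus the orientation of 17
    vertebral levels in three anatomical planes) with a variational
    autoencoder, and for evaluating how indistinguishable the synthetic
    postures are from real ones. Provides a subject-grouped synthetic cohort
    generator, preprocessing (per-subject session selection, isolation-forest
    outlier removal, subject-disjoint grouped k-fold splits, feature
    standardization), a dense variational autoencoder trained with Adam,
    a three-armed quality evaluation (k-nearest-neighbour discriminability,
    nonparametric one-dimensional statistical parametric mapping with
    permutation max-statistic inference, and rater-agreement scoring with
    Fleiss' kappa), and a deep-autoencoder benchmark quantifying the
    reconstruction benefit of training on mixtures of real and synthetic
    samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
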