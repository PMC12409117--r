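Package: epcaFusion
Title: Graph-Regularized Sparse PCA Fusion of Multimodal Radiomic Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature-level fusion of two-block radiomic feature tables
    (e.g., CT and quantitative-ultrasound features per patient) by an
    enhanced principal component analysis that couples a Hessian-energy
    manifold regularizer on the sample components with a non-convex
    l2,1-2 row-sparsity penalty on the principal directions, solved by a
    concave-convex procedure with alternating closed-form and eigenvector
    updates. Includes comparator fusers (PCA, kernel PCA, ridge CCA
    fusion, robust PCA via ADMM, l2,1 graph-Laplacian PCA, mRMR ranking
    with sequential forward selection), a leave-one-patient-out
    evaluation protocol with fold-wise standardization, SMOTE
    oversampling, nested hyperparameter tuning and bootstrap metrics,
    and a seeded two-modality synthetic data generator with known latent
    manifold structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    kernlab,
    class,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: DimensionReduction, Classification, FeatureExtraction
RoxygenNote: 7.3.3
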