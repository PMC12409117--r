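# epcaFusion

Feature-level fusion of two-modality radiomic feature tables — a CT block
and a quantitative-ultrasound (QUS) block per patient — for binary
treatment-response prediction (complete responder CR vs. partial responder
PR), built in Bioconductor style on `SummarizedExperiment`.

## What it does

At its core is an **enhanced PCA (EPCA)**: with `X` the standardized
features-by-samples table of both blocks,

    min_{U,V}  1/2 ||X − U Vᵀ||²_F  +  λ ||U||_{2,1−2}  +  α Tr(Vᵀ H V)
    s.t. VᵀV = I

where `||U||_{2,1−2} = ||U||_{2,1} − ||U||_F` is a non-convex row-sparsity
penalty on the principal directions (sparser than ℓ2,1, still Lipschitz)
and `H` is a Hessian-energy graph over the samples whose null space
contains functions varying *linearly* along the data manifold — a weaker
bias than the graph Laplacian's pull toward constancy. The objective is
solved by a concave–convex procedure: a closed-form diagonal update of `U`
(safeguarded so the majorizer never increases) alternating with an
eigenvector update of the orthonormal components `V`, with a provably
non-increasing objective trace. Components fuse the two blocks into `k`
patient-level features (default `k = 6`).

Around the core, the package provides:

* `hessianGraph()` — kNN patches → SVD tangent frames → least-squares
  Hessian energy → assembled symmetric PSD regularizer;
* comparator fusers behind one interface (`fitFusion`/`predictFusion`):
  plain PCA, RBF kernel PCA, ridge CCA fusion, robust PCA by ADMM
  (`rpcaAdmm`), ℓ2,1 graph-Laplacian PCA, and mRMR ranking + sequential
  forward selection;
* a leakage-free evaluation protocol (`runLopo`): leave-one-patient-out,
  per-fold z-scoring, SMOTE on fused training scores, nested stratified
  tuning of an RBF-SVM or kNN, pooled metrics (Sn, Sp, ACC, BACC, F1, AUC)
  with seeded bootstrap, Welch t-tests on components with Bonferroni
  correction, and the McNemar χ² = (b−c)²/(b+c) comparison at the 3.84
  threshold;
* a seeded synthetic generator (`simulateMultimodal`) with known latent
  manifold, per-block class factors, correlated noise, and optional
  heavy-tailed row contamination, plus a low-rank + sparse fixture
  generator for the robust-PCA path;
* delimited-text I/O (`writeFeatureTables`/`readFeatureTables`) and a thin
  CLI (`inst/cli/epcafuse.R`: `simulate | fuse | evaluate | compare`).

## Worked example

```r
library(epcaFusion)

d <- simulateMultimodal(n = 71, pCt = 70, pQus = 476, seed = 7)
d
#> class: MultimodalRadiomics
#> dim: 546 71
#> modalities: CT(70) QUS(476)
#> labels: CR(25) PR(46)

x <- cbind(modalityBlock(d, "CT"), modalityBlock(d, "QUS"))
m <- epca(x, k = 6, lambda = 0.01, alpha = 0.01)
m
#> EPCAModel (l21m2 penalty): p=546 features, n=71 samples, k=6
#>   lambda=0.01 alpha=0.01, 3 iterations, converged: TRUE

rankFeaturesByLoading(m, colnames(x), topM = 5)
#>    feature    score
#> 1 QUS_f459 8.128417
#> 2 QUS_f468 8.053631
#> 3 QUS_f475 8.023444
#> 4 QUS_f471 7.968029
#> 5 QUS_f453 7.959196

rec <- runLopo(d, method = "epca", classifier = "svm_rbf", k = 6,
               grid = expand.grid(C = c(0.1, 1, 10),
                                  gamma = c(0.01, 0.1, 1)), seed = 1)
bt <- bootstrapMetrics(rec, B = 1000, seed = 1)
round(rbind(mean = bt$mean, sd = bt$sd), 3)
#>         Sn    Sp   ACC  BACC    F1   AUC
#> mean 0.694 0.638 0.674 0.666 0.732 0.658
#> sd   0.071 0.099 0.056 0.060 0.055 0.077
```

The top-ranked loadings all sit in the generator's planted informative QUS
columns, and the pooled LOPO balanced accuracy of 0.67 ± 0.06 reflects the
generator's per-block class separation of 1 at 71 patients. On this seed,
`componentTtest(sampleComponents(m), responseLabels(d), mCorrections = 6)`
gives component 4 the smallest p-value (0.012, short of the Bonferroni
threshold 0.05/6 ≈ 0.0083).

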