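# Uniform fuser interface: every fusion method is fitted on training blocks
# only and maps arbitrary samples to fused coordinates with training-side
# parameters, so the evaluation protocol can swap methods freely.

.fuserMethods <- c("epca", "pca", "kpca", "cca", "rpca", "l21lap",
                   "mrmr_sfs", "passthrough")

#' Fit a feature fuser on training blocks
#'
#' \code{method} selects the fusion model: \code{"epca"} (Hessian-graph
#' l2,1-2 sparse PCA), \code{"pca"}, \code{"kpca"} (RBF kernel PCA),
#' \code{"cca"} (ridge CCA fusion of the two blocks), \code{"rpca"}
#' (robust-PCA low-rank part + PCA), \code{"l21lap"} (l2,1 graph-Laplacian
#' PCA), \code{"mrmr_sfs"} (mRMR ranking + sequential forward selection;
#' supervised), or \code{"passthrough"} (concatenated features unchanged;
#' useful for protocol checks). Blocks are assumed already standardized by
#' the caller (the LOPO driver z-scores per fold).
#'
#' @param xCt n x p1 training CT block
#' @param xQus n x p2 training QUS block
#' @param labels training labels (needed by mrmr_sfs only)
#' @param method fuser identifier
#' @param k fused dimension (ignored by mrmr_sfs / passthrough)
#' @param lambda,alpha EPCA / l21lap regularization weights
#' @param kNN,d graph construction parameters
#' @param gamma RBF width for kpca (default 1/(p1+p2))
#' @param ridge CCA ridge fraction
#' @param seed seed for seeded sub-procedures (SFS folds)
#' @param sfsClassifier classifier used to score SFS prefixes
#' @return a \linkS4class{FusionModel}
#' @export
fitFusion <- function(xCt, xQus, labels = NULL,
                      method = .fuserMethods, k = 6L,
                      lambda = 1e-2, alpha = 1e-2, kNN = 12L, d = 2L,
                      gamma = NULL, ridge = 0.1, seed = 1L,
                      sfsClassifier = "svm_rbf") {
    method <- match.arg(method)
    xCt <- as.matrix(xCt); xQus <- as.matrix(xQus)
    xAll <- cbind(xCt, xQus)
    n <- nrow(xAll)
    kNN <- min(kNN, n - 2L)
    k <- min(k, n - 1L, ncol(xAll))
    fit <- switch(method,
        epca = list(model = epca(xAll, k = k, lambda = lambda, alpha = alpha,
                                 kNN = kNN, d = d, standardize = FALSE)),
        pca = list(emb = pcaEmbed(xAll, NULL, k)),
        kpca = {
            if (is.null(gamma)) gamma <- 1 / ncol(xAll)
            list(emb = kpcaEmbed(xAll, NULL, k, gamma), gamma = gamma)
        },
        cca = {
            kk <- min(k, ncol(xCt), ncol(xQus))
            list(cca = ccaFuse(xCt, xQus, NULL, NULL, kk, ridge))
        },
        rpca = list(emb = rpcaFuse(xAll, NULL, k)),
        l21lap = list(model = l21LaplacianPca(xAll, k = k, lambda = lambda,
                                              alpha = alpha, kNN = kNN,
                                              standardize = FALSE)),
        mrmr_sfs = {
            if (is.null(labels)) stop("mrmr_sfs requires training labels")
            rk <- mrmrRank(xAll, labels)
            sel <- sfsSelect(rk, xAll, labels, classifier = sfsClassifier,
                             seed = seed)
            list(selection = sel)
        },
        passthrough = list())
    methods::new("FusionModel", method = method, k = as.integer(k),
                 fit = c(fit, list(p1 = ncol(xCt), p2 = ncol(xQus))))
}

#' Map samples to the fused feature space
#'
#' Uses exclusively training-fitted parameters; the rows of the inputs are
#' mapped independently, so held-out samples cannot influence each other.
#'
#' @param object a \linkS4class{FusionModel}
#' @param xCt,xQus samples x features blocks on the training scale
#' @return matrix of fused coordinates, one row per sample
#' @export
predictFusion <- function(object, xCt, xQus) {
    stopifnot(is(object, "FusionModel"))
    xCt <- matrix(as.matrix(xCt), ncol = object@fit$p1)
    xQus <- matrix(as.matrix(xQus), ncol = object@fit$p2)
    xAll <- cbind(xCt, xQus)
    f <- object@fit
    out <- switch(object@method,
        epca = ,
        l21lap = {
            v <- projectSamples(f$model, xAll, standardized = TRUE)
            matrix(v, nrow = nrow(xAll))
        },
        pca = scale(xAll, f$emb$center, FALSE) %*% f$emb$rotation,
        kpca = {
            te <- kernlab::predict(f$emb$fit, xAll)
            te[, seq_len(object@k), drop = FALSE]
        },
        cca = sweep(xCt, 2, f$cca$center1) %*% f$cca$w1 +
              sweep(xQus, 2, f$cca$center2) %*% f$cca$w2,
        rpca = scale(xAll, f$emb$center, FALSE) %*% f$emb$rotation,
        mrmr_sfs = xAll[, f$selection$selected, drop = FALSE],
        passthrough = xAll)
    as.matrix(out)
}
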