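#' @import methods
#' @importFrom stats cor dist median prcomp predict qchisq quantile rbinom
#'   rnorm rt runif sd t.test var setNames
#' @importFrom utils read.csv write.csv write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Two-modality radiomic feature container
#'
#' Extends \linkS4class{SummarizedExperiment}: one assay \code{"features"}
#' holding the features x samples matrix for both modality blocks stacked
#' row-wise, a \code{modality} column in \code{rowData} tagging each feature
#' as \code{"CT"} or \code{"QUS"}, and a binary \code{label} column
#' (\code{"CR"} / \code{"PR"}) in \code{colData}. Simulated datasets carry
#' their generating ground truth in \code{metadata(x)$truth}.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @export
setClass("MultimodalRadiomics", contains = "SummarizedExperiment")

setValidity("MultimodalRadiomics", function(object) {
    msg <- NULL
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is missing")
    rd <- SummarizedExperiment::rowData(object)
    if (!"modality" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a 'modality' column")
    else if (!all(rd$modality %in% c("CT", "QUS")))
        msg <- c(msg, "modality must be 'CT' or 'QUS'")
    cd <- SummarizedExperiment::colData(object)
    if (!"label" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(as.character(cd$label) %in% c("CR", "PR")))
        msg <- c(msg, "labels must be 'CR' or 'PR'")
    if (is.null(msg)) TRUE else msg
})

#' Hessian-energy graph regularizer
#'
#' Symmetric positive-semidefinite n x n matrix accumulating the per-patch
#' quadratic forms that estimate local second-order (Hessian) energy of a
#' function sampled at the n points. Functions that vary linearly along the
#' underlying manifold lie in its (approximate) null space, so penalizing
#' \eqn{Tr(V^T H V)} pulls low-dimensional sample components toward
#' geodesic-linear behaviour rather than the constancy bias of a graph
#' Laplacian.
#'
#' @slot H symmetric n x n matrix
#' @slot kNN neighborhood size used in construction
#' @slot d assumed intrinsic manifold dimension
#' @slot psdFloor relative eigenvalue clipping tolerance
#' @slot flagged integer indices of samples whose local patch was degenerate
#' @export
setClass("HessianGraph",
    representation(H = "matrix", kNN = "integer", d = "integer",
                   psdFloor = "numeric", flagged = "integer"))

setValidity("HessianGraph", function(object) {
    H <- object@H
    if (nrow(H) != ncol(H)) return("H must be square")
    if (max(abs(H - t(H))) > 0) return("H must be exactly symmetric")
    TRUE
})

#' Graph Laplacian regularizer
#'
#' kNN heat-kernel graph Laplacian L = D - W (union symmetrization), the
#' first-order counterpart of \linkS4class{HessianGraph}.
#'
#' @slot L symmetric n x n PSD matrix with zero row sums
#' @slot kNN neighborhood size
#' @slot bandwidth heat-kernel bandwidth
#' @export
setClass("LaplacianGraph",
    representation(L = "matrix", kNN = "integer", bandwidth = "numeric"))

#' Fitted graph-regularized sparse PCA model
#'
#' Holds the factorization X ~ U V^T (X features x samples): principal
#' directions \code{U} (p x k, row-sparse under the penalty), orthonormal
#' sample components \code{V} (n x k), the eigenvalues of the surrogate
#' matrix for the selected components, the per-iteration objective trace,
#' the diagonal update operator at convergence, and the training-feature
#' standardization constants needed for out-of-sample projection.
#'
#' @slot U p x k principal directions
#' @slot V n x k orthonormal sample components
#' @slot eigenvalues eigenvalues of the surrogate matrix (ascending)
#' @slot objectiveTrace objective value per iteration
#' @slot ADiag diagonal of the update operator A at convergence
#' @slot config list of fitting parameters
#' @slot center,scale training feature means / sds (length p)
#' @slot converged logical
#' @slot penalty "l21m2" (l2,1 - Frobenius) or "l21"
#' @export
setClass("EPCAModel",
    representation(U = "matrix", V = "matrix", eigenvalues = "numeric",
                   objectiveTrace = "numeric", ADiag = "numeric",
                   config = "list", center = "numeric", scale = "numeric",
                   converged = "logical", penalty = "character"))

setValidity("EPCAModel", function(object) {
    msg <- NULL
    if (ncol(object@U) != ncol(object@V))
        msg <- c(msg, "U and V must have the same number of columns")
    VtV <- crossprod(object@V)
    if (max(abs(VtV - diag(ncol(VtV)))) > 1e-8)
        msg <- c(msg, "V columns must be orthonormal")
    if (!all(is.finite(object@U)) || !all(is.finite(object@V)))
        msg <- c(msg, "factors must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Robust PCA decomposition X = Z + S
#'
#' Low-rank plus sparse split obtained by ADMM on the nuclear-norm /
#' l1 objective.
#'
#' @slot Z low-rank component
#' @slot S sparse component
#' @slot lambda sparsity trade-off used
#' @slot residual final relative residual ||X - Z - S||_F / ||X||_F
#' @slot iterations iterations run
#' @slot converged logical
#' @export
setClass("RPCADecomposition",
    representation(Z = "matrix", S = "matrix", lambda = "numeric",
                   residual = "numeric", iterations = "integer",
                   converged = "logical"))

#' Uniform fuser wrapper
#'
#' Every fusion method (epca, pca, kpca, cca, rpca, l21lap, mrmr_sfs)
#' is fitted into a FusionModel so the evaluation protocol can treat them
#' interchangeably: fit on training blocks, then map any sample to the fused
#' feature space with \code{\link{predictFusion}}.
#'
#' @slot method fuser identifier
#' @slot k fused dimension
#' @slot fit method-specific fitted state
#' @export
setClass("FusionModel",
    representation(method = "character", k = "integer", fit = "list"))

setMethod("show", "MultimodalRadiomics", function(object) {
    callNextMethod()
    md <- SummarizedExperiment::rowData(object)$modality
    cat("modalities:", paste(sprintf("%s(%d)", names(table(md)), table(md)),
        collapse = " "), "\n")
    cat("labels:", paste(sprintf("%s(%d)",
        names(table(object$label)), table(object$label)), collapse = " "), "\n")
})

setMethod("show", "HessianGraph", function(object) {
    ev <- eigen(object@H, symmetric = TRUE, only.values = TRUE)$values
    cat(sprintf("HessianGraph: %d samples, kNN=%d, d=%d\n",
        nrow(object@H), object@kNN, object@d))
    cat(sprintf("  eigenvalue range [%.3g, %.3g], null dim (<1e-8*max): %d\n",
        min(ev), max(ev), sum(ev < 1e-8 * max(ev))))
})

setMethod("show", "EPCAModel", function(object) {
    rn <- sqrt(rowSums(object@U^2))
    cat(sprintf("EPCAModel (%s penalty): p=%d features, n=%d samples, k=%d\n",
        object@penalty, nrow(object@U), nrow(object@V), ncol(object@U)))
    cat(sprintf("  lambda=%g alpha=%g, %d iterations, converged: %s\n",
        object@config$lambdaSparse, object@config$alphaGraph,
        length(object@objectiveTrace), object@converged))
    cat(sprintf("  active rows of U (>1e-6*max): %d/%d\n",
        sum(rn > 1e-6 * max(rn)), length(rn)))
})

setMethod("show", "RPCADecomposition", function(object) {
    cat(sprintf("RPCADecomposition: %d x %d, lambda=%.4g\n",
        nrow(object@Z), ncol(object@Z), object@lambda))
    cat(sprintf("  rank(Z)~%d, nnz(S)=%d, residual=%.3g, %d iterations\n",
        sum(svd(object@Z, nu = 0, nv = 0)$d > 1e-8 * max(svd(object@Z,
            nu = 0, nv = 0)$d)), sum(object@S != 0), object@residual,
        object@iterations))
})

setMethod("show", "FusionModel", function(object) {
    cat(sprintf("FusionModel: method=%s, k=%d\n", object@method, object@k))
})

# ---- accessors ------------------------------------------------------------

#' Extract one modality block as a samples x features matrix
#'
#' @param x a MultimodalRadiomics object
#' @param modality "CT" or "QUS"
#' @return numeric matrix, samples in rows
#' @export
modalityBlock <- function(x, modality = c("CT", "QUS")) {
    modality <- match.arg(modality)
    stopifnot(is(x, "MultimodalRadiomics"))
    keep <- SummarizedExperiment::rowData(x)$modality == modality
    t(SummarizedExperiment::assay(x, "features")[keep, , drop = FALSE])
}

#' Binary response labels as a factor with levels CR, PR
#' @param x a MultimodalRadiomics object
#' @return factor of length n
#' @export
responseLabels <- function(x) {
    stopifnot(is(x, "MultimodalRadiomics"))
    factor(as.character(x$label), levels = c("CR", "PR"))
}

#' Ground-truth record of a simulated dataset
#' @param x a MultimodalRadiomics object created by simulateMultimodal
#' @return list with latent scores, loading supports, effect sizes, outliers
#' @export
simulationTruth <- function(x) S4Vectors::metadata(x)$truth

#' Hessian graph matrix accessor
#' @param x a HessianGraph
#' @return n x n symmetric matrix
#' @export
hessianMatrix <- function(x) { stopifnot(is(x, "HessianGraph")); x@H }

#' Laplacian matrix accessor
#' @param x a LaplacianGraph
#' @return n x n symmetric matrix
#' @export
laplacianMatrix <- function(x) { stopifnot(is(x, "LaplacianGraph")); x@L }

#' Principal direction / component accessors
#' @param x an EPCAModel
#' @return numeric matrix
#' @export
principalDirections <- function(x) { stopifnot(is(x, "EPCAModel")); x@U }

#' @rdname principalDirections
#' @export
sampleComponents <- function(x) { stopifnot(is(x, "EPCAModel")); x@V }

#' @rdname principalDirections
#' @export
objectiveTrace <- function(x) { stopifnot(is(x, "EPCAModel")); x@objectiveTrace }
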