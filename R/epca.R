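# Enhanced PCA: min_{U,V} 1/2 ||X - U V^T||_F^2 + lambda ||U||_{2,1-2}
#                          + alpha Tr(V^T H V),   s.t. V^T V = I
# with X features x samples. The non-convex row-sparsity penalty
# ||U||_{2,1-2} = ||U||_{2,1} - ||U||_F is handled by a concave-convex
# (majorize-minimize) step: the l2,1 term gets the standard IRLS quadratic
# upper bound with weights Q = diag(1/(2(||u_i|| + eps))), the concave
# -||U||_F term the tangent quadratic bound
# -||U||_F <= -||U||_F^2/(2||U'||_F) - ||U'||_F/2. Both touch at the current
# iterate, so the closed-form minimizer U = A^{-1} X V with
# A = I + 2 lambda Q - lambda ||U'||_F^{-1} I never increases the objective.
# (A is positive definite: ||u_i|| <= ||U||_F entrywise implies
# A_ii >= 1 - O(eps).) V is then the matrix of eigenvectors of the k
# smallest eigenvalues of the surrogate Psi.

#' Row-sparsity penalty ||U||_2,1 - ||U||_F
#'
#' The l2,1-2 matrix norm: sum of row-wise l2 norms minus the Frobenius
#' norm. Non-negative, zero iff U has at most one nonzero row; sparser
#' than l2,1 while remaining Lipschitz continuous.
#'
#' @param U numeric matrix
#' @return non-negative scalar
#' @examples
#' l21MinusFNorm(diag(2))  # 2 - sqrt(2)
#' @export
l21MinusFNorm <- function(U) {
    U <- as.matrix(U)
    if (!all(is.finite(U))) stop("non-finite input")
    sum(sqrt(rowSums(U^2))) - sqrt(sum(U^2))
}

.penaltyValue <- function(U, penalty) {
    rs <- sqrt(rowSums(U^2))
    if (penalty == "l21m2") sum(rs) - sqrt(sum(U^2)) else sum(rs)
}

#' Full objective of the graph-regularized sparse PCA problem
#'
#' @param X p x n matrix (features x samples)
#' @param U p x k principal directions
#' @param V n x k sample components
#' @param H n x n graph regularizer matrix (Hessian or Laplacian)
#' @param lambda sparsity weight
#' @param alpha graph weight
#' @param penalty "l21m2" or "l21"
#' @return scalar objective value
#' @export
epcaObjective <- function(X, U, V, H, lambda, alpha, penalty = "l21m2") {
    if (nrow(U) != nrow(X) || nrow(V) != ncol(X) || ncol(U) != ncol(V))
        stop("shape mismatch")
    if (!is.null(H) && (nrow(H) != ncol(X))) stop("graph dimension mismatch")
    R <- X - tcrossprod(U, V)
    g <- if (alpha != 0 && !is.null(H)) alpha * sum(V * (H %*% V)) else 0
    0.5 * sum(R^2) + lambda * .penaltyValue(U, penalty) + g
}

#' Closed-form concave-convex update of the principal directions
#'
#' Builds Q = diag(1/(2(||u_i|| + epsilon))) and the linearized concave-term
#' gradient g = U / ||U||_F from the previous iterate, forms the diagonal
#' operator A = I + 2 lambda Q - lambda ||U||_F^{-1} I (the Frobenius
#' subtraction is absent for the plain l2,1 penalty), and returns
#' U = A^{-1} X V. The step is safeguarded: if A loses positive definiteness
#' (possible at strong sparsity once U collapses toward a single row), or
#' if the candidate would increase the CCCP-majorized objective
#' J(U) = 1/2 ||X - U V^T||_F^2 + lambda (Tr(U^T Q U) - <U, g>), the exact
#' minimizer of J, U = (I + 2 lambda Q)^{-1} (X V + lambda g), is used
#' instead (with a warning in the indefinite case). Either way the returned
#' U never increases J, hence never the true objective.
#'
#' @param X p x n matrix
#' @param V n x k with orthonormal columns
#' @param Uprev previous p x k iterate
#' @param lambda sparsity weight
#' @param epsilon denominator guard (> 0)
#' @param penalty "l21m2" or "l21"
#' @return list with the new \code{U} and the diagonal \code{ADiag} of A
#' @export
epcaUpdateU <- function(X, V, Uprev, lambda, epsilon = 1e-8,
                        penalty = "l21m2") {
    rn <- sqrt(rowSums(Uprev^2))
    q <- 1 / (2 * (rn + epsilon))
    fro <- sqrt(sum(Uprev^2))
    s <- if (penalty == "l21m2" && fro > 0) 1 / fro else 0
    a <- 1 + 2 * lambda * q - lambda * s
    XV <- X %*% V
    g <- if (s > 0) Uprev * s else 0 * Uprev
    Jmaj <- function(U)
        0.5 * sum((X - tcrossprod(U, V))^2) +
            lambda * (sum(q * rowSums(U^2)) - sum(U * g))
    exactStep <- function() (XV + lambda * g) / (1 + 2 * lambda * q)
    if (any(a <= 1e-10)) {
        warning("update operator not positive definite; using exact CCCP step")
        Unew <- exactStep()
    } else {
        Unew <- XV / a
        if (lambda > 0 && Jmaj(Unew) > Jmaj(Uprev))
            Unew <- exactStep()
    }
    list(U = Unew, ADiag = a)
}

#' Eigenvector update of the orthonormal sample components
#'
#' Forms the surrogate matrix Psi and returns the eigenvectors of its k
#' smallest eigenvalues (ascending; in the unregularized limit this is the
#' descending-variance PCA order), with deterministic column signs.
#' \code{psiForm = "mm"} (default) uses Psi = -X^T A^{-1} X + 2 alpha H,
#' the exact minimization over V of the joint quadratic surrogate after
#' eliminating U = A^{-1} X V: with it the alternation is a true
#' majorize-minimize scheme and the objective trace is provably
#' non-increasing. \code{"derived"}, Psi = X^T (A^-2 - 2 A^-1) X +
#' 2 alpha H, substitutes U = A^{-1} X V into the reconstruction term only
#' (it ignores the penalty's dependence on V and can climb slightly at
#' strong sparsity); \code{"literal"} uses X^T (2 A^-1 + A^-2) X +
#' 2 alpha H. "mm" and "derived" coincide with -X^T X when
#' lambda = alpha = 0, so both reduce to PCA; the literal form does not.
#'
#' @param X p x n matrix
#' @param ADiag diagonal of the update operator A from the U-step
#' @param H n x n graph matrix (or NULL when alpha = 0)
#' @param alpha graph weight
#' @param k number of components (<= n)
#' @param psiForm "mm", "derived" or "literal"
#' @return list with \code{V} (n x k orthonormal) and \code{values}
#'   (the k selected eigenvalues of Psi, ascending)
#' @export
epcaUpdateV <- function(X, ADiag, H, alpha, k, psiForm = "mm") {
    n <- ncol(X)
    if (k > n) stop("k must be <= n")
    ai <- 1 / ADiag
    w <- switch(match.arg(psiForm, c("mm", "derived", "literal")),
        mm = -ai,
        derived = ai^2 - 2 * ai,
        literal = 2 * ai + ai^2)
    Psi <- crossprod(X, w * X)  # X^T diag(w) X; w scales the p rows of X
    if (alpha != 0 && !is.null(H)) Psi <- Psi + 2 * alpha * H
    Psi <- (Psi + t(Psi)) / 2
    eg <- eigen(Psi, symmetric = TRUE)
    sel <- seq(n, n - k + 1)            # eigen() sorts decreasing
    V <- .signFix(eg$vectors[, sel, drop = FALSE])
    list(V = V, values = eg$values[sel])
}

# shared alternating solver; X is p x n and already standardized
.graphSparsePcaFit <- function(X, G, k, lambda, alpha, epsilon = 1e-8,
                               maxIter = 100L, relTol = 1e-6,
                               psiForm = "mm", penalty = "l21m2",
                               center = rep(0, nrow(X)),
                               scale = rep(1, nrow(X))) {
    p <- nrow(X); n <- ncol(X)
    if (k > min(p, n)) stop("k must be <= min(p, n)")
    if (!is.null(G) && nrow(G) != n) stop("graph dimension must equal n")
    X <- unname(X); center <- unname(center); scale <- unname(scale)
    sv <- svd(X, nu = 0, nv = k)
    V <- .signFix(sv$v[, seq_len(k), drop = FALSE])
    U <- X %*% V
    obj <- epcaObjective(X, U, V, G, lambda, alpha, penalty)
    trace <- obj
    ADiag <- rep(1, p)
    vals <- rep(NA_real_, k)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        us <- epcaUpdateU(X, V, U, lambda, epsilon, penalty)
        ADiag <- us$ADiag
        objU <- epcaObjective(X, us$U, V, G, lambda, alpha, penalty)
        if (objU <= obj) { U <- us$U; obj <- objU }
        # eigen V-step on the surrogate; accepted only if the true objective
        # does not increase (monotone safeguard; rejections only occur in
        # degenerate strong-sparsity regimes and then trigger convergence)
        vs <- epcaUpdateV(X, ADiag, G, alpha, k, psiForm)
        Ucand <- (X %*% vs$V) / ADiag
        objV <- epcaObjective(X, Ucand, vs$V, G, lambda, alpha, penalty)
        if (objV <= obj) {
            V <- vs$V; U <- Ucand; vals <- vs$values; obj <- objV
        }
        trace <- c(trace, obj)
        if (abs(trace[it] - obj) <= relTol * max(abs(trace[it]), 1e-12)) {
            converged <- TRUE
            break
        }
    }
    methods::new("EPCAModel", U = U, V = V, eigenvalues = vals,
        objectiveTrace = trace, ADiag = ADiag,
        config = list(k = k, lambdaSparse = lambda, alphaGraph = alpha,
                      epsilon = epsilon, maxIter = maxIter, relTol = relTol,
                      psiForm = psiForm),
        center = center, scale = scale, converged = converged,
        penalty = penalty)
}

#' Fit the enhanced PCA fusion model
#'
#' Standardizes features (unless \code{standardize = FALSE}), builds or
#' accepts a Hessian graph over the samples, and runs the alternating
#' CCCP / eigenvector solver. Initialization is deterministic (plain PCA),
#' so refitting with identical inputs reproduces the model exactly.
#'
#' @param x n x p matrix, samples in rows (both modality blocks already
#'   concatenated), or a \linkS4class{MultimodalRadiomics}
#' @param k number of fused components (default 6)
#' @param lambda sparsity weight (>= 0)
#' @param alpha graph weight (>= 0)
#' @param graph a \linkS4class{HessianGraph} over the same samples, or NULL
#'   to build one (kNN, d below); ignored when alpha = 0
#' @param kNN,d Hessian construction parameters used when graph is NULL
#' @param epsilon denominator guard of the reweighting
#' @param maxIter,relTol convergence controls (relative objective change)
#' @param psiForm surrogate form for the V-step: "mm" (default,
#'   guaranteed-descent), "derived", or "literal" (the latter two kept for
#'   fidelity experiments; see \code{\link{epcaUpdateV}})
#' @param standardize z-score the features before fitting (constants stored
#'   in the model for projection)
#' @return an \linkS4class{EPCAModel}
#' @examples
#' d <- simulateMultimodal(n = 40, pCt = 10, pQus = 20, seed = 7)
#' x <- cbind(modalityBlock(d, "CT"), modalityBlock(d, "QUS"))
#' m <- epca(x, k = 4, lambda = 0.1, alpha = 0.1, kNN = 8)
#' @export
epca <- function(x, k = 6L, lambda = 0, alpha = 0, graph = NULL,
                 kNN = 12L, d = 2L, epsilon = 1e-8, maxIter = 100L,
                 relTol = 1e-6, psiForm = c("mm", "derived", "literal"),
                 standardize = TRUE) {
    psiForm <- match.arg(psiForm)
    if (is(x, "MultimodalRadiomics"))
        x <- cbind(modalityBlock(x, "CT"), modalityBlock(x, "QUS"))
    x <- as.matrix(x)
    if (lambda < 0 || alpha < 0) stop("lambda and alpha must be >= 0")
    if (standardize) {
        ctr <- colMeans(x)
        scl <- apply(x, 2, sd)
        scl[scl == 0] <- 1
        x <- scale(x, ctr, scl)
    } else {
        ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    }
    G <- NULL
    if (alpha > 0) {
        if (is.null(graph)) graph <- hessianGraph(x, kNN = kNN, d = d)
        stopifnot(is(graph, "HessianGraph"))
        G <- graph@H
    }
    .graphSparsePcaFit(t(x), G, k, lambda, alpha, epsilon, maxIter, relTol,
                       psiForm, "l21m2", center = ctr, scale = scl)
}

#' Project new samples onto a fitted model's components
#'
#' Applies the training standardization and returns the least-squares
#' coordinates v = (U^T U)^{-1} U^T x (pseudo-inverse with 1e-10 relative
#' cutoff when U^T U is singular). For a vector x, returns a length-k vector;
#' for an m x p matrix, an m x k matrix.
#'
#' @param model an \linkS4class{EPCAModel}
#' @param xNew length-p vector or m x p matrix of raw (unstandardized)
#'   samples
#' @param standardized set TRUE if xNew is already on the training scale
#' @return fused coordinates
#' @export
projectSamples <- function(model, xNew, standardized = FALSE) {
    stopifnot(is(model, "EPCAModel"))
    U <- model@U
    if (is.null(dim(xNew))) xNew <- matrix(xNew, nrow = 1)
    xNew <- as.matrix(xNew)
    if (ncol(xNew) != nrow(U)) stop("feature dimension mismatch")
    if (!standardized)
        xNew <- scale(xNew, model@center, model@scale)
    G <- crossprod(U)
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > 1e-10 * max(eg$values, 0)
    if (!any(keep)) return(matrix(0, nrow(xNew), ncol(U)))
    Ginv <- eg$vectors[, keep, drop = FALSE] %*%
        (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
    out <- xNew %*% U %*% Ginv
    if (nrow(out) == 1) drop(out) else out
}

#' Rank original features by their loading contribution
#'
#' Scores each feature by the l2 norm of its row of U restricted to the
#' selected components ("loading vector" contribution), and returns the
#' topM features in descending score order, ties broken alphabetically.
#'
#' @param model an \linkS4class{EPCAModel}
#' @param featureNames character vector of length p
#' @param topM how many features to return
#' @param components which components to restrict to (default all)
#' @return data.frame with columns feature, score, in rank order
#' @export
rankFeaturesByLoading <- function(model, featureNames,
                                  topM = 10L, components = NULL) {
    stopifnot(is(model, "EPCAModel"))
    U <- model@U
    if (length(featureNames) != nrow(U))
        stop("featureNames length must equal the number of features")
    if (topM > nrow(U)) stop("topM exceeds the number of features")
    if (is.null(components)) components <- seq_len(ncol(U))
    sc <- sqrt(rowSums(U[, components, drop = FALSE]^2))
    o <- order(-sc, featureNames)
    data.frame(feature = featureNames[o][seq_len(topM)],
               score = sc[o][seq_len(topM)], stringsAsFactors = FALSE)
}

#' Lossless plain-text model serialization
#'
#' Writes/reads U, V, eigenvalues, objective trace, A diagonal, the fitting
#' configuration and the standardization constants at full double precision
#' ("%.17g"), so a round trip reproduces the model bit-exactly.
#'
#' @param model an EPCAModel
#' @param path file path
#' @return \code{readEpcaModel} returns the model
#' @export
writeEpcaModel <- function(model, path) {
    stopifnot(is(model, "EPCAModel"))
    num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
    cfg <- model@config
    lines <- c(
        sprintf("epcaFusionModel 1"),
        sprintf("penalty %s", model@penalty),
        sprintf("psiForm %s", cfg$psiForm),
        sprintf("dims %d %d %d", nrow(model@U), nrow(model@V), ncol(model@U)),
        sprintf("k %d", cfg$k),
        sprintf("lambda %.17g", cfg$lambdaSparse),
        sprintf("alpha %.17g", cfg$alphaGraph),
        sprintf("epsilon %.17g", cfg$epsilon),
        sprintf("maxIter %d", cfg$maxIter),
        sprintf("relTol %.17g", cfg$relTol),
        sprintf("converged %d", as.integer(model@converged)),
        paste("U", num(model@U)),
        paste("V", num(model@V)),
        paste("eigenvalues", num(model@eigenvalues)),
        paste("objectiveTrace", num(model@objectiveTrace)),
        paste("ADiag", num(model@ADiag)),
        paste("center", num(model@center)),
        paste("scale", num(model@scale)))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeEpcaModel
#' @export
readEpcaModel <- function(path) {
    lines <- readLines(path)
    kv <- function(key) {
        ln <- lines[startsWith(lines, paste0(key, " "))][1]
        substring(ln, nchar(key) + 2)
    }
    nums <- function(key) as.numeric(strsplit(kv(key), " ")[[1]])
    dims <- as.integer(strsplit(kv("dims"), " ")[[1]])
    methods::new("EPCAModel",
        U = matrix(nums("U"), dims[1], dims[3]),
        V = matrix(nums("V"), dims[2], dims[3]),
        eigenvalues = nums("eigenvalues"),
        objectiveTrace = nums("objectiveTrace"),
        ADiag = nums("ADiag"),
        config = list(k = as.integer(kv("k")),
                      lambdaSparse = as.numeric(kv("lambda")),
                      alphaGraph = as.numeric(kv("alpha")),
                      epsilon = as.numeric(kv("epsilon")),
                      maxIter = as.integer(kv("maxIter")),
                      relTol = as.numeric(kv("relTol")),
                      psiForm = kv("psiForm")),
        center = nums("center"), scale = nums("scale"),
        converged = as.logical(as.integer(kv("converged"))),
        penalty = kv("penalty"))
}
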