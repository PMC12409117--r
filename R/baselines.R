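# Comparator fusers. Each exposes a fit-on-train / map-test surface so the
# evaluation protocol never touches held-out samples during fitting.

#' Plain PCA embedding with out-of-sample projection
#'
#' PCA is fitted on the training table only; test samples are projected
#' with the training loadings and centering.
#'
#' @param xTrain n x p training matrix
#' @param xTest m x p test matrix (or NULL)
#' @param k number of components
#' @return list with \code{train} (n x k scores), \code{test} (m x k),
#'   \code{rotation}, \code{center}
#' @export
pcaEmbed <- function(xTrain, xTest = NULL, k) {
    xTrain <- as.matrix(xTrain)
    pc <- prcomp(xTrain, center = TRUE, scale. = FALSE)
    if (k > ncol(pc$rotation)) stop("k exceeds the available rank")
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    tr <- pc$x[, seq_len(k), drop = FALSE]
    te <- NULL
    if (!is.null(xTest))
        te <- scale(as.matrix(xTest), pc$center, FALSE) %*% rot
    list(train = tr, test = te, rotation = rot, center = pc$center)
}

#' RBF kernel PCA embedding
#'
#' Kernel PCA (Gaussian kernel exp(-gamma ||x - y||^2)) fitted on training
#' samples; test samples mapped through the centered cross-kernel.
#'
#' @param xTrain,xTest as in \code{\link{pcaEmbed}}
#' @param k components
#' @param gamma RBF width (> 0)
#' @return list with \code{train}, \code{test}, and the fitted kernlab object
#' @export
kpcaEmbed <- function(xTrain, xTest = NULL, k, gamma) {
    if (gamma <= 0) stop("gamma must be > 0")
    xTrain <- as.matrix(xTrain)
    kp <- kernlab::kpca(xTrain, kernel = "rbfdot",
                        kpar = list(sigma = gamma), features = k)
    tr <- kernlab::rotated(kp)
    te <- NULL
    if (!is.null(xTest))
        te <- kernlab::predict(kp, as.matrix(xTest))
    list(train = tr[, seq_len(k), drop = FALSE],
         test = if (is.null(te)) NULL else te[, seq_len(k), drop = FALSE],
         fit = kp)
}

#' Ridge-regularized CCA feature fusion
#'
#' Canonical correlation analysis between the two training blocks with a
#' ridge on each within-block covariance (necessary when a block has more
#' features than samples). The fused representation is the sum of the two
#' blocks' canonical variates for the first k pairs; test samples are mapped
#' with the training weights and centers.
#'
#' @param x1Train,x2Train n x p1 / n x p2 training blocks
#' @param x1Test,x2Test test blocks (or NULL)
#' @param k number of canonical pairs
#' @param ridge ridge fraction of the mean covariance diagonal (default 0.1)
#' @return list with \code{train}, \code{test}, canonical correlations
#'   \code{cor}, weights \code{w1}, \code{w2}, centers
#' @export
ccaFuse <- function(x1Train, x2Train, x1Test = NULL, x2Test = NULL, k,
                    ridge = 0.1) {
    x1Train <- as.matrix(x1Train); x2Train <- as.matrix(x2Train)
    n <- nrow(x1Train)
    if (ridge <= 0 && (ncol(x1Train) >= n || ncol(x2Train) >= n))
        stop("ridge must be > 0 when a block has more features than samples")
    c1 <- colMeans(x1Train); c2 <- colMeans(x2Train)
    X1 <- sweep(x1Train, 2, c1); X2 <- sweep(x2Train, 2, c2)
    S11 <- crossprod(X1) / (n - 1); S22 <- crossprod(X2) / (n - 1)
    S12 <- crossprod(X1, X2) / (n - 1)
    r1 <- ridge * mean(diag(S11)); r2 <- ridge * mean(diag(S22))
    isq <- function(S, r) {
        eg <- eigen(S + r * diag(nrow(S)), symmetric = TRUE)
        vals <- pmax(eg$values, max(eg$values) * 1e-12)
        eg$vectors %*% (t(eg$vectors) / sqrt(vals))
    }
    W1 <- isq(S11, r1); W2 <- isq(S22, r2)
    M <- W1 %*% S12 %*% W2
    sv <- svd(M)
    if (k > length(sv$d)) stop("k exceeds the number of canonical pairs")
    w1 <- W1 %*% sv$u[, seq_len(k), drop = FALSE]
    w2 <- W2 %*% sv$v[, seq_len(k), drop = FALSE]
    # sign-fix w1 deterministically; flip w2 with it to keep pairs aligned
    for (j in seq_len(k)) {
        i <- which.max(abs(w1[, j]))
        if (w1[i, j] < 0) { w1[, j] <- -w1[, j]; w2[, j] <- -w2[, j] }
    }
    tr <- X1 %*% w1 + X2 %*% w2
    te <- NULL
    if (!is.null(x1Test))
        te <- sweep(as.matrix(x1Test), 2, c1) %*% w1 +
              sweep(as.matrix(x2Test), 2, c2) %*% w2
    list(train = tr, test = te, cor = sv$d[seq_len(k)], w1 = w1, w2 = w2,
         center1 = c1, center2 = c2)
}

#' Robust PCA by ADMM: X = Z + S
#'
#' Minimizes ||Z||_* + lambda ||S||_1 subject to X = Z + S, alternating
#' singular-value thresholding for the low-rank part, entrywise soft
#' thresholding for the sparse part, and a dual ascent step, until the
#' relative residual ||X - Z - S||_F / ||X||_F drops below tol.
#'
#' @param X n x p matrix
#' @param lambda sparsity trade-off (default 1/sqrt(max(n, p)))
#' @param rho ADMM penalty parameter
#' @param tol relative residual tolerance
#' @param maxIter iteration cap
#' @return an \linkS4class{RPCADecomposition}
#' @examples
#' f <- simulateLowRankSparse(60, 40, r = 2, sparseFraction = 0.02, seed = 3)
#' dec <- rpcaAdmm(f$observed)
#' norm(dec@Z - f$lowRank, "F") / norm(f$lowRank, "F")
#' @export
rpcaAdmm <- function(X, lambda = 1 / sqrt(max(dim(X))), rho = 1,
                     tol = 1e-7, maxIter = 500L) {
    X <- as.matrix(X)
    if (lambda <= 0) stop("lambda must be > 0")
    normX <- sqrt(sum(X^2))
    if (normX == 0) normX <- 1
    S <- matrix(0, nrow(X), ncol(X))
    Y <- matrix(0, nrow(X), ncol(X))
    Z <- X
    res <- Inf
    it <- 0L
    svt <- function(M, tau) {
        sv <- svd(M)
        dd <- pmax(sv$d - tau, 0)
        keep <- dd > 0
        if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
        sv$u[, keep, drop = FALSE] %*% (dd[keep] * t(sv$v[, keep, drop = FALSE]))
    }
    soft <- function(M, tau) sign(M) * pmax(abs(M) - tau, 0)
    for (it in seq_len(maxIter)) {
        Z <- svt(X - S + Y / rho, 1 / rho)
        S <- soft(X - Z + Y / rho, lambda / rho)
        R <- X - Z - S
        Y <- Y + rho * R
        res <- sqrt(sum(R^2)) / normX
        if (res < tol) break
    }
    methods::new("RPCADecomposition", Z = Z, S = S, lambda = lambda,
                 residual = res, iterations = it, converged = res < tol)
}

#' Robust-PCA fusion: PCA on the recovered low-rank part
#'
#' Decomposes the training table with \code{\link{rpcaAdmm}} and fits plain
#' PCA on the low-rank component Z; test samples are projected with those
#' loadings.
#'
#' @inheritParams pcaEmbed
#' @param lambda rPCA sparsity trade-off
#' @return as \code{\link{pcaEmbed}}, plus the decomposition
#' @export
rpcaFuse <- function(xTrain, xTest = NULL, k,
                     lambda = 1 / sqrt(max(dim(as.matrix(xTrain))))) {
    dec <- rpcaAdmm(as.matrix(xTrain), lambda = lambda)
    emb <- pcaEmbed(dec@Z, xTest, k)
    # training scores from projecting the observed training rows is the
    # leakage-free map used for test; report Z-scores for the train rows
    c(emb, list(decomposition = dec))
}

#' kNN heat-kernel graph Laplacian
#'
#' Union-symmetrized kNN adjacency with weights exp(-||xi - xj||^2 / bw^2);
#' L = D - W. Zero row sums by construction; PSD.
#'
#' @param samples n x p matrix
#' @param kNN neighborhood size (< n)
#' @param bandwidth heat-kernel bandwidth; default is the median pairwise
#'   distance
#' @return a \linkS4class{LaplacianGraph}
#' @export
buildLaplacian <- function(samples, kNN = 12L, bandwidth = NULL) {
    samples <- as.matrix(samples)
    n <- nrow(samples)
    if (kNN >= n) stop("kNN must be < n")
    D <- as.matrix(dist(samples))
    if (is.null(bandwidth)) bandwidth <- median(D[upper.tri(D)])
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
        o <- order(D[i, ], seq_len(n))
        o <- o[o != i][seq_len(kNN)]
        W[i, o] <- exp(-D[i, o]^2 / bandwidth^2)
    }
    W <- pmax(W, t(W))                     # union rule
    L <- diag(rowSums(W)) - W
    L <- (L + t(L)) / 2
    methods::new("LaplacianGraph", L = L, kNN = as.integer(kNN),
                 bandwidth = bandwidth)
}

#' l2,1-norm graph-Laplacian PCA
#'
#' Same alternating scheme as \code{\link{epca}} but with the convex l2,1
#' penalty (no Frobenius subtraction; the concave linearization is absent)
#' and a graph Laplacian in place of the Hessian regularizer. Shares the
#' solver code path with EPCA.
#'
#' @inheritParams epca
#' @param graph a \linkS4class{LaplacianGraph} (or NULL to build one)
#' @param bandwidth heat-kernel bandwidth when building the Laplacian
#' @return an \linkS4class{EPCAModel} with \code{penalty == "l21"}
#' @export
l21LaplacianPca <- function(x, k = 6L, lambda = 0, alpha = 0, graph = NULL,
                            kNN = 12L, bandwidth = NULL, epsilon = 1e-8,
                            maxIter = 100L, relTol = 1e-6,
                            standardize = TRUE) {
    if (is(x, "MultimodalRadiomics"))
        x <- cbind(modalityBlock(x, "CT"), modalityBlock(x, "QUS"))
    x <- as.matrix(x)
    if (standardize) {
        ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
        x <- scale(x, ctr, scl)
    } else { ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x)) }
    G <- NULL
    if (alpha > 0) {
        if (is.null(graph)) graph <- buildLaplacian(x, kNN, bandwidth)
        stopifnot(is(graph, "LaplacianGraph"))
        G <- graph@L
    }
    .graphSparsePcaFit(t(x), G, k, lambda, alpha, epsilon, maxIter, relTol,
                       "derived", "l21", center = ctr, scale = scl)
}

#' mRMR feature ranking (F-statistic / correlation quotient)
#'
#' Ranks all features by iteratively adding the feature maximizing
#' relevance / redundancy, where relevance is the two-group F statistic of
#' the feature against the binary label and redundancy is the mean absolute
#' Pearson correlation with already-ranked features. Constant features get
#' zero relevance; all ties break toward the lower column index.
#'
#' @param x n x p matrix
#' @param y binary labels (factor or 0/1), both classes present
#' @return integer vector of length p: column indices in rank order
#' @export
mrmrRank <- function(x, y) {
    x <- as.matrix(x)
    y <- as.integer(as.factor(y))
    if (length(unique(y)) != 2) stop("y must contain exactly two classes")
    p <- ncol(x)
    g1 <- y == 1
    n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
    rel <- vapply(seq_len(p), function(j) {
        v <- x[, j]
        if (var(v) == 0) return(0)
        m1 <- mean(v[g1]); m2 <- mean(v[!g1])
        ssb <- n1 * (m1 - mean(v))^2 + n2 * (m2 - mean(v))^2
        ssw <- sum((v[g1] - m1)^2) + sum((v[!g1] - m2)^2)
        if (ssw == 0) return(Inf)
        (ssb / 1) / (ssw / (n - 2))
    }, 0)
    sdv <- apply(x, 2, sd)
    ranked <- integer(0)
    remaining <- seq_len(p)
    first <- remaining[which.max(rel[remaining])]
    ranked <- first
    remaining <- setdiff(remaining, first)
    while (length(remaining) > 0) {
        red <- vapply(remaining, function(j) {
            if (sdv[j] == 0) return(1)
            cc <- abs(cor(x[, j], x[, ranked, drop = FALSE]))
            cc[!is.finite(cc)] <- 0
            mean(cc)
        }, 0)
        scoreQ <- rel[remaining] / pmax(red, 1e-12)
        scoreQ[rel[remaining] == 0] <- 0
        nxt <- remaining[which.max(scoreQ)]
        ranked <- c(ranked, nxt)
        remaining <- setdiff(remaining, nxt)
    }
    ranked
}

#' Sequential forward selection over an mRMR ranking
#'
#' Grows the prefix of the ranked feature list one feature at a time,
#' scoring each prefix by stratified inner-CV balanced accuracy of the given
#' classifier, and returns the best prefix (ties toward the smaller prefix).
#'
#' @param ranked integer vector from \code{\link{mrmrRank}}
#' @param x n x p matrix
#' @param y binary labels
#' @param classifier "svm_rbf" or "knn" (fixed default hyperparameters are
#'   used for scoring)
#' @param innerFolds stratified CV folds
#' @param maxSize largest prefix examined
#' @param seed fold-assignment seed
#' @return list with \code{ranked}, \code{selected} (the chosen prefix),
#'   \code{scoreTrace} (BACC per prefix size)
#' @export
sfsSelect <- function(ranked, x, y, classifier = c("svm_rbf", "knn"),
                      innerFolds = 5L, maxSize = min(30L, length(ranked)),
                      seed = 1L) {
    classifier <- match.arg(classifier)
    if (length(ranked) == 0) stop("ranked must be non-empty")
    x <- as.matrix(x)
    y <- factor(y)
    folds <- .stratifiedFolds(y, innerFolds, seed)
    sizes <- seq_len(min(maxSize, length(ranked)))
    scoreTrace <- vapply(sizes, function(m) {
        cols <- ranked[seq_len(m)]
        .cvBacc(x[, cols, drop = FALSE], y, folds, classifier)
    }, 0)
    best <- which.max(scoreTrace)           # which.max takes the first tie
    list(ranked = ranked, selected = ranked[seq_len(sizes[best])],
         scoreTrace = scoreTrace)
}

# inner-CV balanced accuracy with fixed default hyperparameters
.cvBacc <- function(x, y, folds, classifier) {
    preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in folds) {
        xtr <- x[-f, , drop = FALSE]; ytr <- y[-f]
        xte <- x[f, , drop = FALSE]
        if (length(unique(ytr)) < 2) next
        if (classifier == "svm_rbf") {
            fit <- e1071::svm(xtr, ytr, kernel = "radial", scale = FALSE)
            preds[f] <- predict(fit, xte)
        } else {
            kk <- min(5L, length(ytr))
            preds[f] <- class::knn(xtr, xte, ytr, k = kk)
        }
    }
    ok <- !is.na(preds)
    if (!any(ok)) return(0)
    .baccOf(y[ok], preds[ok])
}

.baccOf <- function(truth, pred) {
    lv <- levels(factor(truth))
    se <- vapply(lv, function(l) {
        idx <- truth == l
        if (!any(idx)) return(NA_real_)
        mean(pred[idx] == l)
    }, 0)
    mean(se, na.rm = TRUE)
}
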