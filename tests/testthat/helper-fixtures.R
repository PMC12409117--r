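# shared helpers: principal angles, small fixtures, reference ADMM

# largest principal angle (radians) between the column spaces of A and B,
# via the sine formula (accurate for tiny angles, unlike acos near 1)
principalAngle <- function(A, B) {
    qa <- qr.Q(qr(as.matrix(A)))
    qb <- qr.Q(qr(as.matrix(B)))
    s <- svd(qa - qb %*% crossprod(qb, qa), nu = 0, nv = 0)$d
    asin(min(max(s), 1))
}

# points exactly on a d-flat embedded in R^ambient, plus the chart coords
flatManifold <- function(n, d = 2, ambient = 10, seed = 1) {
    set.seed(seed)
    basis <- qr.Q(qr(matrix(rnorm(ambient * d), ambient, d)))
    coords <- matrix(runif(n * d), n, d)
    list(x = coords %*% t(basis), coords = coords, basis = basis)
}

# independent robust-PCA ADMM with the opposite update ordering (S before Z)
referenceRpca <- function(X, lambda = 1 / sqrt(max(dim(X))), rho = 1,
                          tol = 1e-7, maxIter = 500) {
    S <- matrix(0, nrow(X), ncol(X)); Y <- S; Z <- X
    normX <- sqrt(sum(X^2))
    soft <- function(M, tau) sign(M) * pmax(abs(M) - tau, 0)
    for (it in seq_len(maxIter)) {
        S <- soft(X - Z + Y / rho, lambda / rho)
        sv <- svd(X - S + Y / rho)
        dd <- pmax(sv$d - 1 / rho, 0)
        Z <- sv$u %*% (dd * t(sv$v))
        R <- X - Z - S
        Y <- Y + rho * R
        if (sqrt(sum(R^2)) / normX < tol) break
    }
    list(Z = Z, S = S,
         objective = sum(svd(Z, nu = 0, nv = 0)$d) + lambda * sum(abs(S)))
}

# objective recomputed term by term with explicit loops (independent oracle)
objectiveByLoops <- function(X, U, V, H, lambda, alpha) {
    recon <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X)))
        recon <- recon + (X[i, j] - sum(U[i, ] * V[j, ]))^2
    pen <- 0
    for (i in seq_len(nrow(U))) pen <- pen + sqrt(sum(U[i, ]^2))
    pen <- pen - sqrt(sum(U^2))
    graph <- 0
    if (!is.null(H))
        for (a in seq_len(ncol(V)))
            graph <- graph + as.numeric(t(V[, a]) %*% H %*% V[, a])
    0.5 * recon + lambda * pen + alpha * graph
}

# the CCCP majorizer of the U-subproblem, built at Uprev
cccpMajorizer <- function(X, V, Uprev, lambda, epsilon = 1e-8) {
    rn <- sqrt(rowSums(Uprev^2))
    q <- 1 / (2 * (rn + epsilon))
    g <- if (sum(Uprev^2) > 0) Uprev / sqrt(sum(Uprev^2)) else 0 * Uprev
    function(U) 0.5 * sum((X - tcrossprod(U, V))^2) +
        lambda * (sum(q * rowSums(U^2)) - sum(U * g))
}

tinyDataset <- function(n = 30, pCt = 8, pQus = 12, seed = 1, ...)
    simulateMultimodal(n = n, pCt = pCt, pQus = pQus, seed = seed, ...)
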