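test_that("PCA embedding matches the SVD oracle and maps out-of-sample", {
    set.seed(1)
    x <- matrix(rnorm(30 * 8), 30, 8)
    emb <- pcaEmbed(x[1:20, ], x[21:30, ], k = 3)
    xc <- scale(x[1:20, ], center = TRUE, scale = FALSE)
    sv <- svd(xc)
    oracle <- xc %*% sv$v[, 1:3]
    expect_lt(principalAngle(emb$train, oracle), 1e-10)
    expect_lt(max(abs(abs(emb$train) - abs(oracle))), 1e-10)
    # training scores have orthogonal columns
    expect_lt(max(abs(crossprod(emb$train) -
        diag(diag(crossprod(emb$train))))), 1e-8)
    # data on a 2-plane reconstructs exactly with k = 2
    fm <- flatManifold(25, d = 2, ambient = 7, seed = 2)
    e2 <- pcaEmbed(fm$x, NULL, 2)
    rec <- e2$train %*% t(e2$rotation)
    expect_lt(max(abs(rec - scale(fm$x, scale = FALSE))), 1e-10)
})

test_that("kernel PCA approaches linear PCA in the flat-kernel limit and
           gives duplicates identical scores", {
    set.seed(3)
    x <- scale(matrix(rnorm(60 * 5), 60, 5))
    # tiny gamma flattens the kernel; kernlab warns about small eigenvalues
    kp <- suppressWarnings(kpcaEmbed(x, NULL, k = 2, gamma = 1e-5))
    pc <- pcaEmbed(x, NULL, 2)
    for (j in 1:2)
        expect_gt(max(abs(cor(kp$train[, j], pc$train))), 0.999)
    xdup <- rbind(x, x[1:3, ])
    kd <- kpcaEmbed(xdup, xdup[c(1, 61), , drop = FALSE], k = 2,
                    gamma = 0.1)
    expect_equal(kd$test[1, ], kd$test[2, ], tolerance = 1e-8)
    expect_error(kpcaEmbed(x, NULL, 2, gamma = -1), "gamma")
})

test_that("ridge CCA: identical views correlate perfectly, independent views
           do not, fused dimension is k", {
    set.seed(4)
    x <- matrix(rnorm(50 * 4), 50, 4)
    cc <- ccaFuse(x, x, NULL, NULL, k = 2, ridge = 1e-10)
    expect_gt(min(cc$cor), 0.999)
    x1 <- matrix(rnorm(2000 * 5), 2000, 5)
    x2 <- matrix(rnorm(2000 * 5), 2000, 5)
    cc2 <- ccaFuse(x1, x2, x1[1:4, ], x2[1:4, ], k = 3, ridge = 1e-8)
    expect_lt(max(cc2$cor), 0.1)
    expect_equal(dim(cc2$test), c(4L, 3L))
    expect_equal(ncol(cc2$train), 3L)
    expect_error(ccaFuse(matrix(rnorm(20), 4, 5), matrix(rnorm(8), 4, 2),
                         NULL, NULL, 1, ridge = 0), "ridge")
})

test_that("robust PCA recovers the planted low-rank part and satisfies the
           split contract", {
    f <- simulateLowRankSparse(100, 80, r = 2, sparseFraction = 0.01,
                               magnitude = 10, seed = 5)
    dec <- rpcaAdmm(f$observed)
    expect_lt(norm(dec@Z - f$lowRank, "F") / norm(f$lowRank, "F"), 1e-3)
    expect_lt(dec@residual, 1e-7)
    expect_true(dec@converged)
    # clean low-rank input with a large lambda: no sparse component
    f0 <- simulateLowRankSparse(40, 30, r = 2, sparseFraction = 0, seed = 6)
    d0 <- rpcaAdmm(f0$observed, lambda = 10)
    expect_lt(sum(abs(d0@S)), 1e-6 * sum(abs(f0$observed)))
    expect_lt(norm(d0@Z - f0$observed, "F") / norm(f0$observed, "F"), 1e-6)
})

test_that("rpcaAdmm agrees with an independently ordered reference ADMM", {
    set.seed(7)
    for (i in 1:10) {
        f <- simulateLowRankSparse(40, 30, r = 2, sparseFraction = 0.02,
                                   magnitude = 5, seed = 100 + i)
        a <- rpcaAdmm(f$observed)
        b <- referenceRpca(f$observed)
        objA <- sum(svd(a@Z, nu = 0, nv = 0)$d) + a@lambda * sum(abs(a@S))
        expect_lt(abs(objA - b$objective) / b$objective, 1e-6)
    }
})

test_that("rpca fusion degenerates to PCA on clean data and resists
           row outliers", {
    f0 <- simulateLowRankSparse(50, 20, r = 3, sparseFraction = 0, seed = 8)
    rf <- rpcaFuse(f0$observed, NULL, k = 3)
    pf <- pcaEmbed(f0$observed, NULL, k = 3)
    expect_lt(principalAngle(rf$train, pf$train), 1e-3)
    # row-contaminated latent data: rPCA's subspace is closer to truth
    wins <- vapply(1:20, function(s) {
        set.seed(s)
        n <- 60; p <- 20
        B <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
        Z <- matrix(rnorm(n * 2), n, 2)
        X <- Z %*% t(B) + matrix(rnorm(n * p, sd = 0.05), n, p)
        out <- sample(n, 3)
        X[out, ] <- matrix(5 * rt(3 * p, df = 2), 3, p)
        angR <- principalAngle(rpcaFuse(X, NULL, 2)$rotation, B)
        angP <- principalAngle(pcaEmbed(X, NULL, 2)$rotation, B)
        angR < angP
    }, NA)
    expect_gte(mean(wins), 0.5)
})

test_that("graph Laplacian has zero row sums, non-positive off-diagonals,
           PSD spectrum, and one null vector per component", {
    set.seed(9)
    x <- matrix(rnorm(30 * 4), 30, 4)
    lg <- buildLaplacian(x, kNN = 6)
    L <- laplacianMatrix(lg)
    expect_lt(max(abs(L %*% rep(1, 30))), 1e-10)
    expect_true(all(L[row(L) != col(L)] <= 0))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    # two well-separated clusters: zero eigenvalue with multiplicity 2
    x2 <- rbind(matrix(rnorm(20 * 3), 20, 3),
                matrix(rnorm(20 * 3) + 100, 20, 3))
    L2 <- laplacianMatrix(buildLaplacian(x2, kNN = 4))
    ev2 <- eigen(L2, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev2) < 1e-10 * max(ev2)), 2)
    expect_error(buildLaplacian(x, kNN = 6, bandwidth = 0), "bandwidth")
})

test_that("l2,1 Laplacian PCA reduces to PCA unregularized and descends
           monotonically", {
    set.seed(10)
    x <- matrix(rnorm(40 * 15), 40, 15)
    m <- l21LaplacianPca(x, k = 3, lambda = 0, alpha = 0)
    pc <- prcomp(scale(x))
    expect_lt(principalAngle(sampleComponents(m), pc$x[, 1:3]), 1e-6)
    m2 <- l21LaplacianPca(x, k = 3, lambda = 0.5, alpha = 0.5, kNN = 8)
    tr <- objectiveTrace(m2)
    expect_true(all(diff(tr) <= 1e-10 * pmax(abs(tr[-length(tr)]), 1)))
    expect_lt(max(abs(crossprod(sampleComponents(m2)) - diag(3))), 1e-8)
})

test_that("the EPCA and Laplacian-PCA solvers share one code path: swapping
           penalty and graph reproduces the EPCA fit", {
    for (s in 1:5) {
        d <- tinyDataset(n = 30, pCt = 8, pQus = 10, seed = s)
        x <- cbind(modalityBlock(d, "CT"), modalityBlock(d, "QUS"))
        xs <- scale(x)
        h <- hessianGraph(xs, kNN = 8, d = 2)
        m1 <- epca(xs, k = 3, lambda = 0.3, alpha = 0.2, graph = h,
                   standardize = FALSE)
        m2 <- epcaFusion:::.graphSparsePcaFit(t(xs), hessianMatrix(h),
            k = 3, lambda = 0.3, alpha = 0.2, penalty = "l21m2")
        expect_identical(principalDirections(m1), principalDirections(m2))
        expect_identical(objectiveTrace(m1), objectiveTrace(m2))
    }
})

test_that("l2,1-2 penalty value never exceeds the l2,1 value minus the
           Frobenius norm identity", {
    set.seed(11)
    for (i in 1:20) {
        U <- matrix(rnorm(30), 10, 3)
        l212 <- l21MinusFNorm(U)
        l21 <- sum(sqrt(rowSums(U^2)))
        expect_equal(l212, l21 - sqrt(sum(U^2)), tolerance = 1e-12)
        expect_lte(l212, l21)
    }
})

test_that("mRMR ranks a lone informative feature first and demotes
           redundant duplicates", {
    firsts <- vapply(1:20, function(s) {
        set.seed(s)
        n <- 500
        y <- rep(0:1, each = n / 2)
        x <- matrix(rnorm(n * 15), n, 15)
        x[, 7] <- x[, 7] + y * 1.5
        mrmrRank(x, y)[1] == 7
    }, NA)
    expect_gte(sum(firsts), 19)
    # duplicated strong feature is demoted below an independent weaker one
    set.seed(12)
    n <- 400
    y <- rep(0:1, each = n / 2)
    strong <- rnorm(n) + y * 1.2
    weak <- rnorm(n) + y * 1.0
    x <- cbind(strong, strong + rnorm(n, sd = 0.01), weak,
               rnorm(n))
    rk <- mrmrRank(x, y)
    expect_equal(rk[1], 1)          # strongest first
    expect_lt(which(rk == 3), which(rk == 2))  # weak beats the duplicate
    # permutation invariance up to the tie rule
    perm <- c(3, 1, 4, 2)
    rkp <- mrmrRank(x[, perm], y)
    expect_equal(perm[rkp], rk)
    expect_error(mrmrRank(x, rep(1, n)), "two classes")
})

test_that("SFS picks a single separating feature and traces every prefix", {
    set.seed(13)
    n <- 80
    y <- factor(rep(c("A", "B"), each = n / 2))
    x <- cbind(c(rnorm(n / 2), rnorm(n / 2) + 10), matrix(rnorm(n * 4), n, 4))
    rk <- mrmrRank(x, y)
    expect_equal(rk[1], 1)
    sel <- sfsSelect(rk, x, y, classifier = "knn", seed = 1)
    expect_equal(sel$selected, 1L)
    expect_length(sel$scoreTrace, 5)
    expect_true(all(sel$selected %in% sel$ranked))
    # deterministic under a fixed seed
    sel2 <- sfsSelect(rk, x, y, classifier = "knn", seed = 1)
    expect_identical(sel$scoreTrace, sel2$scoreTrace)
})

test_that("every fuser maps test samples with training-only parameters", {
    d <- tinyDataset(n = 26, pCt = 6, pQus = 9, seed = 14)
    xc <- scale(modalityBlock(d, "CT")); xq <- scale(modalityBlock(d, "QUS"))
    y <- responseLabels(d)
    for (meth in c("epca", "pca", "kpca", "cca", "rpca", "l21lap",
                   "mrmr_sfs")) {
        fus <- fitFusion(xc, xq, labels = y, method = meth, k = 3,
                         kNN = 8, seed = 1)
        f1 <- predictFusion(fus, xc[1:2, ], xq[1:2, ])
        expect_equal(nrow(f1), 2L)
        expect_true(all(is.finite(f1)))
        # row-wise mapping: a sample's fused coordinates do not depend on
        # which other samples are mapped alongside it
        f2 <- predictFusion(fus, xc[2, , drop = FALSE],
                            xq[2, , drop = FALSE])
        expect_equal(f1[2, ], f2[1, ], tolerance = 1e-10,
                     ignore_attr = TRUE)
    }
})
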