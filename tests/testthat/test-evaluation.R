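test_that("LOPO plan covers every sample exactly once", {
    plan <- lopoPlan(71)
    expect_length(plan, 71)
    tests <- vapply(plan, function(f) f$test, 0L)
    expect_setequal(tests, 1:71)
    for (f in plan[c(1, 40, 71)]) {
        expect_length(f$test, 1)
        expect_setequal(c(f$train, f$test), 1:71)
        expect_false(f$test %in% f$train)
    }
    expect_error(lopoPlan(1), "n >= 2")
})

test_that("fold-wise z-scoring standardizes training data and reuses the
           training constants on test rows", {
    set.seed(1)
    tr <- matrix(rnorm(40 * 5, mean = 3, sd = 2), 40, 5)
    tr[, 5] <- 7                       # constant feature
    te <- matrix(rnorm(10 * 5), 10, 5)
    z <- zscoreFitApply(tr, te)
    expect_lt(max(abs(colMeans(z$train))), 1e-12)
    expect_equal(apply(z$train[, 1:4], 2, sd), rep(1, 4))
    expect_equal(z$constant, 5L, ignore_attr = TRUE)
    expect_true(all(z$train[, 5] == 0))
    # mutating test rows leaves the stored constants unchanged
    z2 <- zscoreFitApply(tr, te * 100)
    expect_identical(z2$center, z$center)
    expect_identical(z2$scale, z$scale)
    expect_error(zscoreFitApply(matrix(c(1, NA), 1)), "non-finite")
})

test_that("SMOTE balances 46/25 to 46/46 with on-segment synthetics and
           leaves balanced input untouched", {
    set.seed(2)
    x <- matrix(rnorm(71 * 4), 71, 4)
    y <- factor(rep(c("PR", "CR"), c(46, 25)))
    sm <- smoteOversample(x, y, kSmote = 5, seed = 3)
    expect_equal(as.integer(table(sm$y)), c(46L, 46L))
    expect_equal(nrow(sm$x), 92L)
    # each synthetic point lies on a segment between two real minority points
    minX <- x[y == "CR", ]
    syn <- sm$x[-seq_len(71), , drop = FALSE]
    for (j in seq_len(nrow(syn))) {
        resid <- Inf
        for (a in seq_len(nrow(minX) - 1)) for (b in (a + 1):nrow(minX)) {
            seg <- minX[b, ] - minX[a, ]
            t0 <- sum((syn[j, ] - minX[a, ]) * seg) / sum(seg^2)
            if (t0 >= 0 && t0 <= 1)
                resid <- min(resid,
                             sqrt(sum((syn[j, ] - minX[a, ] - t0 * seg)^2)))
        }
        expect_lt(resid, 1e-10)
    }
    yb <- factor(rep(c("PR", "CR"), c(10, 10)))
    smb <- smoteOversample(x[1:20, ], yb, seed = 4)
    expect_identical(smb$x, x[1:20, ])
    # seeded reproducibility
    sm2 <- smoteOversample(x, y, kSmote = 5, seed = 3)
    expect_identical(sm$x, sm2$x)
    # single-sample minority falls back with a warning
    ys <- factor(rep(c("PR", "CR"), c(19, 1)))
    expect_warning(smoteOversample(x[1:20, ], ys, seed = 5),
                   "single-sample")
})

test_that("classifier tuning is seeded, honors one-point grids, and aces a
           separable toy problem", {
    set.seed(5)
    x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40) + 6, 20, 2))
    y <- factor(rep(c("CR", "PR"), each = 20))
    fit <- tuneClassifier(x, y, "svm_rbf", seed = 1)
    pr <- predictClassifier(fit, x)
    expect_equal(as.character(pr$label), as.character(y))
    expect_gte(max(fit$cvScores), 0.95)
    one <- data.frame(C = 1, gamma = 0.1)
    f1 <- tuneClassifier(x, y, "svm_rbf", grid = one, seed = 1)
    expect_equal(f1$best$C, 1)
    f2 <- tuneClassifier(x, y, "svm_rbf", seed = 1)
    expect_identical(fit$best, f2$best)
    expect_error(tuneClassifier(x, y, "svm_rbf", grid = one[0, ]), "grid")
    expect_error(tuneClassifier(x, factor(rep("CR", 40)), "knn"),
                 "both classes")
})

test_that("classifier scores orient toward the positive class", {
    set.seed(6)
    x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60) + 4, 30, 2))
    y <- factor(rep(c("CR", "PR"), each = 30))
    for (spec in c("svm_rbf", "knn")) {
        fit <- tuneClassifier(x, y, spec, seed = 2)
        sc <- predictClassifier(fit, x, positiveClass = "PR")$score
        expect_gt(mean(sc[y == "PR"]), mean(sc[y == "CR"]))
    }
})

test_that("LOPO produces one record per sample and is reproducible", {
    d <- tinyDataset(n = 20, pCt = 6, pQus = 8, seed = 7)
    rec <- runLopo(d, method = "pca", classifier = "knn", k = 3, kNN = 6,
                   grid = data.frame(k = c(3, 5)), innerFolds = 3, seed = 1)
    expect_equal(nrow(rec), 20L)
    expect_setequal(rec$sample, 1:20)
    expect_true(all(rec$truth %in% c("CR", "PR")))
    rec2 <- runLopo(d, method = "pca", classifier = "knn", k = 3, kNN = 6,
                    grid = data.frame(k = c(3, 5)), innerFolds = 3, seed = 1)
    expect_identical(rec, rec2)
})

test_that("training-side artifacts are invariant to the held-out sample,
           for every fuser", {
    d <- tinyDataset(n = 26, pCt = 6, pQus = 9, seed = 8)
    xc <- modalityBlock(d, "CT"); xq <- modalityBlock(d, "QUS")
    y <- responseLabels(d)
    fold <- list(train = 2:26, test = 1L)
    xcMut <- xc; xcMut[1, ] <- xcMut[1, ] + 50
    xqMut <- xq; xqMut[1, ] <- -xqMut[1, ]
    for (meth in c("epca", "pca", "kpca", "cca", "rpca", "l21lap",
                   "mrmr_sfs")) {
        a <- epcaFusion:::.lopoFold(xc, xq, y, fold, meth, "knn", k = 3,
            lambda = 1e-2, alpha = 1e-2, kNN = 6, d = 2, kSmote = 3,
            seed = 5, positiveClass = "PR", grid = data.frame(k = 3),
            innerFolds = 3)
        b <- epcaFusion:::.lopoFold(xcMut, xqMut, y, fold, meth, "knn",
            k = 3, lambda = 1e-2, alpha = 1e-2, kNN = 6, d = 2, kSmote = 3,
            seed = 5, positiveClass = "PR", grid = data.frame(k = 3),
            innerFolds = 3)
        expect_identical(a$center, b$center)
        expect_identical(a$scale, b$scale)
        expect_identical(a$fusedTrain, b$fusedTrain)
        expect_identical(a$classifier$best, b$classifier$best)
    }
})

test_that("metric set follows its definitions on constructed records", {
    rec <- data.frame(truth = c("PR", "PR", "PR", "CR", "CR"),
                      predicted = c("PR", "PR", "CR", "CR", "PR"),
                      score = c(0.9, 0.8, 0.3, 0.1, 0.7))
    m <- computeMetrics(rec)
    expect_equal(m[["Sn"]], 2 / 3)
    expect_equal(m[["Sp"]], 1 / 2)
    expect_equal(m[["BACC"]], (2 / 3 + 1 / 2) / 2)
    expect_equal(m[["ACC"]], 3 / 5)
    expect_equal(m[["F1"]], 2 * 2 / (2 * 2 + 1 + 1))
    # perfect predictions
    perf <- data.frame(truth = c("PR", "CR"), predicted = c("PR", "CR"),
                       score = c(1, 0))
    expect_true(all(computeMetrics(perf)[1:5] == 1))
    # all-positive predictor
    allp <- data.frame(truth = c("PR", "PR", "CR"),
                       predicted = rep("PR", 3), score = rep(1, 3))
    ma <- computeMetrics(allp)
    expect_equal(ma[["Sn"]], 1)
    expect_equal(ma[["Sp"]], 0)
    expect_equal(ma[["BACC"]], 0.5)
    # single-class truth: AUC undefined
    expect_true(is.na(computeMetrics(data.frame(truth = c("PR", "PR"),
        predicted = c("PR", "CR"), score = c(1, 0)))[["AUC"]]))
})

test_that("bootstrap metrics are seeded, collapse to zero spread on perfect
           records, and are stable in B", {
    set.seed(9)
    rec <- data.frame(truth = sample(c("PR", "CR"), 60, replace = TRUE),
                      predicted = sample(c("PR", "CR"), 60, replace = TRUE),
                      score = runif(60))
    b1 <- bootstrapMetrics(rec, B = 200, seed = 1)
    b2 <- bootstrapMetrics(rec, B = 200, seed = 1)
    expect_identical(b1$mean, b2$mean)
    perf <- data.frame(truth = rep(c("PR", "CR"), 10),
                       predicted = rep(c("PR", "CR"), 10),
                       score = rep(c(1, 0), 10))
    expect_equal(bootstrapMetrics(perf, B = 50, seed = 2)$sd[["ACC"]], 0)
    b3 <- bootstrapMetrics(rec, B = 1000, seed = 3)
    b4 <- bootstrapMetrics(rec, B = 2000, seed = 4)
    se <- b3$sd[["BACC"]] / sqrt(1000)
    expect_lt(abs(b3$mean[["BACC"]] - b4$mean[["BACC"]]), 4 * se)
    expect_error(bootstrapMetrics(rec, B = 1), "B must be")
})

test_that("component t-tests flag separated components under Bonferroni", {
    set.seed(10)
    V <- matrix(rnorm(200 * 3), 200, 3)
    labels <- rep(c("CR", "PR"), each = 100)
    V[labels == "PR", 2] <- V[labels == "PR", 2] + 10
    res <- componentTtest(V, labels, mCorrections = 6)
    expect_lt(res$p[2], 1e-10)
    expect_true(res$significant[2])
    expect_false(any(res$significant[c(1, 3)]))
    # identical groups (copied rows): p = 1
    Vd <- rbind(matrix(1:6, 2, 3, byrow = TRUE),
                matrix(1:6, 2, 3, byrow = TRUE))
    resd <- componentTtest(Vd, c("CR", "CR", "PR", "PR"), mCorrections = 1)
    expect_equal(resd$p, rep(1, 3))
    expect_error(componentTtest(V, rep("CR", 200)), "binary")
})

test_that("McNemar statistic and 3.84 decision threshold", {
    r <- mcnemarChi2(8, 2)
    expect_equal(r$statistic, 3.6)
    expect_false(r$significant)
    expect_equal(mcnemarChi2(5, 5)$statistic, 0)
    r2 <- mcnemarChi2(10, 0)
    expect_equal(r2$statistic, 10)
    expect_true(r2$significant)
    expect_equal(mcnemarChi2(0, 0)$statistic, 0)
    expect_false(mcnemarChi2(0, 0)$significant)
    expect_error(mcnemarChi2(-1, 2), "non-negative")
    # cross-tabulation from matched record sets
    rec1 <- data.frame(sample = 1:6, truth = rep("PR", 6),
                       predicted = c("PR", "PR", "PR", "CR", "CR", "PR"))
    rec2 <- data.frame(sample = 1:6,
                       predicted = c("PR", "CR", "CR", "CR", "PR", "PR"))
    mc <- mcnemarCompare(rec1, rec2)
    expect_equal(mc$a + mc$b + mc$c + mc$d, 6)
    expect_equal(mc$b, 2)   # first right, second wrong
    expect_equal(mc$c, 1)
})
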