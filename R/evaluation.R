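# Leave-one-patient-out protocol: per fold, features are z-scored with
# training statistics, the fuser is fitted on standardized training blocks,
# SMOTE balances the fused training scores, the classifier is tuned by
# stratified inner CV, and the single held-out patient is predicted. Pooled
# predictions feed the metric set, the bootstrap, and the paired tests.

#' Leave-one-patient-out fold plan
#'
#' @param n number of samples (>= 2)
#' @return list of folds; each has \code{train} and \code{test} index sets,
#'   with singleton disjoint test sets covering all samples
#' @export
lopoPlan <- function(n) {
    if (n < 2) stop("LOPO requires n >= 2")
    lapply(seq_len(n), function(i)
        list(train = setdiff(seq_len(n), i), test = i))
}

#' Fold-wise z-scoring with training statistics
#'
#' Standardizes training columns to mean 0 / sd 1 and applies the same
#' constants to the test rows. Zero-variance training features get sd 1
#' (reported in the result).
#'
#' @param train n x p training matrix
#' @param test m x p test matrix (or NULL)
#' @return list with \code{train}, \code{test}, \code{center}, \code{scale},
#'   \code{constant} (indices of zero-sd features)
#' @export
zscoreFitApply <- function(train, test = NULL) {
    train <- as.matrix(train)
    if (!all(is.finite(train))) stop("non-finite training values")
    ctr <- colMeans(train)
    scl <- apply(train, 2, sd)
    constant <- which(scl == 0)
    scl[constant] <- 1
    tr <- scale(train, ctr, scl)
    attr(tr, "scaled:center") <- NULL; attr(tr, "scaled:scale") <- NULL
    te <- NULL
    if (!is.null(test)) {
        test <- matrix(as.matrix(test), ncol = ncol(train))
        if (!all(is.finite(test))) stop("non-finite test values")
        te <- scale(test, ctr, scl)
        attr(te, "scaled:center") <- NULL; attr(te, "scaled:scale") <- NULL
    }
    list(train = tr, test = te, center = ctr, scale = scl,
         constant = constant)
}

#' SMOTE oversampling of the minority class
#'
#' Oversamples the minority class to the majority count; each synthetic
#' sample is x + u (x_nn - x) with u ~ U(0,1) and x_nn one of the sample's
#' kSmote nearest minority neighbors. Already-balanced input is returned
#' unchanged. A single-sample minority class falls back to jittered
#' duplication with a warning.
#'
#' @param x n x p matrix
#' @param y binary labels
#' @param kSmote neighbor pool size (capped at minority size - 1)
#' @param seed integer seed
#' @return list with augmented \code{x} and \code{y}
#' @export
smoteOversample <- function(x, y, kSmote = 5L, seed = 1L) {
    x <- as.matrix(x)
    y <- factor(y)
    tab <- table(y)
    if (length(tab) != 2) stop("y must have exactly two classes")
    if (tab[1] == tab[2]) return(list(x = x, y = y))
    minLab <- names(tab)[which.min(tab)]
    majLab <- names(tab)[which.max(tab)]
    need <- as.integer(tab[majLab] - tab[minLab])
    minIdx <- which(y == minLab)
    rng <- .rngState(seed)
    on.exit(rng$restore())
    if (length(minIdx) == 1) {
        warning("single-sample minority class; duplicating with jitter")
        base <- x[minIdx, , drop = FALSE]
        syn <- base[rep(1, need), , drop = FALSE] +
            matrix(rnorm(need * ncol(x), sd = 1e-6), need)
    } else {
        kk <- min(kSmote, length(minIdx) - 1L)
        xm <- x[minIdx, , drop = FALSE]
        nb <- buildNeighborhoods(xm, kk)
        src <- rep_len(seq_len(nrow(xm)), need)
        syn <- t(vapply(seq_len(need), function(j) {
            i <- src[j]
            nnLocal <- nb$index[i, sample.int(kk, 1)]
            u <- runif(1)
            xm[i, ] + u * (xm[nnLocal, ] - xm[i, ])
        }, numeric(ncol(x))))
    }
    list(x = rbind(x, syn),
         y = factor(c(as.character(y), rep(minLab, need)),
                    levels = levels(y)))
}

# deterministic stratified fold assignment
.stratifiedFolds <- function(y, nFolds, seed) {
    rng <- .rngState(seed)
    on.exit(rng$restore())
    y <- factor(y)
    idx <- vector("list", nFolds)
    for (lv in levels(y)) {
        members <- sample(which(y == lv))
        f <- rep_len(seq_len(nFolds), length(members))
        for (j in seq_len(nFolds))
            idx[[j]] <- c(idx[[j]], members[f == j])
    }
    lapply(idx, sort)
}

#' Default hyperparameter grids
#'
#' SVM: C in 10^(-2..2), gamma in 10^(-3..1); KNN: odd k up to 15.
#' @param spec "svm_rbf" or "knn"
#' @return data.frame grid
#' @export
defaultGrid <- function(spec = c("svm_rbf", "knn")) {
    spec <- match.arg(spec)
    if (spec == "svm_rbf")
        expand.grid(C = 10^(-2:2), gamma = 10^(-3:1))
    else
        data.frame(k = c(1L, 3L, 5L, 7L, 9L, 11L, 15L))
}

#' Tune and fit a classifier by stratified inner cross-validation
#'
#' Scores every grid point by inner-CV balanced accuracy (stratified folds,
#' seeded) and refits the best configuration on the full training data.
#' Ties break toward the smaller parameter values (grid order).
#'
#' @param x n x p training matrix
#' @param y binary labels (both classes present)
#' @param spec "svm_rbf" or "knn"
#' @param grid data.frame of candidate hyperparameters
#' @param innerFolds number of CV folds
#' @param seed fold-assignment seed
#' @return list with \code{spec}, \code{best} (chosen row), \code{model}
#'   (fitted svm, or the stored training set for knn), \code{cvScores}
#' @export
tuneClassifier <- function(x, y, spec = c("svm_rbf", "knn"),
                           grid = defaultGrid(spec), innerFolds = 5L,
                           seed = 1L) {
    spec <- match.arg(spec)
    x <- as.matrix(x); y <- factor(y)
    if (length(levels(y)) != 2 || any(table(y) == 0))
        stop("y must contain both classes")
    if (nrow(grid) == 0) stop("empty grid")
    nf <- min(innerFolds, min(table(y)))
    nf <- max(nf, 2L)
    folds <- .stratifiedFolds(y, nf, seed)
    scores <- vapply(seq_len(nrow(grid)), function(g) {
        preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
        for (f in folds) {
            xtr <- x[-f, , drop = FALSE]; ytr <- y[-f]
            if (length(unique(ytr)) < 2) next
            if (spec == "svm_rbf") {
                fit <- e1071::svm(xtr, ytr, kernel = "radial",
                                  cost = grid$C[g], gamma = grid$gamma[g],
                                  scale = FALSE)
                preds[f] <- predict(fit, x[f, , drop = FALSE])
            } else {
                kk <- min(grid$k[g], length(ytr))
                preds[f] <- class::knn(xtr, x[f, , drop = FALSE], ytr, k = kk)
            }
        }
        ok <- !is.na(preds)
        if (!any(ok)) 0 else .baccOf(y[ok], preds[ok])
    }, 0)
    best <- which.max(scores)   # first maximum: smallest parameters win ties
    model <- if (spec == "svm_rbf")
        e1071::svm(x, y, kernel = "radial", cost = grid$C[best],
                   gamma = grid$gamma[best], scale = FALSE,
                   probability = FALSE)
    else list(x = x, y = y, k = min(grid$k[best], length(y)))
    list(spec = spec, best = grid[best, , drop = FALSE], model = model,
         cvScores = scores)
}

#' Predict labels and continuous scores from a tuned classifier
#'
#' The score is oriented so larger values favor the positive class.
#'
#' @param fit output of \code{\link{tuneClassifier}}
#' @param xNew m x p matrix
#' @param positiveClass label treated as positive
#' @return list with \code{label} (factor) and \code{score} (numeric)
#' @export
predictClassifier <- function(fit, xNew, positiveClass = "PR") {
    xNew <- as.matrix(xNew)
    if (fit$spec == "svm_rbf") {
        pr <- predict(fit$model, xNew, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        sc <- dv[, 1]
        # e1071 orients the decision value toward the first class in the
        # colname "A/B"; flip so positiveClass gets the positive direction
        nm <- strsplit(colnames(dv)[1], "/")[[1]]
        if (nm[1] != positiveClass) sc <- -sc
        list(label = pr, score = as.numeric(sc))
    } else {
        pr <- class::knn(fit$model$x, xNew, fit$model$y, k = fit$model$k,
                         prob = TRUE)
        pWin <- attr(pr, "prob")
        sc <- ifelse(pr == positiveClass, pWin, 1 - pWin)
        list(label = pr, score = as.numeric(sc))
    }
}

# one LOPO fold; exposed internally so leakage tests can inspect artifacts
.lopoFold <- function(xCt, xQus, y, fold, method, classifier, k, lambda,
                      alpha, kNN, d, kSmote, seed, positiveClass, grid,
                      innerFolds, applySmote = TRUE) {
    tr <- fold$train; te <- fold$test
    zc <- zscoreFitApply(xCt[tr, , drop = FALSE], xCt[te, , drop = FALSE])
    zq <- zscoreFitApply(xQus[tr, , drop = FALSE], xQus[te, , drop = FALSE])
    fus <- fitFusion(zc$train, zq$train, labels = y[tr], method = method,
                     k = k, lambda = lambda, alpha = alpha, kNN = kNN, d = d,
                     seed = seed)
    ftr <- predictFusion(fus, zc$train, zq$train)
    fte <- predictFusion(fus, zc$test, zq$test)
    if (applySmote) {
        sm <- smoteOversample(ftr, y[tr], kSmote = kSmote, seed = seed)
    } else sm <- list(x = ftr, y = y[tr])
    cls <- tuneClassifier(sm$x, sm$y, spec = classifier, grid = grid,
                          innerFolds = innerFolds, seed = seed)
    pred <- predictClassifier(cls, fte, positiveClass)
    list(center = c(zc$center, zq$center), scale = c(zc$scale, zq$scale),
         fuser = fus, fusedTrain = ftr, classifier = cls, pred = pred)
}

#' Run the full leave-one-patient-out evaluation of one fuser
#'
#' Per fold: z-score on the training block statistics, fit the fuser on
#' standardized training blocks, map train and test to fused space, SMOTE
#' the fused training scores, tune the classifier by stratified inner CV,
#' and predict the held-out patient. Returns one pooled prediction record
#' per sample.
#'
#' @param dataset a \linkS4class{MultimodalRadiomics}, or a list with
#'   elements \code{ct}, \code{qus} (samples x features) and \code{labels}
#' @param method fuser identifier (see \code{\link{fitFusion}})
#' @param classifier "svm_rbf" or "knn"
#' @param k fused dimension
#' @param lambda,alpha EPCA regularization weights
#' @param kNN,d graph parameters
#' @param kSmote SMOTE neighbor pool
#' @param grid classifier hyperparameter grid
#' @param innerFolds inner CV folds
#' @param positiveClass label treated as positive (default "PR")
#' @param seed master seed; per-fold seeds are derived deterministically
#' @param applySmote set FALSE to skip oversampling
#' @return data.frame of prediction records: sample, truth, predicted,
#'   score, fold, method
#' @export
runLopo <- function(dataset, method = "epca",
                    classifier = c("svm_rbf", "knn"), k = 6L,
                    lambda = 1e-2, alpha = 1e-2, kNN = 12L, d = 2L,
                    kSmote = 5L, grid = NULL, innerFolds = 5L,
                    positiveClass = "PR", seed = 1L, applySmote = TRUE) {
    classifier <- match.arg(classifier)
    if (is(dataset, "MultimodalRadiomics")) {
        xCt <- modalityBlock(dataset, "CT")
        xQus <- modalityBlock(dataset, "QUS")
        y <- responseLabels(dataset)
    } else {
        xCt <- as.matrix(dataset$ct); xQus <- as.matrix(dataset$qus)
        y <- factor(dataset$labels)
    }
    if (length(levels(y)) != 2) stop("labels must be binary")
    if (is.null(grid)) grid <- defaultGrid(classifier)
    n <- nrow(xCt)
    plan <- lopoPlan(n)
    rec <- vector("list", n)
    for (i in seq_len(n)) {
        fr <- tryCatch(
            .lopoFold(xCt, xQus, y, plan[[i]], method, classifier, k,
                      lambda, alpha, kNN, d, kSmote,
                      seed = (seed + i) %% .Machine$integer.max,
                      positiveClass, grid, innerFolds, applySmote),
            error = function(e) stop(sprintf("fold %d failed: %s", i,
                                             conditionMessage(e))))
        rec[[i]] <- data.frame(sample = i,
                               truth = as.character(y[plan[[i]]$test]),
                               predicted = as.character(fr$pred$label),
                               score = fr$pred$score,
                               fold = i, method = method,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, rec)
}
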