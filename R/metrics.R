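# Metrics on pooled LOPO prediction records, bootstrap variability, and the
# statistical tests used to compare components and classifiers.

#' Classification metrics from pooled prediction records
#'
#' Sensitivity is computed on the positive class (default PR, the partial
#' responders), specificity on the other; BACC = (Sn + Sp)/2 by definition;
#' F1 on the positive class; AUC from the pooled continuous scores
#' (NA when only one class is present).
#'
#' @param records data.frame with columns truth, predicted, score
#' @param positiveClass label treated as positive
#' @return named numeric vector: Sn, Sp, ACC, BACC, F1, AUC
#' @export
computeMetrics <- function(records, positiveClass = "PR") {
    truth <- as.character(records$truth)
    pred <- as.character(records$predicted)
    pos <- positiveClass
    neg <- setdiff(unique(c(truth, pred)), pos)
    neg <- if (length(neg) == 0) "other" else neg[1]
    tp <- sum(truth == pos & pred == pos)
    fn <- sum(truth == pos & pred != pos)
    tn <- sum(truth != pos & pred != pos)
    fp <- sum(truth != pos & pred == pos)
    sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    acc <- (tp + tn) / length(truth)
    bacc <- (sn + sp) / 2
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    auc <- NA_real_
    if (length(unique(truth)) == 2 && !is.null(records$score)) {
        r <- pROC::roc(response = factor(truth, levels = c(neg, pos)),
                       predictor = records$score, levels = c(neg, pos),
                       direction = "<", quiet = TRUE)
        auc <- as.numeric(pROC::auc(r))
    }
    c(Sn = sn, Sp = sp, ACC = acc, BACC = bacc, F1 = f1, AUC = auc)
}

#' Bootstrap mean and standard deviation of the metric set
#'
#' Resamples the pooled records with replacement B times and recomputes the
#' metrics per resample; single-class resamples contribute no AUC.
#'
#' @param records as in \code{\link{computeMetrics}}
#' @param B number of bootstrap resamples (>= 2)
#' @param seed integer seed
#' @param positiveClass label treated as positive
#' @return list with \code{mean}, \code{sd} (named vectors) and the
#'   B x 6 matrix of resample metrics
#' @export
bootstrapMetrics <- function(records, B = 1000L, seed = 1L,
                             positiveClass = "PR") {
    if (B < 2) stop("B must be >= 2")
    rng <- .rngState(seed)
    on.exit(rng$restore())
    n <- nrow(records)
    M <- t(vapply(seq_len(B), function(b) {
        computeMetrics(records[sample.int(n, n, replace = TRUE), ,
                               drop = FALSE], positiveClass)
    }, numeric(6)))
    colnames(M) <- c("Sn", "Sp", "ACC", "BACC", "F1", "AUC")
    list(mean = colMeans(M, na.rm = TRUE),
         sd = apply(M, 2, sd, na.rm = TRUE), samples = M)
}

#' Two-sided t-tests on components with Bonferroni flags
#'
#' Welch two-sided t-test per component between the two label groups;
#' a component is flagged significant iff p < 0.05 / mCorrections.
#'
#' @param V n x k matrix of sample components
#' @param labels binary labels of length n
#' @param mCorrections number of comparisons corrected for (default k)
#' @return data.frame with component, p, significant
#' @export
componentTtest <- function(V, labels, mCorrections = ncol(as.matrix(V))) {
    V <- as.matrix(V)
    labels <- factor(labels)
    if (length(levels(labels)) != 2) stop("labels must be binary")
    if (any(table(labels) < 2)) stop("each group needs >= 2 samples")
    p <- vapply(seq_len(ncol(V)), function(j) {
        a <- V[labels == levels(labels)[1], j]
        b <- V[labels == levels(labels)[2], j]
        if (var(a) == 0 && var(b) == 0)
            return(if (mean(a) == mean(b)) 1 else 0)
        t.test(a, b)$p.value
    }, 0)
    data.frame(component = seq_len(ncol(V)), p = p,
               significant = p < 0.05 / mCorrections)
}

#' McNemar chi-squared statistic for two classifiers
#'
#' From the 2x2 cross-tabulation of correctness (a: both correct, b: first
#' only, c: second only, d: both wrong): chi2 = (b - c)^2 / (b + c),
#' declared significant at the 0.05 level iff chi2 > 3.84 (the 0.95
#' chi-squared quantile with 1 df). b + c = 0 yields statistic 0, not
#' significant.
#'
#' @param b,c discordant counts
#' @return list with \code{statistic}, \code{significant}, \code{threshold}
#' @export
mcnemarChi2 <- function(b, c) {
    if (b < 0 || c < 0) stop("counts must be non-negative")
    stat <- if (b + c == 0) 0 else (b - c)^2 / (b + c)
    list(statistic = stat, significant = stat > 3.84, threshold = 3.84)
}

#' Cross-tabulate two record sets and run the McNemar comparison
#'
#' @param records1,records2 prediction records of two methods on the same
#'   samples (matched by the \code{sample} column)
#' @return list with the 2x2 table (a, b, c, d) and the test result
#' @export
mcnemarCompare <- function(records1, records2) {
    m <- merge(records1[, c("sample", "truth", "predicted")],
               records2[, c("sample", "predicted")], by = "sample",
               suffixes = c("1", "2"))
    ok1 <- m$predicted1 == m$truth
    ok2 <- m$predicted2 == m$truth
    a <- sum(ok1 & ok2); b <- sum(ok1 & !ok2)
    cc <- sum(!ok1 & ok2); d <- sum(!ok1 & !ok2)
    c(list(a = a, b = b, c = cc, d = d), mcnemarChi2(b, cc))
}
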