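# Delimited-text interchange format: header row with feature names prefixed
# "CT_" / "QUS_", first column the sample ID, final column the label
# (CR/PR); a sidecar key=value file records generator parameters and seed.

#' Write a two-modality dataset as delimited text
#'
#' @param x a \linkS4class{MultimodalRadiomics}
#' @param path CSV output path
#' @param metaPath sidecar metadata path (key=value lines); NULL to skip
#' @return invisibly, \code{path}
#' @export
writeFeatureTables <- function(x, path, metaPath = paste0(path, ".meta")) {
    stopifnot(is(x, "MultimodalRadiomics"))
    feats <- t(SummarizedExperiment::assay(x, "features"))
    df <- data.frame(sample_id = rownames(feats),
                     as.data.frame(feats, check.names = FALSE),
                     label = as.character(responseLabels(x)),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    if (!is.null(metaPath)) {
        par <- S4Vectors::metadata(x)$params
        if (is.null(par)) par <- list()
        writeLines(sprintf("%s=%s", names(par),
                           vapply(par, function(v) format(v, digits = 17),
                                  "")),
                   metaPath)
    }
    invisible(path)
}

#' Read a two-modality feature table
#'
#' Validates the layout: a \code{sample_id} first column, feature columns
#' carrying a \code{CT_} or \code{QUS_} prefix, and a final \code{label}
#' column in \{CR, PR\}. Duplicate sample IDs and missing values are
#' rejected with the offending cell named.
#'
#' @param path CSV file in the layout written by
#'   \code{\link{writeFeatureTables}}
#' @return a \linkS4class{MultimodalRadiomics}
#' @export
readFeatureTables <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3 || names(df)[1] != "sample_id" ||
        names(df)[ncol(df)] != "label")
        stop("expected columns: sample_id, <features>, label")
    sid <- as.character(df[[1]])
    if (anyDuplicated(sid))
        stop("duplicated sample ID: ", sid[duplicated(sid)][1])
    featNames <- names(df)[-c(1, ncol(df))]
    modality <- ifelse(startsWith(featNames, "CT_"), "CT",
                ifelse(startsWith(featNames, "QUS_"), "QUS", NA))
    if (anyNA(modality))
        stop("feature columns must be prefixed CT_ or QUS_: ",
             featNames[is.na(modality)][1])
    lab <- as.character(df$label)
    if (!all(lab %in% c("CR", "PR")))
        stop("labels must be CR or PR")
    fm <- as.matrix(df[, featNames, drop = FALSE])
    if (anyNA(fm) || !all(is.finite(fm))) {
        bad <- which(!is.finite(fm) | is.na(fm), arr.ind = TRUE)[1, ]
        stop(sprintf("missing/non-finite value at row %d, column %s",
                     bad[1], featNames[bad[2]]))
    }
    feats <- t(fm)
    colnames(feats) <- sid
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = feats),
        rowData = S4Vectors::DataFrame(modality = modality,
                                       row.names = featNames),
        colData = S4Vectors::DataFrame(
            label = factor(lab, levels = c("CR", "PR")), row.names = sid))
    methods::new("MultimodalRadiomics", se)
}

#' Write / read pooled prediction records
#' @param records prediction record data.frame
#' @param path CSV path
#' @return \code{readPredictionRecords} returns the data.frame
#' @export
writePredictionRecords <- function(records, path) {
    write.csv(records, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writePredictionRecords
#' @export
readPredictionRecords <- function(path)
    read.csv(path, stringsAsFactors = FALSE)
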