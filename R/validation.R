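#' Quality measures: RMSE, PCC, MAE
#'
#' The three statistics used throughout model comparison, computed between
#' observed and predicted \eqn{\ln(k_f)} vectors. `pcc()` returns `NA` with
#' a warning of class `"undefinedCorrelationWarning"` when either vector is
#' constant or has fewer than two points -- undefined correlations are
#' flagged, never coerced to zero.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A single nonnegative number (`rmse`, `mae`) or a correlation in
#'   \[-1, 1\] / `NA` (`pcc`).
#' @examples
#' rmse(c(1, 2, 3), c(2, 2, 2))   # sqrt(2/3)
#' pcc(c(1, 2, 3), c(1, 3, 2))    # 0.5
#' mae(c(1, 2, 3), c(2, 2, 2))    # 2/3
#' @name quality-measures
#' @aliases rmse pcc mae
NULL

.checkPaired <- function(observed, predicted) {
    if (length(observed) == 0L)
        stop("empty input")
    if (length(observed) != length(predicted))
        stop("length mismatch: ", length(observed), " observed vs ",
             length(predicted), " predicted")
    if (any(!is.finite(observed)) || any(!is.finite(predicted)))
        stop("non-finite values in input")
    invisible(TRUE)
}

#' @rdname quality-measures
#' @export
rmse <- function(observed, predicted) {
    .checkPaired(observed, predicted)
    sqrt(mean((observed - predicted)^2))
}

#' @rdname quality-measures
#' @export
mae <- function(observed, predicted) {
    .checkPaired(observed, predicted)
    mean(abs(observed - predicted))
}

#' @rdname quality-measures
#' @export
pcc <- function(observed, predicted) {
    .checkPaired(observed, predicted)
    if (length(observed) < 2L ||
        stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
        warning(warningCondition(
            "undefined correlation: constant vector or n < 2",
            class = "undefinedCorrelationWarning"))
        return(NA_real_)
    }
    stats::cor(observed, predicted)
}

.makeReport <- function(mode, observed, predicted, modelName, datasetName,
                        minLength = NA_integer_) {
    p <- suppressWarnings(pcc(observed, predicted))
    new("EvaluationReport", mode = mode, n = length(observed),
        rmse = rmse(observed, predicted), pcc = p,
        mae = mae(observed, predicted),
        modelName = modelName, datasetName = datasetName,
        minLength = as.integer(minLength))
}

#' Evaluate a model's fit on its training data
#'
#' Residual-based quality of the fitting procedure itself: predictions for
#' the training records come from the already-fitted model (no refitting).
#'
#' @param model A [LogLinearModel-class].
#' @param train The training [ProteinDataset-class].
#' @return An [EvaluationReport-class] with `mode = "fit"`.
#' @export
evaluateFit <- function(model, train) {
    stopifnot(is(model, "LogLinearModel"), is(train, "ProteinDataset"))
    .makeReport("fit", lnKf(train), predict(model, chainLengths(train)),
                modelName = model@trainingName, datasetName =
                    datasetName(train))
}

#' Leave-one-out cross-validation of the chain-length baseline
#'
#' For each record, the model is refitted on the other n-1 records and used
#' to predict the held-out one; RMSE/PCC/MAE are computed over the n
#' held-out predictions. The refits are explicit (datasets here are small);
#' the algebraically equivalent leverage identity serves as an independent
#' cross-check in the test suite. LOO error is never below the fit error for
#' this model class.
#'
#' @param train A [ProteinDataset-class] with at least 4 records; every
#'   leave-one-out design must retain two distinct lengths.
#' @return An [EvaluationReport-class] with `mode = "loo"`.
#' @export
looValidate <- function(train) {
    stopifnot(is(train, "ProteinDataset"))
    n <- length(train)
    if (n < 4L) stop("insufficient data for LOO: need >= 4 records")
    L <- chainLengths(train)
    y <- lnKf(train)
    held <- numeric(n)
    for (i in seq_len(n)) {
        if (length(unique(L[-i])) < 2L)
            stop("degenerate reduced design when leaving out record ", i,
                 " (", pdbIds(train)[i], ")")
        m <- fitLogLinear(train[-i])
        held[i] <- predict(m, L[i])
    }
    .makeReport("loo", y, held,
                modelName = datasetName(train),
                datasetName = datasetName(train))
}

#' External validation on a test set
#'
#' The most stringent check of a predictor: error on proteins never used in
#' training. Predictions come either from an already-fitted
#' [LogLinearModel-class] (applied to the test chain lengths, never refit)
#' or from an ingested [PredictionTable-class] matched to the test set by
#' PDB code. An optional minimum-length filter emulates servers that only
#' predict chains of at least `minLength` residues; excluded and unmatched
#' proteins reduce the reported `n`.
#'
#' @param object A [LogLinearModel-class] or [PredictionTable-class].
#' @param test The external [ProteinDataset-class].
#' @param minLength Optional integer: drop test records with \eqn{L <}
#'   `minLength` before evaluating.
#' @param ... Ignored.
#' @return An [EvaluationReport-class] with `mode = "external"`.
#' @examples
#' m <- LogLinearModel(30.788, -5.985, 52)
#' d <- ProteinDataset("ext", c("1AAA", "2BBB", "3CCC"),
#'                     ln_kf = c(7, 4, 1), length = c(45, 60, 70))
#' evaluateExternal(m, d, minLength = 50)   # n = 2
#' @aliases evaluateExternal
#' @name evaluateExternal
NULL

#' @rdname evaluateExternal
#' @export
setMethod("evaluateExternal", signature("LogLinearModel", "ProteinDataset"),
          function(object, test, minLength = NULL, ...) {
    keep <- .lengthFilter(test, minLength)
    if (!any(keep)) stop("no test records left after length filter")
    sub <- test[keep]
    .makeReport("external", lnKf(sub), predict(object, chainLengths(sub)),
                modelName = object@trainingName,
                datasetName = datasetName(test),
                minLength = if (is.null(minLength)) NA_integer_ else
                    minLength)
})

#' @rdname evaluateExternal
#' @export
setMethod("evaluateExternal", signature("PredictionTable", "ProteinDataset"),
          function(object, test, minLength = NULL, ...) {
    keep <- .lengthFilter(test, minLength)
    if (!any(keep)) stop("no test records left after length filter")
    sub <- test[keep]
    ids <- pdbIds(sub)
    matched <- ids %in% names(object@predictions)
    if (sum(matched) < 2L)
        stop("fewer than 2 test proteins matched predictions from '",
             object@predictorName, "'")
    if (any(!matched))
        warning(sum(!matched), " test protein(s) without a prediction ",
                "dropped: ", paste(unique(ids[!matched]), collapse = ", "))
    sub <- sub[matched]
    .makeReport("external", lnKf(sub),
                unname(object@predictions[pdbIds(sub)]),
                modelName = object@predictorName,
                datasetName = datasetName(test),
                minLength = if (is.null(minLength)) NA_integer_ else
                    minLength)
})

.lengthFilter <- function(test, minLength) {
    if (is.null(minLength)) rep(TRUE, length(test))
    else chainLengths(test) >= minLength
}

setMethod("show", "EvaluationReport", function(object) {
    lab <- c(fit = "fitting", loo = "LOO cross-validation",
             external = "external prediction")[object@mode]
    cat("EvaluationReport (", lab, "): '", object@modelName, "' on '",
        object@datasetName, "'\n", sep = "")
    cat(sprintf("  n = %d%s, RMSE = %.2f, PCC = %s, MAE = %.2f\n",
                object@n,
                if (!is.na(object@minLength))
                    sprintf(" (L >= %d)", object@minLength) else "",
                object@rmse,
                if (is.na(object@pcc)) "undefined" else
                    sprintf("%.3f", object@pcc),
                object@mae))
})

#' Extract an EvaluationReport as a one-row data.frame
#'
#' Full precision (display rounding happens only in show/render methods).
#'
#' @param x An [EvaluationReport-class].
#' @param ... Ignored.
#' @return A one-row `data.frame` with columns `model`, `dataset`, `mode`,
#'   `n`, `rmse`, `pcc`, `mae`, `min_length`.
#' @export
setMethod("as.data.frame", "EvaluationReport", function(x, ...) {
    data.frame(model = x@modelName, dataset = x@datasetName, mode = x@mode,
               n = x@n, rmse = x@rmse, pcc = x@pcc, mae = x@mae,
               min_length = x@minLength, stringsAsFactors = FALSE)
})
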