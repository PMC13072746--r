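#' Fit the chain-length baseline model ln(kf) = a0 + a1 * ln(L)
#'
#' Ordinary least squares of experimental \eqn{\ln(k_f)} on \eqn{\ln L},
#' computed in closed form from centered moments:
#' \deqn{a_1 = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'                  {\sum_i (x_i - \bar x)^2}, \qquad
#'       a_0 = \bar y - a_1 \bar x, \qquad x_i = \ln L_i .}
#' Duplicated records are kept as independent observations. The fitted
#' model records the inclusive training length range as its minimal
#' applicability domain (see [inDomain()]).
#'
#' @param train A [ProteinDataset-class] with at least 3 records and at
#'   least two distinct lengths.
#' @return A [LogLinearModel-class].
#' @examples
#' d <- ProteinDataset("toy", sprintf("%04d", 1:5), length = c(50, 75, 100, 150, 220),
#'                     ln_kf = 30 - 6 * log(c(50, 75, 100, 150, 220)))
#' coef(fitLogLinear(d))
#' @export
fitLogLinear <- function(train) {
    stopifnot(is(train, "ProteinDataset"))
    n <- length(train)
    if (n < 3L)
        stop("insufficient data: need at least 3 records, got ", n)
    L <- chainLengths(train)
    if (length(unique(L)) < 2L)
        stop("degenerate design: all training lengths are equal (L = ",
             L[1L], ")")
    x <- log(L)
    y <- lnKf(train)
    xc <- x - mean(x)
    a1 <- sum(xc * (y - mean(y))) / sum(xc * xc)
    a0 <- mean(y) - a1 * mean(x)
    new("LogLinearModel", a0 = a0, a1 = a1, nTrain = n,
        trainingName = datasetName(train),
        domainL = range(as.numeric(L)))
}

#' Construct a LogLinearModel from known coefficients
#'
#' For models taken from a publication rather than fitted here (the
#' applicability domain must then be supplied explicitly).
#'
#' @param a0,a1 Intercept and slope of \eqn{\ln(k_f) = a_0 + a_1 \ln L}.
#' @param nTrain Training-set size the coefficients were fitted on.
#' @param trainingName Label of the training set.
#' @param domainL Inclusive training length range `c(Lmin, Lmax)`.
#' @return A [LogLinearModel-class].
#' @export
LogLinearModel <- function(a0, a1, nTrain, trainingName = "unnamed",
                           domainL = c(1, Inf)) {
    if (any(!is.finite(domainL))) domainL <- c(1, .Machine$double.xmax)
    new("LogLinearModel", a0 = a0, a1 = a1, nTrain = as.integer(nTrain),
        trainingName = trainingName, domainL = as.numeric(domainL))
}

#' @describeIn fitLogLinear Model coefficients as `c(a0 = , a1 = )`.
#' @param object A [LogLinearModel-class].
#' @param ... Ignored.
#' @export
setMethod("coef", "LogLinearModel", function(object, ...)
    c(a0 = object@a0, a1 = object@a1))

#' Predict ln(kf) from chain length
#'
#' Evaluates \eqn{a_0 + a_1 \ln L}; strictly decreasing in `L` for the
#' negative slopes seen in real data.
#'
#' @param object A [LogLinearModel-class].
#' @param L Positive integer chain length(s), in residues.
#' @param ... Ignored.
#' @return Predicted \eqn{\ln(k_f)}, same length as `L`.
#' @examples
#' m <- LogLinearModel(30.788, -5.985, 52)
#' predict(m, 100)
#' @export
setMethod("predict", "LogLinearModel", function(object, L, ...) {
    L <- as.numeric(L)
    if (any(!is.finite(L) | L < 1))
        stop("domain error: L must be >= 1")
    object@a0 + object@a1 * log(L)
})

#' Classify a length against a model's applicability domain
#'
#' A minimal applicability domain in the QSAR sense: predictions are
#' considered reliable only for chain lengths inside the inclusive training
#' range.
#'
#' @param model A [LogLinearModel-class].
#' @param L Chain length(s) to classify.
#' @return Character vector over `L`: `"inside"`, `"outside-low"` or
#'   `"outside-high"`.
#' @export
inDomain <- function(model, L) {
    stopifnot(is(model, "LogLinearModel"))
    ifelse(L < model@domainL[1L], "outside-low",
           ifelse(L > model@domainL[2L], "outside-high", "inside"))
}

setMethod("show", "LogLinearModel", function(object) {
    cat(sprintf("LogLinearModel: ln(kf) = %.3f %s %.3f*ln(L)\n",
                object@a0, if (object@a1 < 0) "-" else "+", abs(object@a1)))
    cat("  trained on '", object@trainingName, "' (n = ", object@nTrain,
        "), applicability domain L in [", object@domainL[1L], ", ",
        object@domainL[2L], "]\n", sep = "")
})

#' Published chain-length baseline models
#'
#' The six ln(L) baselines fitted on the pairwise overlap subsets of the
#' S77, S80 and S111 kinetics compilations, with the coefficients as printed
#' in the comparative-validation literature (3 decimals). Useful as
#' reference points for [theoryConsistency()] without access to the
#' underlying supplementary tables; their applicability domains are unknown
#' and set wide open.
#'
#' @return Named list of six [LogLinearModel-class] objects.
#' @examples
#' theoryConsistency(publishedLengthModels())$negA1Range
#' @export
publishedLengthModels <- function() {
    tbl <- list(
        "MO.1" = list(30.788, -5.985, 52L, "S77∩S80"),
        "MO.2" = list(32.439, -6.411, 50L, "S80∩S77"),
        "MO.3" = list(24.140, -4.496, 42L, "S77∩S111"),
        "MO.4" = list(24.621, -4.587, 40L, "S111∩S77"),
        "MO.5" = list(35.521, -7.068, 51L, "S80∩S111"),
        "MO.6" = list(35.888, -7.111, 51L, "S111∩S80"))
    lapply(tbl, function(s)
        LogLinearModel(s[[1L]], s[[2L]], s[[3L]], trainingName = s[[4L]]))
}
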