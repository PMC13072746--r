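#' Generate a synthetic protein kinetics dataset with known ground truth
#'
#' Emulates the statistical structure of published folding-kinetics
#' compilations: integer chain lengths drawn log-uniformly over `lRange`
#' (so \eqn{\ln L} has near-uniform leverage in the regression design),
#' i.i.d. uniform standard-residue sequences of those lengths, and rates
#' generated from the chain-length law with Gaussian residuals,
#' \deqn{\ln(k_f) = a_0 + a_1 \ln L + \varepsilon, \quad
#'       \varepsilon \sim N(0, \sigma^2).}
#' Defaults match the regime of the real compilations: \eqn{a_0 = 30.4},
#' \eqn{a_1 = -6}, residual scatter \eqn{\sigma = 2.6}, lengths 40-400.
#' Synthetic PDB-style 4-character identifiers are unique. The realised
#' ground truth (parameters, lengths, residuals) is returned alongside so
#' recovery can be asserted exactly in oracle tests.
#'
#' @param n Number of proteins (>= 4).
#' @param lRange Inclusive integer length range, default `c(40, 400)`.
#' @param a0,a1 True intercept and slope of the generating law.
#' @param sigma Residual standard deviation of \eqn{\ln(k_f)} (>= 0).
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @param name Dataset label.
#' @param sequences Generate sequences (default `TRUE`); with `FALSE` only
#'   lengths are stored, which is faster for regression-only studies.
#' @return List with `dataset` (a [ProteinDataset-class]) and `truth`
#'   (list: `a0`, `a1`, `sigma`, `lengths`, `residuals`).
#' @examples
#' sim <- simulateDataset(50, seed = 1)
#' coef(fitLogLinear(sim$dataset))
#' @export
simulateDataset <- function(n, lRange = c(40L, 400L), a0 = 30.4, a1 = -6.0,
                            sigma = 2.6, seed = NULL, name = "synthetic",
                            sequences = TRUE) {
    stopifnot(n >= 4L, length(lRange) == 2L, lRange[1L] >= 1L,
              lRange[1L] <= lRange[2L], sigma >= 0)
    if (lRange[1L] == lRange[2L])
        stop("infeasible config: degenerate length range")
    if (!is.null(seed)) set.seed(seed)
    L <- as.integer(round(exp(stats::runif(n, log(lRange[1L]),
                                           log(lRange[2L])))))
    L <- pmin(pmax(L, lRange[1L]), lRange[2L])
    # two distinct lengths are needed downstream; a log-uniform draw over a
    # non-degenerate range collides only with tiny probability, but be safe
    while (length(unique(L)) < 2L)
        L[1L] <- if (L[1L] == lRange[1L]) lRange[2L] else lRange[1L]
    eps <- stats::rnorm(n, 0, sigma)
    y <- a0 + a1 * log(L) + eps
    ids <- .syntheticIds(n)
    seqv <- if (sequences) .randomSequences(L) else NULL
    ds <- ProteinDataset(name = name, pdb_id = ids, ln_kf = y,
                         sequence = seqv, length = L)
    list(dataset = ds,
         truth = list(a0 = a0, a1 = a1, sigma = sigma,
                      lengths = L, residuals = eps))
}

## Unique synthetic 4-char PDB-style codes: digit + three alphanumerics.
.syntheticIds <- function(n) {
    pool <- c(LETTERS, 0:9)
    repeat {
        ids <- paste0(sample(1:9, n, replace = TRUE),
                      replicate(n, paste(sample(pool, 3L, replace = TRUE),
                                         collapse = "")))
        if (!anyDuplicated(ids)) return(ids)
    }
}

.randomSequences <- function(L) {
    vapply(L, function(l)
        paste(sample(.AA_STANDARD, l, replace = TRUE), collapse = ""), "")
}

#' Generate a paired experimental variant of a dataset
#'
#' Emulates the disagreement observed between compilations that share PDB
#' codes: the variant keeps every identifier but perturbs a random subset
#' of records. Selected sequences get up to `maxLenDelta` residues inserted
#' or deleted at a random position; selected rates are shifted by an
#' exponentially distributed magnitude (mean `rateDeltaMean`) with random
#' sign -- a heavy-tailed scatter around a small mean, as seen when real
#' compilations are compared. A perturbation log records exactly what was
#' changed, so discrepancy summaries can be reconciled against it.
#'
#' @param dataset A [ProteinDataset-class] to perturb.
#' @param pSeqChange Probability a record's sequence is edited.
#' @param maxLenDelta Maximum residues inserted or deleted per edit (>= 1).
#' @param pRateChange Probability a record's \eqn{\ln(k_f)} is shifted.
#' @param rateDeltaMean Mean absolute rate shift (default 0.5).
#' @param seed Integer seed.
#' @return List with `dataset` (the variant, named `"<name>_v"`) and `log`
#'   (`data.frame`: `pdb_id`, `seq_changed`, `len_delta`, `rate_delta`,
#'   signed).
#' @export
simulateVariant <- function(dataset, pSeqChange = 0.2, maxLenDelta = 10L,
                            pRateChange = 0.6, rateDeltaMean = 0.5,
                            seed = NULL) {
    stopifnot(is(dataset, "ProteinDataset"),
              pSeqChange >= 0, pSeqChange <= 1,
              pRateChange >= 0, pRateChange <= 1, rateDeltaMean >= 0)
    if (!is.null(seed)) set.seed(seed)
    rec <- records(dataset)
    n <- nrow(rec)
    seq_hit <- stats::runif(n) < pSeqChange & !is.na(rec$sequence)
    rate_hit <- stats::runif(n) < pRateChange
    len_delta <- integer(n)
    for (i in which(seq_hit)) {
        d <- sample(seq_len(max(1L, maxLenDelta)), 1L) *
            sample(c(-1L, 1L), 1L)
        # never delete below one residue
        if (nchar(rec$sequence[i]) + d < 1L) d <- abs(d)
        rec$sequence[i] <- .editSequence(rec$sequence[i], d)
        rec$length[i] <- nchar(rec$sequence[i])
        len_delta[i] <- d
    }
    rate_delta <- numeric(n)
    hits <- which(rate_hit)
    if (length(hits) && rateDeltaMean > 0) {
        rate_delta[hits] <- stats::rexp(length(hits), 1 / rateDeltaMean) *
            sample(c(-1, 1), length(hits), replace = TRUE)
        rec$ln_kf[hits] <- rec$ln_kf[hits] + rate_delta[hits]
    }
    variant <- ProteinDataset(name = paste0(datasetName(dataset), "_v"),
                              pdb_id = rec$pdb_id, ln_kf = rec$ln_kf,
                              sequence = rec$sequence, length = rec$length,
                              kinetic_class = rec$kinetic_class,
                              structural_class = rec$structural_class)
    list(dataset = variant,
         log = data.frame(pdb_id = rec$pdb_id, seq_changed = seq_hit,
                          len_delta = len_delta, rate_delta = rate_delta,
                          stringsAsFactors = FALSE))
}

## Insert (d > 0) or delete (d < 0) |d| residues at a random position; an
## edit of sequence content alone (d == 0) is not used by the generator.
.editSequence <- function(s, d) {
    l <- nchar(s)
    if (d >= 0) {
        pos <- sample(0:l, 1L)
        ins <- paste(sample(.AA_STANDARD, d, replace = TRUE), collapse = "")
        paste0(substr(s, 1L, pos), ins, substr(s, pos + 1L, l))
    } else {
        k <- min(-d, l - 1L)
        pos <- sample(seq_len(l - k + 1L), 1L)
        paste0(substr(s, 1L, pos - 1L), substr(s, pos + k, l))
    }
}

#' Simulate an overfitted external predictor
#'
#' Demonstrates the signature of overfitting that external validation is
#' designed to expose: a predictor that is very accurate on the proteins it
#' was trained on and much worse (noisier and biased) on new ones.
#' Predictions are `observed + N(0, sigmaTrain)` for training-set codes and
#' `observed + N(0, sigmaTest) + biasTest` for test-set codes.
#'
#' @param train,test [ProteinDataset-class] objects with disjoint or
#'   overlapping codes; a code present in both is treated as training.
#' @param sigmaTrain,sigmaTest Prediction noise SD on the two sets.
#' @param biasTest Systematic offset added on the test set.
#' @param seed Integer seed.
#' @param predictorName Label, default `"overfit-sim"`.
#' @return A [PredictionTable-class] covering both sets.
#' @export
simulateOverfitPredictor <- function(train, test, sigmaTrain = 0.5,
                                     sigmaTest = 2, biasTest = 4,
                                     seed = NULL,
                                     predictorName = "overfit-sim") {
    stopifnot(is(train, "ProteinDataset"), is(test, "ProteinDataset"),
              sigmaTrain >= 0, sigmaTest >= 0)
    if (!is.null(seed)) set.seed(seed)
    tr <- records(train)[!duplicated(pdbIds(train)), ]
    te <- records(test)[!duplicated(pdbIds(test)), ]
    te <- te[!te$pdb_id %in% tr$pdb_id, , drop = FALSE]
    pred <- c(tr$ln_kf + stats::rnorm(nrow(tr), 0, sigmaTrain),
              te$ln_kf + stats::rnorm(nrow(te), 0, sigmaTest) + biasTest)
    PredictionTable(predictorName, c(tr$pdb_id, te$pdb_id), pred)
}
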