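#' @import methods
NULL

## Canonical record columns, in storage order. `sequence` may be NA per record;
## `length` is always populated (from the sequence when one is present).
.RECORD_COLS <- c("pdb_id", "sequence", "length", "ln_kf",
                  "kinetic_class", "structural_class", "source")

.AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_EXTENDED <- c(.AA_STANDARD, "B", "Z", "X", "U", "O")

.KINETIC_CLASSES    <- c("two-state", "multi-state", "unknown")
.STRUCTURAL_CLASSES <- c("all-alpha", "all-beta", "mixed", "unknown")

#' ProteinDataset: a named, ordered collection of protein kinetics records
#'
#' Holds one protein per row: a PDB code (possibly with a chain suffix, and
#' possibly duplicated -- some published sets list the same code twice with
#' different measured rates), an optional amino-acid sequence, the chain
#' length \eqn{L} in residues, the experimental natural-log folding rate
#' \eqn{\ln(k_f)} (units \eqn{\ln(s^{-1})}), and optional kinetic and
#' structural class tags. Record order is meaningful and is never changed by
#' parsing or subset operations.
#'
#' @slot name Dataset label, e.g. \code{"S77"}.
#' @slot records A \code{data.frame} with columns \code{pdb_id},
#'   \code{sequence}, \code{length}, \code{ln_kf}, \code{kinetic_class},
#'   \code{structural_class}, \code{source}.
#'
#' @exportClass ProteinDataset
setClass("ProteinDataset",
         representation(name = "character", records = "data.frame"))

setValidity("ProteinDataset", function(object) {
    msg <- character()
    r <- object@records
    if (length(object@name) != 1L || is.na(object@name))
        msg <- c(msg, "'name' must be a single non-NA string")
    if (!all(.RECORD_COLS %in% names(r)))
        msg <- c(msg, paste0("records must have columns: ",
                             paste(.RECORD_COLS, collapse = ", ")))
    if (nrow(r) < 1L)
        msg <- c(msg, "dataset must contain at least one record")
    if (length(msg)) return(msg)
    if (any(is.na(r$pdb_id) | !nzchar(r$pdb_id)))
        msg <- c(msg, "every record needs a non-empty pdb_id")
    if (any(!is.finite(r$ln_kf)))
        msg <- c(msg, "ln_kf must be finite for every record")
    if (any(is.na(r$length) | r$length < 1L))
        msg <- c(msg, "length must be >= 1 for every record")
    has_seq <- !is.na(r$sequence)
    if (any(has_seq & nchar(r$sequence) != r$length))
        msg <- c(msg, "length must equal the residue count of the sequence")
    if (any(has_seq)) {
        letters_used <- unique(unlist(strsplit(r$sequence[has_seq], "")))
        bad <- setdiff(letters_used, .AA_EXTENDED)
        if (length(bad))
            msg <- c(msg, paste0("invalid residue letter(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' PredictionTable: third-party folding-rate predictions for a set of proteins
#'
#' Carrier for predictions ingested from an external predictor (e.g. a web
#' server's output), keyed by PDB code. Values are always stored on the
#' natural-log scale; log10 input is converted on read.
#'
#' @slot predictorName Label for the predictor the values came from.
#' @slot predictions Named numeric vector, names are upper-cased PDB codes,
#'   values predicted \eqn{\ln(k_f)}.
#'
#' @exportClass PredictionTable
setClass("PredictionTable",
         representation(predictorName = "character", predictions = "numeric"))

setValidity("PredictionTable", function(object) {
    msg <- character()
    p <- object@predictions
    if (length(object@predictorName) != 1L)
        msg <- c(msg, "'predictorName' must be a single string")
    if (is.null(names(p)) || any(!nzchar(names(p))))
        msg <- c(msg, "predictions must be named by pdb_id")
    if (anyDuplicated(names(p)))
        msg <- c(msg, "duplicate pdb_id in predictions")
    if (any(!is.finite(p)))
        msg <- c(msg, "predictions must be finite")
    if (length(msg)) msg else TRUE
})

#' LogLinearModel: the chain-length baseline ln(kf) = a0 + a1 * ln(L)
#'
#' A two-parameter ordinary-least-squares fit of experimental log folding
#' rates against log chain length, together with its training metadata and a
#' minimal applicability domain: the inclusive residue-length range of the
#' training set.
#'
#' @slot a0 Intercept, units \eqn{\ln(s^{-1})}; \eqn{\exp(a_0)} is the
#'   pre-exponential factor of the equivalent rate law.
#' @slot a1 Slope on \eqn{\ln L} (dimensionless), negative for real data:
#'   longer chains fold more slowly.
#' @slot nTrain Number of training records (duplicated PDB codes count).
#' @slot trainingName Label of the training dataset.
#' @slot domainL Inclusive length range \code{c(Lmin, Lmax)} of the training
#'   set, used by [inDomain()].
#'
#' @exportClass LogLinearModel
setClass("LogLinearModel",
         representation(a0 = "numeric", a1 = "numeric", nTrain = "integer",
                        trainingName = "character", domainL = "numeric"))

setValidity("LogLinearModel", function(object) {
    msg <- character()
    if (!is.finite(object@a0) || !is.finite(object@a1))
        msg <- c(msg, "a0 and a1 must be finite")
    if (object@nTrain < 3L)
        msg <- c(msg, "nTrain must be >= 3")
    if (length(object@domainL) != 2L || any(!is.finite(object@domainL)) ||
        object@domainL[1L] > object@domainL[2L])
        msg <- c(msg, "domainL must be c(Lmin, Lmax) with Lmin <= Lmax")
    if (length(msg)) msg else TRUE
})

#' EvaluationReport: RMSE / PCC / MAE for one model on one dataset
#'
#' Quality measures for one evaluation mode: \code{"fit"} (residuals of the
#' training fit), \code{"loo"} (leave-one-out cross-validated predictions) or
#' \code{"external"} (predictions on a set never used in training, the
#' RMSE_PR / PCC_PR of external validation). PCC is \code{NA} when undefined
#' (constant vector or fewer than two points) -- never silently zero.
#'
#' @slot mode One of \code{"fit"}, \code{"loo"}, \code{"external"}.
#' @slot n Number of evaluated proteins after any length filter.
#' @slot rmse Root mean square error of \eqn{\ln(k_f)}.
#' @slot pcc Pearson correlation between observed and predicted, or
#'   \code{NA} when undefined.
#' @slot mae Mean absolute error.
#' @slot modelName,datasetName Labels for the model and evaluation set.
#' @slot minLength Length filter applied before evaluation (\code{NA} = none).
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
         representation(mode = "character", n = "integer", rmse = "numeric",
                        pcc = "numeric", mae = "numeric",
                        modelName = "character", datasetName = "character",
                        minLength = "integer"))

setValidity("EvaluationReport", function(object) {
    msg <- character()
    if (!object@mode %in% c("fit", "loo", "external"))
        msg <- c(msg, "mode must be 'fit', 'loo' or 'external'")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (!is.finite(object@rmse) || !is.finite(object@mae) ||
        object@rmse < 0 || object@mae < 0)
        msg <- c(msg, "rmse and mae must be finite and nonnegative")
    else if (object@rmse < object@mae - 1e-12)
        msg <- c(msg, "rmse must be >= mae")
    if (!is.na(object@pcc) && abs(object@pcc) > 1 + 1e-12)
        msg <- c(msg, "pcc must lie in [-1, 1] when defined")
    if (length(msg)) msg else TRUE
})

#' DiscrepancyReport: experimental-data disagreement between two datasets
#'
#' Pairwise comparison of two datasets over their distinct shared PDB codes:
#' how many pairs have identical vs non-identical sequences, the range and
#' mean of absolute length differences among the non-identical sequence
#' pairs, and the same summaries for experimental \eqn{\ln(k_f)} values,
#' where two rates count as non-identical when they differ by at least the
#' rate tolerance (default 0.01).
#'
#' @slot pair Names of the two compared datasets, provenance first.
#' @slot nOverlap Number of distinct shared PDB codes compared.
#' @slot rateTol Threshold on \eqn{|\Delta \ln k_f|} for "non-identical".
#' @slot seqIdentical,seqNonidentical Sequence-pair counts (pairs missing a
#'   sequence on either side are excluded; see \code{seqMissing}).
#' @slot seqMissing Pairs lacking a sequence on at least one side.
#' @slot lengthDiffRange,lengthDiffMean Range / mean of \eqn{|\Delta L|} over
#'   non-identical sequence pairs (residues); \code{NA} when there are none.
#' @slot rateIdentical,rateNonidentical Rate-pair counts.
#' @slot rateDiffRange,rateDiffMean Range / mean of \eqn{|\Delta \ln k_f|}
#'   over non-identical rate pairs; \code{NA} when there are none.
#'
#' @exportClass DiscrepancyReport
setClass("DiscrepancyReport",
         representation(pair = "character", nOverlap = "integer",
                        rateTol = "numeric",
                        seqIdentical = "integer", seqNonidentical = "integer",
                        seqMissing = "integer",
                        lengthDiffRange = "numeric", lengthDiffMean = "numeric",
                        rateIdentical = "integer", rateNonidentical = "integer",
                        rateDiffRange = "numeric", rateDiffMean = "numeric"))

setValidity("DiscrepancyReport", function(object) {
    msg <- character()
    if (length(object@pair) != 2L)
        msg <- c(msg, "'pair' must name two datasets")
    if (object@seqIdentical + object@seqNonidentical + object@seqMissing !=
        object@nOverlap)
        msg <- c(msg, "sequence pair counts must partition the overlap")
    if (object@rateIdentical + object@rateNonidentical != object@nOverlap)
        msg <- c(msg, "rate pair counts must partition the overlap")
    if (object@rateTol < 0) msg <- c(msg, "rateTol must be nonnegative")
    if (length(msg)) msg else TRUE
})
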