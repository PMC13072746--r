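#' Quantify experimental-data disagreement between two datasets
#'
#' Different compilations report different sequences, lengths and measured
#' rates for the same PDB code. `compareDatasets()` pairs the two datasets
#' over their distinct shared codes (one pair per code; when a code is
#' duplicated, its first occurrence on each side is used) and summarises:
#' how many pairs have exactly identical sequences, the range and mean of
#' absolute length differences among the non-identical sequence pairs, and
#' the same for \eqn{\ln(k_f)}, where two rates are non-identical when they
#' differ by at least `rateTol` (default 0.01, i.e. at table precision).
#'
#' Lengths are taken from the sequences where both sides have one, else
#' from the length fields. All counts, ranges and means are symmetric in
#' the two arguments.
#'
#' @param A,B [ProteinDataset-class] objects sharing at least one PDB code.
#' @param rateTol Minimum \eqn{|\Delta \ln k_f|} for a rate pair to count
#'   as non-identical.
#' @return A [DiscrepancyReport-class].
#' @examples
#' A <- ProteinDataset("A", c("1AAA", "2BBB"), c(5.00, 1.0),
#'                     sequence = c("ACDEF", "MKVLAWH"))
#' B <- ProteinDataset("B", c("1AAA", "2BBB"), c(5.009, 1.6),
#'                     sequence = c("ACDEF", "MKVLAW"))
#' compareDatasets(A, B)   # one rate and one sequence discrepancy
#' @export
compareDatasets <- function(A, B, rateTol = 0.01) {
    p <- .sharedPairs(A, B)
    if (nrow(p) == 0L)
        stop("datasets '", datasetName(A), "' and '", datasetName(B),
             "' share no PDB codes")
    both_seq <- !is.na(p$seq_A) & !is.na(p$seq_B)
    seq_id <- both_seq & p$seq_A == p$seq_B
    seq_nonid <- both_seq & !seq_id
    dL <- abs(p$L_A - p$L_B)[seq_nonid]
    # 'at least rateTol', robust to binary representation of decimal input
    rate_nonid <- abs(p$ln_kf_A - p$ln_kf_B) >= rateTol - 1e-9
    dR <- abs(p$ln_kf_A - p$ln_kf_B)[rate_nonid]
    new("DiscrepancyReport",
        pair = c(datasetName(A), datasetName(B)),
        nOverlap = nrow(p), rateTol = rateTol,
        seqIdentical = sum(seq_id), seqNonidentical = sum(seq_nonid),
        seqMissing = sum(!both_seq),
        lengthDiffRange = if (length(dL)) range(as.numeric(dL)) else
            c(NA_real_, NA_real_),
        lengthDiffMean = if (length(dL)) mean(dL) else NA_real_,
        rateIdentical = sum(!rate_nonid), rateNonidentical = sum(rate_nonid),
        rateDiffRange = if (length(dR)) range(dR) else c(NA_real_, NA_real_),
        rateDiffMean = if (length(dR)) mean(dR) else NA_real_)
}

## One row per distinct shared pdb_id, first occurrence on each side.
.sharedPairs <- function(A, B) {
    ra <- records(A)
    rb <- records(B)
    shared <- intersect(unique(ra$pdb_id), unique(rb$pdb_id))
    ia <- match(shared, ra$pdb_id)
    ib <- match(shared, rb$pdb_id)
    # sequence length is authoritative where present (class invariant makes
    # length == nchar(sequence), so the length field can be used directly)
    data.frame(pdb_id = shared,
               seq_A = ra$sequence[ia], seq_B = rb$sequence[ib],
               L_A = ra$length[ia], L_B = rb$length[ib],
               ln_kf_A = ra$ln_kf[ia], ln_kf_B = rb$ln_kf[ib],
               stringsAsFactors = FALSE)
}

#' List the discrepant pairs between two datasets
#'
#' One row per distinct shared PDB code whose two records disagree in
#' sequence, length or rate (at the `rateTol` threshold), sorted by
#' \eqn{|\Delta \ln k_f|} descending. Identical datasets give an empty
#' table.
#'
#' @inheritParams compareDatasets
#' @return A `data.frame` with columns `pdb_id`, `L_A`, `L_B`, `ln_kf_A`,
#'   `ln_kf_B`, `dL` (absolute length difference) and `dlnkf` (absolute
#'   rate difference).
#' @export
listDiscrepantPairs <- function(A, B, rateTol = 0.01) {
    p <- .sharedPairs(A, B)
    both_seq <- !is.na(p$seq_A) & !is.na(p$seq_B)
    seq_diff <- both_seq & p$seq_A != p$seq_B
    dL <- abs(p$L_A - p$L_B)
    dR <- abs(p$ln_kf_A - p$ln_kf_B)
    keep <- seq_diff | dL > 0L | dR >= rateTol - 1e-9
    out <- data.frame(pdb_id = p$pdb_id, L_A = p$L_A, L_B = p$L_B,
                      ln_kf_A = p$ln_kf_A, ln_kf_B = p$ln_kf_B,
                      dL = dL, dlnkf = dR,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    out <- out[order(-out$dlnkf), , drop = FALSE]
    rownames(out) <- NULL
    out
}

setMethod("show", "DiscrepancyReport", function(object) {
    cat("DiscrepancyReport (", object@pair[1L], ", ", object@pair[2L],
        ")\n", sep = "")
    cat("  distinct shared PDB codes:", object@nOverlap, "\n")
    cat("  sequences: ", object@seqIdentical, " identical, ",
        object@seqNonidentical, " non-identical",
        if (object@seqMissing > 0)
            paste0(" (", object@seqMissing, " pair(s) lacking a sequence)"),
        "\n", sep = "")
    if (object@seqNonidentical > 0)
        cat(sprintf("    |dL| range %g-%g, mean %.1f residues\n",
                    object@lengthDiffRange[1L], object@lengthDiffRange[2L],
                    object@lengthDiffMean))
    cat("  ln(kf) (tol ", format(object@rateTol), "): ",
        object@rateIdentical, " identical, ", object@rateNonidentical,
        " non-identical\n", sep = "")
    if (object@rateNonidentical > 0)
        cat(sprintf("    |d ln(kf)| range %.2f-%.2f, mean %.2f\n",
                    object@rateDiffRange[1L], object@rateDiffRange[2L],
                    object@rateDiffMean))
})
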