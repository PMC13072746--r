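#' Overlap and difference subsets with explicit data provenance
#'
#' Published kinetics datasets for the same proteins disagree in sequence
#' length and measured rate, so which dataset supplies the experimental data
#' for a shared protein matters. `datasetOverlap(A, B)` returns every record
#' of `A` whose PDB code also occurs in `B`, carrying `A`'s data -- the
#' provenance-first overlap conventionally written "A \eqn{\cap} B". The
#' mirror subset "B \eqn{\cap} A" is `datasetOverlap(B, A)`.
#' `datasetDifference(A, B)` ("A\\B") keeps the records of `A` whose code
#' does not occur in `B`.
#'
#' Duplicate handling follows the provenance set: every copy in `A` whose
#' code matches is kept (a dataset that lists a protein twice contributes
#' both measurements), while membership in `B` is tested against distinct
#' codes only. This is why the two overlaps of a pair can have different
#' sizes even though they share the same distinct codes.
#'
#' Record order of `A` is always preserved, and for every pair the overlap
#' and difference partition `A` exactly.
#'
#' @param A Provenance dataset ([ProteinDataset-class]): all returned data
#'   come from here.
#' @param B Dataset whose PDB codes define membership.
#' @return A [ProteinDataset-class] named `"A∩B"` / `"A\\B"` after the two
#'   input names. An empty overlap or difference is returned with zero
#'   records is impossible under the class invariant, so an empty result
#'   instead returns a zero-row dataset via a bare records table with a
#'   warning -- see Details.
#'
#' @details An empty result cannot satisfy the one-record class invariant;
#' both operations therefore warn and return `NULL` when no record
#' qualifies, which downstream code (e.g. [runBenchmark()]) treats as "this
#' subset is absent".
#'
#' @examples
#' A <- ProteinDataset("A", c("1ABC", "2DEF"), c(1, 2), length = c(60, 80))
#' B <- ProteinDataset("B", c("2DEF", "3GHI"), c(5, 6), length = c(81, 90))
#' lnKf(datasetOverlap(A, B))     # 2: data from A
#' pdbIds(datasetDifference(A, B))
#' @aliases datasetOverlap datasetDifference
#' @name datasetOverlap
NULL

#' @rdname datasetOverlap
#' @export
setMethod("datasetOverlap", signature("ProteinDataset", "ProteinDataset"),
          function(A, B) {
    keep <- pdbIds(A) %in% unique(pdbIds(B))
    nm <- paste0(datasetName(A), "∩", datasetName(B))
    if (!any(keep)) {
        warning("overlap '", nm, "' is empty")
        return(NULL)
    }
    out <- A[keep]
    datasetName(out) <- nm
    out
})

#' @rdname datasetOverlap
#' @export
setMethod("datasetDifference", signature("ProteinDataset", "ProteinDataset"),
          function(A, B) {
    keep <- !pdbIds(A) %in% unique(pdbIds(B))
    nm <- paste0(datasetName(A), "\\", datasetName(B))
    if (!any(keep)) {
        warning("difference '", nm, "' is empty")
        return(NULL)
    }
    out <- A[keep]
    datasetName(out) <- nm
    out
})

#' Check the overlap/difference partition identity
#'
#' For any pair of datasets, the provenance-first overlap and the difference
#' partition the first dataset: every record of `A` lands in exactly one of
#' them. This is the consistency audit for subset construction.
#'
#' @param A,B [ProteinDataset-class] objects.
#' @return `TRUE` iff `|A ∩ B| + |A \\ B| == |A|`.
#' @export
partitionCheck <- function(A, B) {
    ov <- suppressWarnings(datasetOverlap(A, B))
    df <- suppressWarnings(datasetDifference(A, B))
    nOv <- if (is.null(ov)) 0L else length(ov)
    nDf <- if (is.null(df)) 0L else length(df)
    nOv + nDf == length(A)
}
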