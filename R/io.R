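#' Read a protein kinetics dataset from a delimited table
#'
#' Expects a header with at least `pdb_id`, `ln_kf` and one of `sequence` /
#' `length`; `kinetic_class` and `structural_class` columns are picked up
#' when present. Record order and duplicated PDB codes are preserved, PDB
#' codes are normalised to upper case, and when a `length` column conflicts
#' with the sequence the sequence wins (with a warning).
#'
#' @param path Path to the table.
#' @param name Dataset label; defaults to the file name without extension.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param permissive Accept nonstandard residue codes (B, Z, X, U, O); see
#'   [ProteinDataset()].
#' @return A [ProteinDataset-class].
#' @seealso [writeProteinDataset()] for the inverse; the two round-trip.
#' @export
readProteinDataset <- function(path, name = NULL,
                               format = c("tsv", "csv"),
                               permissive = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    tab <- utils::read.table(path, header = TRUE,
                             sep = if (format == "tsv") "\t" else ",",
                             stringsAsFactors = FALSE, quote = "\"",
                             comment.char = "", fileEncoding = "UTF-8",
                             colClasses = NA)
    need <- c("pdb_id", "ln_kf")
    miss <- setdiff(need, names(tab))
    if (base::length(miss))
        stop("format error: missing required column(s) ",
             paste(miss, collapse = ", "))
    if (!any(c("sequence", "length") %in% names(tab)))
        stop("format error: need at least one of 'sequence'/'length' columns")
    getcol <- function(col) if (col %in% names(tab)) tab[[col]] else NULL
    ln_kf <- suppressWarnings(as.numeric(tab$ln_kf))
    bad <- which(!is.finite(ln_kf))
    if (base::length(bad))
        stop("validation error: non-finite ln_kf at row ", bad[1L],
             " (pdb_id ", tab$pdb_id[bad[1L]], ")")
    ProteinDataset(name = name,
                   pdb_id = tab$pdb_id,
                   ln_kf = ln_kf,
                   sequence = getcol("sequence"),
                   length = getcol("length"),
                   kinetic_class = getcol("kinetic_class"),
                   structural_class = getcol("structural_class"),
                   source = getcol("source"),
                   permissive = permissive)
}

#' Write a protein kinetics dataset to a delimited table
#'
#' Writes the canonical column layout (`pdb_id`, `sequence`, `length`,
#' `ln_kf`, `kinetic_class`, `structural_class`, `source`) so that
#' [readProteinDataset()] reproduces the dataset field for field, including
#' duplicated PDB codes and record order. `ln_kf` is written with full
#' precision (15 significant digits).
#'
#' @param dataset A [ProteinDataset-class].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeProteinDataset <- function(dataset, path, format = c("tsv", "csv")) {
    format <- match.arg(format)
    stopifnot(is(dataset, "ProteinDataset"))
    rec <- dataset@records
    rec$ln_kf <- sprintf("%.15g", rec$ln_kf)
    utils::write.table(rec, path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE, na = "",
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read sequences from FASTA and join them to a folding-rate table
#'
#' The first whitespace-delimited token of each FASTA header is taken as the
#' PDB code (matched case-insensitively). FASTA entries without a rate are
#' dropped with a warning; a rate whose code has no sequence is an error,
#' because the record could not satisfy the dataset invariants.
#'
#' @param fastaPath Path to a FASTA file (multi-line sequences allowed).
#' @param ratesPath Path to a delimited table with columns `pdb_id`, `ln_kf`.
#' @param name Dataset label; defaults to the FASTA file name.
#' @param format Delimiter of the rates table, `"tsv"` or `"csv"`.
#' @param permissive Accept nonstandard residue codes; see [ProteinDataset()].
#' @return A [ProteinDataset-class] in the order of the rates table.
#' @export
readFastaWithRates <- function(fastaPath, ratesPath, name = NULL,
                               format = c("tsv", "csv"), permissive = FALSE) {
    format <- match.arg(format)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(fastaPath))
    seqs <- Biostrings::readAAStringSet(fastaPath)
    ids <- toupper(vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L))
    seqchar <- as.character(seqs)
    names(seqchar) <- ids
    rates <- utils::read.table(ratesPath, header = TRUE,
                               sep = if (format == "tsv") "\t" else ",",
                               stringsAsFactors = FALSE)
    if (!all(c("pdb_id", "ln_kf") %in% names(rates)))
        stop("format error: rates table needs 'pdb_id' and 'ln_kf' columns")
    rid <- toupper(rates$pdb_id)
    missing_seq <- setdiff(rid, ids)
    if (base::length(missing_seq))
        stop("rate entries with no FASTA sequence: ",
             paste(missing_seq, collapse = ", "))
    unmatched <- setdiff(ids, rid)
    if (base::length(unmatched))
        warning(base::length(unmatched), " FASTA entr",
                if (base::length(unmatched) == 1) "y" else "ies",
                " without a rate dropped: ",
                paste(unmatched, collapse = ", "))
    ProteinDataset(name = name, pdb_id = rid,
                   ln_kf = as.numeric(rates$ln_kf),
                   sequence = unname(seqchar[rid]),
                   permissive = permissive)
}

#' Read a third-party prediction table
#'
#' Two-column table `pdb_id`, `ln_kf_pred` (a column literally named
#' `prediction` is also accepted). Predictions supplied on the log10 scale
#' are converted to natural log by multiplying by \eqn{\ln 10}; the returned
#' table is always natural-log.
#'
#' @param path Path to the table.
#' @param predictorName Label for the predictor.
#' @param scale Scale of the input values: `"natural-log"` (default) or
#'   `"log10"`.
#' @param format `"tsv"` or `"csv"`.
#' @return A [PredictionTable-class].
#' @export
readPredictionTable <- function(path, predictorName,
                                scale = c("natural-log", "log10"),
                                format = c("tsv", "csv")) {
    scale <- match.arg(scale)
    format <- match.arg(format)
    tab <- utils::read.table(path, header = TRUE,
                             sep = if (format == "tsv") "\t" else ",",
                             stringsAsFactors = FALSE)
    valcol <- intersect(c("ln_kf_pred", "prediction"), names(tab))
    if (!"pdb_id" %in% names(tab) || !base::length(valcol))
        stop("format error: need columns 'pdb_id' and 'ln_kf_pred'")
    PredictionTable(predictorName, tab$pdb_id, tab[[valcol[1L]]],
                    scale = scale)
}

#' Construct a PredictionTable from vectors
#'
#' @param predictorName Label for the predictor.
#' @param pdb_id PDB codes (normalised to upper case, must be unique).
#' @param prediction Predicted folding rates.
#' @param scale `"natural-log"` (default) or `"log10"`; log10 values are
#'   converted to natural log.
#' @return A [PredictionTable-class].
#' @export
PredictionTable <- function(predictorName, pdb_id, prediction,
                            scale = c("natural-log", "log10")) {
    scale <- match.arg(scale)
    pdb_id <- toupper(as.character(pdb_id))
    if (anyDuplicated(pdb_id))
        stop("duplicate pdb_id in predictions: ",
             paste(unique(pdb_id[duplicated(pdb_id)]), collapse = ", "))
    prediction <- as.numeric(prediction)
    if (scale == "log10") prediction <- prediction * log(10)
    names(prediction) <- pdb_id
    new("PredictionTable", predictorName = predictorName,
        predictions = prediction)
}

#' @describeIn PredictionTable Number of predictions in the table.
#' @param x A [PredictionTable-class].
#' @export
setMethod("length", "PredictionTable", function(x) base::length(x@predictions))

setMethod("show", "PredictionTable", function(object) {
    cat("PredictionTable '", object@predictorName, "': ",
        base::length(object@predictions), " predictions (natural log)\n",
        sep = "")
})
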