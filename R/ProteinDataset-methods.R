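#' Construct a ProteinDataset from vectors
#'
#' Low-level constructor; most users will call [readProteinDataset()] or
#' [simulateDataset()] instead. Exactly one of `sequence` / `length` may be
#' omitted: lengths are computed from sequences when sequences are present,
#' and when both are supplied the sequence is authoritative (a conflicting
#' `length` entry is replaced with a warning).
#'
#' @param name Dataset label.
#' @param pdb_id Character vector of PDB codes (normalised to upper case;
#'   duplicates are permitted and preserved).
#' @param ln_kf Numeric vector of experimental natural-log folding rates.
#' @param sequence Optional character vector of amino-acid sequences
#'   (`NA` entries allowed).
#' @param length Optional integer vector of chain lengths.
#' @param kinetic_class,structural_class Optional class tags; free text is
#'   normalised to the canonical labels where recognised.
#' @param source Per-record source label; defaults to `name`.
#' @param permissive Accept the ambiguity/rare codes B, Z, X, U, O in
#'   sequences (they still count toward the length). Default `FALSE`:
#'   only the 20 standard residues are allowed.
#' @return A [ProteinDataset-class] object.
#' @examples
#' d <- ProteinDataset("toy", pdb_id = c("1ABC", "2DEF"),
#'                     sequence = c("ACDEFG", "MKVLAW"), ln_kf = c(4.2, -1.0))
#' chainLengths(d)
#' @export
ProteinDataset <- function(name, pdb_id, ln_kf, sequence = NULL,
                           length = NULL, kinetic_class = NULL,
                           structural_class = NULL, source = NULL,
                           permissive = FALSE) {
    n <- base::length(pdb_id)
    if (is.null(sequence) && is.null(length))
        stop("at least one of 'sequence' and 'length' must be supplied")
    pdb_id <- toupper(as.character(pdb_id))
    ln_kf <- as.numeric(ln_kf)
    if (!is.null(sequence)) {
        sequence <- toupper(as.character(sequence))
        sequence[!is.na(sequence) & !nzchar(sequence)] <- NA_character_
        .checkResidues(sequence, pdb_id, permissive = permissive)
    } else {
        sequence <- rep(NA_character_, n)
    }
    seq_len_obs <- ifelse(is.na(sequence), NA_integer_, nchar(sequence))
    if (is.null(length)) {
        length <- seq_len_obs
    } else {
        length <- as.integer(length)
        conflict <- !is.na(seq_len_obs) & !is.na(length) &
            seq_len_obs != length
        if (any(conflict)) {
            warning(sum(conflict), " record(s) had a length column ",
                    "conflicting with the sequence; sequence wins (",
                    paste(utils::head(pdb_id[conflict], 5L), collapse = ", "),
                    ")")
        }
        length <- ifelse(is.na(seq_len_obs), length, seq_len_obs)
    }
    bad_rate <- !is.finite(ln_kf)
    if (any(bad_rate))
        stop("non-finite ln_kf at row(s) ",
             paste(which(bad_rate), collapse = ", "))
    rec <- data.frame(
        pdb_id = pdb_id,
        sequence = sequence,
        length = as.integer(length),
        ln_kf = ln_kf,
        kinetic_class = .normaliseClass(kinetic_class, n, .KINETIC_CLASSES),
        structural_class = .normaliseClass(structural_class, n,
                                           .STRUCTURAL_CLASSES),
        source = if (is.null(source)) rep(name, n) else as.character(source),
        stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    new("ProteinDataset", name = name, records = rec)
}

.checkResidues <- function(sequence, pdb_id, permissive = FALSE) {
    alphabet <- if (permissive) .AA_EXTENDED else .AA_STANDARD
    for (i in which(!is.na(sequence))) {
        letters_i <- strsplit(sequence[i], "")[[1]]
        bad <- setdiff(unique(letters_i), alphabet)
        if (base::length(bad))
            stop("invalid residue letter(s) '", paste(bad, collapse = "', '"),
                 "' in sequence of record ", i, " (", pdb_id[i], ")")
    }
    invisible(TRUE)
}

.normaliseClass <- function(x, n, allowed) {
    if (is.null(x)) return(rep(NA_character_, n))
    x <- tolower(trimws(as.character(x)))
    x[x == ""] <- NA_character_
    # common synonyms seen in published tables
    x[x %in% c("ts", "2s", "two state", "two-state folder")] <- "two-state"
    x[x %in% c("ms", "n2s", "non-two-state", "multi state",
               "multi-state folder")] <- "multi-state"
    x[x %in% c("a", "alpha", "all-a")] <- "all-alpha"
    x[x %in% c("b", "beta", "all-b")] <- "all-beta"
    x[x %in% c("ab", "alpha-beta", "alpha/beta", "mixed class")] <- "mixed"
    unknown <- !is.na(x) & !x %in% allowed
    if (any(unknown)) x[unknown] <- "unknown"
    x
}

#' Accessors for ProteinDataset
#'
#' @param x A [ProteinDataset-class].
#' @param value Replacement dataset name.
#' @return `datasetName` the label; `pdbIds` the (possibly duplicated) PDB
#'   codes in record order; `chainLengths` integer residue counts; `lnKf`
#'   experimental log rates; `records` the full record `data.frame`.
#' @name ProteinDataset-accessors
#' @aliases datasetName pdbIds chainLengths lnKf records datasetName<-
NULL

#' @rdname ProteinDataset-accessors
#' @export
setMethod("datasetName", "ProteinDataset", function(x) x@name)

#' @rdname ProteinDataset-accessors
#' @export
setReplaceMethod("datasetName", "ProteinDataset", function(x, value) {
    x@name <- value
    validObject(x)
    x
})

#' @rdname ProteinDataset-accessors
#' @export
setMethod("pdbIds", "ProteinDataset", function(x) x@records$pdb_id)

#' @rdname ProteinDataset-accessors
#' @export
setMethod("chainLengths", "ProteinDataset", function(x) x@records$length)

#' @rdname ProteinDataset-accessors
#' @export
setMethod("lnKf", "ProteinDataset", function(x) x@records$ln_kf)

#' @rdname ProteinDataset-accessors
#' @export
setMethod("records", "ProteinDataset", function(x) x@records)

#' @describeIn ProteinDataset-accessors Number of records (duplicates count).
#' @export
setMethod("length", "ProteinDataset", function(x) nrow(x@records))

#' Subset a ProteinDataset by record index
#'
#' @param x A [ProteinDataset-class].
#' @param i Integer or logical index over records.
#' @param j,drop,... Ignored.
#' @return A [ProteinDataset-class] with the selected records, order as in
#'   `i`.
#' @export
setMethod("[", "ProteinDataset", function(x, i, j, ..., drop = FALSE) {
    rec <- x@records[i, , drop = FALSE]
    rownames(rec) <- NULL
    initialize(x, records = rec)
})

#' Coerce a ProteinDataset to a data.frame of its records
#'
#' @param x A [ProteinDataset-class].
#' @param ... Ignored.
#' @return The record `data.frame` (a copy).
#' @export
setMethod("as.data.frame", "ProteinDataset",
          function(x, ...) x@records)

setMethod("show", "ProteinDataset", function(object) {
    r <- object@records
    ndup <- nrow(r) - base::length(unique(r$pdb_id))
    cat("ProteinDataset '", object@name, "': ", nrow(r), " proteins",
        if (ndup > 0) paste0(" (", ndup, " duplicated PDB code",
                             if (ndup > 1) "s", ")"), "\n", sep = "")
    cat("  length L: ", min(r$length), "-", max(r$length), " residues",
        if (all(is.na(r$sequence))) " (no sequences)", "\n", sep = "")
    cat(sprintf("  ln(kf): %.2f to %.2f\n", min(r$ln_kf), max(r$ln_kf)))
})
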