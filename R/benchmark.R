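#' Run the full pairwise benchmark for two kinetics datasets
#'
#' The end-to-end comparison workflow for a dataset pair (A, B): build the
#' four provenance-aware subsets A∩B, B∩A, A\\B and B\\A; fit a
#' chain-length baseline on each overlap; evaluate each baseline by fitting
#' statistics and LOO cross-validation on its training overlap and by
#' external prediction on both difference subsets; and evaluate any
#' supplied third-party prediction tables on the same subsets. The result
#' is one long-format comparison table.
#'
#' Baselines are labelled `"MO(A∩B)"` / `"MO(B∩A)"` after their training
#' subsets. Warnings (empty difference subsets, unmatched prediction ids,
#' undefined correlations) never abort the benchmark: the affected rows are
#' simply absent.
#'
#' @param A,B [ProteinDataset-class] objects.
#' @param predictions Optional list of [PredictionTable-class] objects to
#'   evaluate alongside the fitted baselines.
#' @param minLength Optional length filter applied when evaluating the
#'   prediction tables (emulating servers that require \eqn{L \ge}
#'   `minLength`); baselines are evaluated unfiltered.
#' @return A `data.frame` with one row per (model, subset, mode) and
#'   columns `model`, `subset`, `mode`, `n`, `rmse`, `pcc`, `mae`,
#'   `min_length`, sorted by model then subset. Full precision; use
#'   [renderReport()] for 2-decimal display output.
#' @examples
#' base <- simulateDataset(60, seed = 11, sequences = FALSE)$dataset
#' A <- base[1:45];  datasetName(A) <- "A"
#' B <- simulateVariant(base[16:60], seed = 12)$dataset
#' datasetName(B) <- "B"
#' head(runBenchmark(A, B))
#' @export
runBenchmark <- function(A, B, predictions = NULL, minLength = NULL) {
    stopifnot(is(A, "ProteinDataset"), is(B, "ProteinDataset"))
    subsets <- list(
        datasetOverlap(A, B), datasetOverlap(B, A),
        datasetDifference(A, B), datasetDifference(B, A))
    subsets <- Filter(Negate(is.null), subsets)
    names(subsets) <- vapply(subsets, datasetName, "")
    overlaps <- subsets[grepl("∩", names(subsets), fixed = TRUE)]
    differences <- subsets[grepl("\\", names(subsets), fixed = TRUE)]
    rows <- list()
    add <- function(report, model, subset) {
        df <- as.data.frame(report)
        df$model <- model
        df$subset <- subset
        rows[[length(rows) + 1L]] <<- df
    }
    for (ov in overlaps) {
        mlab <- paste0("MO(", datasetName(ov), ")")
        fit <- fitLogLinear(ov)
        add(evaluateFit(fit, ov), mlab, datasetName(ov))
        add(looValidate(ov), mlab, datasetName(ov))
        for (df in differences)
            add(evaluateExternal(fit, df), mlab, datasetName(df))
    }
    for (pt in predictions) {
        for (sub in subsets) {
            rep <- tryCatch(
                suppressWarnings(
                    evaluateExternal(pt, sub, minLength = minLength)),
                error = function(e) NULL)
            if (!is.null(rep))
                add(rep, pt@predictorName, datasetName(sub))
        }
    }
    if (!length(rows))
        return(data.frame(model = character(), subset = character(),
                          mode = character(), n = integer(),
                          rmse = numeric(), pcc = numeric(),
                          mae = numeric(), min_length = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[, c("model", "subset", "mode", "n", "rmse", "pcc", "mae",
                   "min_length")]
    out <- out[order(out$model, out$subset, out$mode), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a benchmark comparison table to disk
#'
#' TSV and markdown renderings round the statistics to 2 decimals (3 for
#' correlations), the convention of published comparison tables; JSON
#' serialises full precision. Row order is deterministic (model, then
#' subset, then mode). An empty table yields a header-only file.
#'
#' @param table A comparison `data.frame` from [runBenchmark()].
#' @param path Output path.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
renderReport <- function(table, path, format = c("tsv", "json", "markdown")) {
    format <- match.arg(format)
    stopifnot(is.data.frame(table))
    ord <- order(table$model, table$subset, table$mode)
    table <- table[ord, , drop = FALSE]
    if (format == "json") {
        jsonlite::write_json(table, path, dataframe = "rows",
                             auto_unbox = TRUE, digits = NA, na = "null")
        return(invisible(path))
    }
    disp <- table
    if (nrow(disp)) {
        disp$rmse <- sprintf("%.2f", disp$rmse)
        disp$mae <- sprintf("%.2f", disp$mae)
        disp$pcc <- ifelse(is.na(table$pcc), "undefined",
                           sprintf("%.3f", table$pcc))
    }
    if (format == "tsv") {
        utils::write.table(disp, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "")
    } else {
        hdr <- paste0("| ", paste(names(disp), collapse = " | "), " |")
        sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"),
                      "|")
        body <- apply(disp, 1L, function(r)
            paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "),
                   " |"))
        writeLines(c(hdr, sep, body), path)
    }
    invisible(path)
}
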