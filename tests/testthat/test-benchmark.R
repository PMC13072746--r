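makeBenchPair <- function(seed, nBase = 70, nA = 50, overlapStart = 21) {
    base <- simulateDataset(nBase, seed = seed, sequences = FALSE)$dataset
    A <- base[1:nA]
    datasetName(A) <- "A"
    B <- base[overlapStart:nBase]
    datasetName(B) <- "B"
    list(A = A, B = B)
}

test_that("the benchmark table covers both baselines in all three modes", {
    p <- makeBenchPair(41)
    tab <- runBenchmark(p$A, p$B)
    expect_s3_class(tab, "data.frame")
    expect_named(tab, c("model", "subset", "mode", "n", "rmse", "pcc",
                        "mae", "min_length"))
    moA <- tab[tab$model == "MO(A∩B)", ]
    expect_setequal(moA$mode[moA$subset == "A∩B"], c("fit", "loo"))
    expect_setequal(moA$subset[moA$mode == "external"],
                    c("A\\B", "B\\A"))
    # n values satisfy the partition identity per source dataset
    nOvA <- unique(moA$n[moA$subset == "A∩B"])
    nDfA <- unique(tab$n[tab$subset == "A\\B"])
    expect_equal(nOvA + nDfA, length(p$A))
})

test_that("benchmark errors on a shared-truth pair stay near the generating noise", {
    # both halves generated from one truth (sigma = 2.6): fit, LOO and
    # external RMSE of the baselines should all sit within sampling error
    # of sigma
    p <- makeBenchPair(42, nBase = 110, nA = 75, overlapStart = 31)
    tab <- runBenchmark(p$A, p$B)
    mo <- tab[grepl("^MO", tab$model), ]
    expect_true(all(mo$rmse > 1.6 & mo$rmse < 3.6))
})

test_that("prediction tables ride along on every subset they cover", {
    p <- makeBenchPair(43)
    ov <- datasetOverlap(p$A, p$B)
    pt <- simulateOverfitPredictor(ov, datasetDifference(p$B, p$A),
                                   seed = 44, predictorName = "srv")
    tab <- runBenchmark(p$A, p$B, predictions = list(pt))
    srv <- tab[tab$model == "srv", ]
    expect_true(all(srv$mode == "external"))
    expect_true("A∩B" %in% srv$subset)
})

test_that("a pair with no overlap yields no baseline rows but does not abort", {
    A <- simulateDataset(10, seed = 45, sequences = FALSE,
                         name = "A")$dataset
    B <- simulateDataset(10, seed = 46, sequences = FALSE,
                         name = "B")$dataset
    stopifnot(length(intersect(pdbIds(A), pdbIds(B))) == 0)
    tab <- suppressWarnings(runBenchmark(A, B))
    expect_equal(nrow(tab[grepl("^MO", tab$model), ]), 0L)
})

test_that("renderReport writes tsv, markdown and full-precision json deterministically", {
    p <- makeBenchPair(47)
    tab <- runBenchmark(p$A, p$B)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    renderReport(tab, tsv, "tsv")
    back <- read.delim(tsv, check.names = FALSE)
    expect_equal(nrow(back), nrow(tab))
    expect_match(as.character(back$rmse[1]), "^[0-9]+\\.[0-9]{2}$")

    md <- withr::local_tempfile(fileext = ".md")
    renderReport(tab, md, "markdown")
    lines <- readLines(md)
    expect_equal(length(lines), nrow(tab) + 2L)   # header + rule + rows

    js <- withr::local_tempfile(fileext = ".json")
    renderReport(tab, js, "json")
    parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
    expect_equal(parsed$rmse, tab$rmse, tolerance = 1e-12)  # full precision
    # byte-identical on re-render
    js2 <- withr::local_tempfile(fileext = ".json")
    renderReport(tab, js2, "json")
    expect_identical(readLines(js), readLines(js2))
})

test_that("an empty table renders as a header-only file", {
    empty <- runBenchmark(
        simulateDataset(8, seed = 48, sequences = FALSE,
                        name = "A")$dataset,
        simulateDataset(8, seed = 49, sequences = FALSE,
                        name = "B")$dataset) |> suppressWarnings()
    tsv <- withr::local_tempfile(fileext = ".tsv")
    renderReport(empty, tsv, "tsv")
    expect_equal(length(readLines(tsv)), 1L)
})
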