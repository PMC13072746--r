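test_that("a dataset compared with itself shows no discrepancies", {
    d <- toyDataset()
    rep <- compareDatasets(d, d)
    expect_equal(rep@nOverlap, 3L)
    expect_equal(rep@seqNonidentical, 0L)
    expect_equal(rep@rateNonidentical, 0L)
    expect_true(is.na(rep@rateDiffMean))
    expect_equal(nrow(listDiscrepantPairs(d, d)), 0L)
})

test_that("the rate threshold is 'at least 0.01', inclusive at the boundary", {
    A <- ProteinDataset("A", c("1AAA", "2BBB"), c(5.000, 5.000),
                        length = c(50, 60))
    B <- ProteinDataset("B", c("1AAA", "2BBB"), c(5.009, 5.010),
                        length = c(50, 60))
    rep <- compareDatasets(A, B)
    expect_equal(rep@rateIdentical, 1L)      # |d| = 0.009 < 0.01
    expect_equal(rep@rateNonidentical, 1L)   # |d| = 0.010 >= 0.01
})

test_that("raising the rate tolerance never increases the nonidentical count", {
    sim <- simulateDataset(40, seed = 21)
    var <- simulateVariant(sim$dataset, seed = 22)
    tols <- c(0.001, 0.01, 0.1, 0.5, 1)
    counts <- vapply(tols, function(tol)
        compareDatasets(sim$dataset, var$dataset, rateTol = tol)
        @rateNonidentical, 0L)
    expect_true(all(diff(counts) <= 0L))
})

test_that("comparison is symmetric in its arguments", {
    sim <- simulateDataset(30, seed = 23)
    var <- simulateVariant(sim$dataset, seed = 24)
    ab <- compareDatasets(sim$dataset, var$dataset)
    ba <- compareDatasets(var$dataset, sim$dataset)
    for (slot in c("nOverlap", "seqIdentical", "seqNonidentical",
                   "rateIdentical", "rateNonidentical",
                   "lengthDiffMean", "rateDiffMean"))
        expect_equal(methods::slot(ab, slot), methods::slot(ba, slot))
    expect_equal(ab@rateDiffRange, ba@rateDiffRange)
})

test_that("duplicated codes contribute one comparison pair (first occurrence)", {
    A <- ProteinDataset("A", c("1UBQ", "1UBQ", "2BBB"), c(7.3, 5.9, 2),
                        length = c(76, 76, 80))
    B <- ProteinDataset("B", c("1UBQ", "2BBB"), c(7.3, 2.5),
                        length = c(76, 80))
    rep <- compareDatasets(A, B)
    expect_equal(rep@nOverlap, 2L)           # distinct shared codes
    expect_equal(rep@rateNonidentical, 1L)   # only 2BBB differs, 7.3 == 7.3
})

test_that("discrepant pair listing is sorted by rate gap and covers length-only cases", {
    A <- ProteinDataset("A", c("1AAA", "2BBB", "3CCC"), c(1, 2, 3),
                        sequence = c("ACDEF", "MKVLAW", "GGSST"))
    B <- ProteinDataset("B", c("1AAA", "2BBB", "3CCC"), c(1, 2, 4.5),
                        sequence = c("ACDEF", "MKVLAWH", "GGSST"))
    tab <- listDiscrepantPairs(A, B)
    expect_equal(nrow(tab), 2L)
    expect_equal(tab$pdb_id, c("3CCC", "2BBB"))   # |d ln kf| descending
    expect_equal(tab$dlnkf, c(1.5, 0))            # length-only row has 0
    expect_equal(tab$dL, c(0L, 1L))
})

test_that("known perturbations are reconstructed exactly", {
    base <- ProteinDataset("base", sprintf("%04d", 1:6),
                           ln_kf = c(0, 1, 2, 3, 4, 5),
                           length = rep(100L, 6))
    shifted <- records(base)
    shifted$ln_kf[c(2, 4, 6)] <- shifted$ln_kf[c(2, 4, 6)] + 0.5
    B <- ProteinDataset("B", shifted$pdb_id, shifted$ln_kf,
                        length = shifted$length)
    rep <- compareDatasets(base, B)
    expect_equal(rep@rateNonidentical, 3L)
    expect_equal(rep@rateDiffMean, 0.5, tolerance = 1e-12)
    expect_equal(nrow(listDiscrepantPairs(base, B)), 3L)
})

test_that("the variant generator's log reconciles with the discrepancy report", {
    sim <- simulateDataset(50, seed = 31)
    var <- simulateVariant(sim$dataset, pRateChange = 1,
                           rateDeltaMean = 0.5, pSeqChange = 0.3,
                           seed = 32)
    rep <- compareDatasets(sim$dataset, var$dataset)
    lg <- var$log
    effective <- abs(lg$rate_delta) >= 0.01     # below-threshold shifts
    expect_equal(rep@rateNonidentical, sum(effective))
    expect_equal(rep@rateDiffMean, mean(abs(lg$rate_delta[effective])),
                 tolerance = 1e-9)
    expect_equal(rep@seqNonidentical, sum(lg$seq_changed))
})

test_that("disjoint datasets are an error", {
    A <- ProteinDataset("A", "1AAA", 1, length = 50)
    B <- ProteinDataset("B", "2BBB", 2, length = 60)
    expect_error(compareDatasets(A, B), "share no PDB codes")
})
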