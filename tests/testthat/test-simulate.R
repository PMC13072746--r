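test_that("generation is deterministic under a fixed seed", {
    a <- simulateDataset(20, seed = 77)
    b <- simulateDataset(20, seed = 77)
    expect_equal(records(a$dataset), records(b$dataset))
    expect_equal(a$truth, b$truth)
    c <- simulateDataset(20, seed = 78)
    expect_false(identical(records(a$dataset), records(c$dataset)))
})

test_that("generated datasets satisfy their declared structure", {
    sim <- simulateDataset(60, lRange = c(40L, 400L), seed = 13)
    d <- sim$dataset
    expect_true(all(chainLengths(d) >= 40L & chainLengths(d) <= 400L))
    expect_false(anyDuplicated(pdbIds(d)) > 0)
    expect_true(all(nchar(pdbIds(d)) == 4L))
    expect_equal(nchar(records(d)$sequence), chainLengths(d))
    # rates decompose exactly into trend + recorded residuals
    expect_equal(lnKf(d),
                 sim$truth$a0 + sim$truth$a1 * log(chainLengths(d)) +
                     sim$truth$residuals, tolerance = 1e-12)
})

test_that("a zero-noise draw is exactly identifiable", {
    sim <- simulateDataset(15, sigma = 0, seed = 14, sequences = FALSE)
    m <- fitLogLinear(sim$dataset)
    expect_equal(m@a0, 30.4, tolerance = 1e-9)
    expect_equal(m@a1, -6.0, tolerance = 1e-9)
})

test_that("degenerate configurations are refused", {
    expect_error(simulateDataset(3, seed = 1), "n >= 4")
    expect_error(simulateDataset(10, lRange = c(100L, 100L), seed = 1),
                 "infeasible|degenerate")
})

test_that("variant generation is a no-op at zero perturbation probabilities", {
    sim <- simulateDataset(25, seed = 15)
    var <- simulateVariant(sim$dataset, pSeqChange = 0, pRateChange = 0,
                           seed = 16)
    rep <- compareDatasets(sim$dataset, var$dataset)
    expect_equal(rep@seqNonidentical, 0L)
    expect_equal(rep@rateNonidentical, 0L)
    expect_true(all(!var$log$seq_changed))
    expect_true(all(var$log$rate_delta == 0))
})

test_that("variant edits respect the length cap and keep all identifiers", {
    sim <- simulateDataset(40, seed = 17)
    var <- simulateVariant(sim$dataset, pSeqChange = 1, maxLenDelta = 10L,
                           pRateChange = 0, seed = 18)
    expect_equal(pdbIds(var$dataset), pdbIds(sim$dataset))
    dL <- abs(chainLengths(var$dataset) - chainLengths(sim$dataset))
    expect_true(all(dL >= 1L & dL <= 10L))
    expect_equal(as.integer(abs(var$log$len_delta)), as.integer(dL))
})

test_that("realised rate shifts centre on the configured mean", {
    sim <- simulateDataset(400, seed = 19, sequences = FALSE)
    var <- simulateVariant(sim$dataset, pRateChange = 1, pSeqChange = 0,
                           rateDeltaMean = 0.5, seed = 20)
    shifts <- abs(var$log$rate_delta)
    # exponential with mean 0.5: SE = 0.5/sqrt(400) = 0.025
    expect_equal(mean(shifts), 0.5, tolerance = 4 * 0.025)
    expect_equal(compareDatasets(sim$dataset, var$dataset)@rateDiffMean,
                 mean(shifts[shifts >= 0.01]), tolerance = 1e-9)
})

test_that("the overfit predictor is exact when noiseless and reproducible", {
    tr <- simulateDataset(20, seed = 25, sequences = FALSE,
                          name = "tr")$dataset
    te <- simulateDataset(15, seed = 26, sequences = FALSE,
                          name = "te")$dataset
    pt0 <- simulateOverfitPredictor(tr, te, sigmaTrain = 0, sigmaTest = 0,
                                    biasTest = 0, seed = 27)
    expect_equal(evaluateExternal(pt0, tr)@rmse, 0, tolerance = 1e-12)
    expect_equal(evaluateExternal(pt0, te)@rmse, 0, tolerance = 1e-12)
    p1 <- simulateOverfitPredictor(tr, te, seed = 28)
    p2 <- simulateOverfitPredictor(tr, te, seed = 28)
    expect_equal(p1@predictions, p2@predictions)
})
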