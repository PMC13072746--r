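test_that("rmse, pcc and mae reproduce hand-computed values", {
    expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
    expect_equal(rmse(0, 3), 3)
    expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
    expect_equal(mae(0, 3), 3)
    expect_equal(pcc(c(1, 2, 3), c(1, 3, 2)), 0.5)
    expect_error(rmse(1:3, 1:2), "mismatch")
    expect_error(rmse(numeric(), numeric()), "empty")
})

test_that("pcc is affine-invariant and flags undefined cases instead of zeroing", {
    x <- c(0.3, 1.7, -2.2, 4.1)
    expect_equal(pcc(x, 2 * x + 1), 1)
    expect_equal(pcc(x, -x), -1)
    expect_warning(p <- pcc(c(1, 2, 3), c(5, 5, 5)),
                   class = "undefinedCorrelationWarning")
    expect_true(is.na(p))
    expect_warning(pcc(1, 1), class = "undefinedCorrelationWarning")
})

test_that("rmse dominates mae on arbitrary inputs (power-mean inequality)", {
    set.seed(99)
    for (i in 1:20) {
        o <- rnorm(sample(2:40, 1))
        p <- o + rnorm(length(o), sd = runif(1, 0, 3))
        expect_gte(rmse(o, p), mae(o, p))
    }
})

test_that("fit evaluation is exact on noiseless data and matches residual RMS", {
    sim <- simulateDataset(12, sigma = 0, seed = 5, sequences = FALSE)
    m <- fitLogLinear(sim$dataset)
    r <- evaluateFit(m, sim$dataset)
    expect_equal(r@rmse, 0, tolerance = 1e-9)
    expect_equal(r@pcc, 1, tolerance = 1e-9)
    # noisy case: report equals the residual root-mean-square by definition
    d <- randomDataset(30, seed = 6)
    m2 <- fitLogLinear(d)
    res <- lnKf(d) - predict(m2, chainLengths(d))
    expect_equal(evaluateFit(m2, d)@rmse, sqrt(mean(res^2)),
                 tolerance = 1e-12)
})

test_that("refit-based LOO equals the leverage identity and never beats the fit", {
    for (seed in 1:10) {
        d <- randomDataset(n = 12 + 2 * seed, seed = 100 + seed)
        loo <- looValidate(d)
        oracle <- looLeverageOracle(d)
        expect_equal(loo@rmse, unname(oracle["rmse"]), tolerance = 1e-9)
        expect_equal(loo@pcc, unname(oracle["pcc"]), tolerance = 1e-9)
        expect_equal(loo@mae, unname(oracle["mae"]), tolerance = 1e-9)
        expect_gte(loo@rmse, evaluateFit(fitLogLinear(d), d)@rmse)
    }
})

test_that("LOO rejects undersized or degenerate-on-removal designs", {
    tiny <- ProteinDataset("t", sprintf("%04d", 1:3), ln_kf = 1:3,
                           length = c(50L, 60L, 70L))
    expect_error(looValidate(tiny), "insufficient")
    # removing the single distinct-length record degenerates the design
    deg <- ProteinDataset("d", sprintf("%04d", 1:4), ln_kf = 1:4,
                          length = c(50L, 50L, 50L, 90L))
    expect_error(looValidate(deg), "degenerate")
})

test_that("external evaluation with the training set equals the fit report", {
    d <- randomDataset(25, seed = 8)
    m <- fitLogLinear(d)
    fit <- evaluateFit(m, d)
    ext <- evaluateExternal(m, d)
    expect_equal(ext@rmse, fit@rmse, tolerance = 1e-12)
    expect_equal(ext@pcc, fit@pcc, tolerance = 1e-12)
    expect_equal(ext@mae, fit@mae, tolerance = 1e-12)
    expect_equal(ext@mode, "external")
})

test_that("the minimum-length filter drops short chains and reports the retained n", {
    d <- ProteinDataset("f", c("1AAA", "2BBB", "3CCC"),
                        ln_kf = c(7, 4, 1), length = c(45L, 60L, 70L))
    m <- LogLinearModel(30, -6, 10)
    r <- evaluateExternal(m, d, minLength = 50)
    expect_equal(r@n, 2L)
    expect_equal(r@minLength, 50L)
    expect_error(evaluateExternal(m, d, minLength = 500), "length filter")
})

test_that("prediction tables are matched by PDB code, never refit", {
    d <- ProteinDataset("t", c("1AAA", "2BBB", "3CCC"),
                        ln_kf = c(7, 4, 1), length = c(45L, 60L, 70L))
    exact <- PredictionTable("perfect", pdbIds(d), lnKf(d))
    expect_equal(evaluateExternal(exact, d)@rmse, 0)
    partial <- PredictionTable("partial", c("1AAA", "2BBB"), c(7.5, 3.5))
    expect_warning(r <- evaluateExternal(partial, d), "3CCC")
    expect_equal(r@n, 2L)
    expect_equal(r@rmse, 0.5)
    one <- PredictionTable("one", "1AAA", 7)
    expect_error(suppressWarnings(evaluateExternal(one, d)),
                 "fewer than 2")
})

test_that("reports serialise full precision via as.data.frame", {
    d <- randomDataset(15, seed = 9)
    r <- evaluateFit(fitLogLinear(d), d)
    df <- as.data.frame(r)
    expect_equal(df$rmse, r@rmse)           # no display rounding
    expect_named(df, c("model", "dataset", "mode", "n", "rmse", "pcc",
                       "mae", "min_length"))
})
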