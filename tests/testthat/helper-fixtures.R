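# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

toyDataset <- function(name = "toy",
                       ids = c("1AAA", "2BBB", "3CCC"),
                       ln_kf = c(4.2, -1.0, 2.5),
                       sequence = c("ACDEFG", "MKVLAWHH", "GGSST")) {
    ProteinDataset(name, pdb_id = ids, ln_kf = ln_kf, sequence = sequence)
}

# Random length-only dataset for regression property tests (fast: no
# sequence generation).
randomDataset <- function(n = 30, seed = NULL, name = "rnd", sigma = 2) {
    simulateDataset(n, seed = seed, sigma = sigma, name = name,
                    sequences = FALSE)$dataset
}

# A pair of datasets with a controlled overlap and duplicated ids in A:
# A = records 1..nA of a base set with its first two ids repeated,
# B = a perturbed copy of records (nA-k+1)..(nA+nB-k) under the same ids.
overlappingPair <- function(seed, nA = 20, nB = 15, k = 8) {
    base <- simulateDataset(nA + nB - k, seed = seed, sequences = FALSE,
                            name = "base")$dataset
    recA <- records(base)[c(1:nA, 1L, 2L), ]
    A <- ProteinDataset("A", pdb_id = recA$pdb_id, ln_kf = recA$ln_kf,
                        length = recA$length)
    recB <- records(base)[(nA - k + 1):(nA + nB - k), ]
    B <- ProteinDataset("B", pdb_id = recB$pdb_id,
                        ln_kf = recB$ln_kf + 0.1, length = recB$length)
    list(A = A, B = B)
}

# Independent OLS oracle: normal equations via lm().
olsOracle <- function(dataset) {
    fit <- lm(lnKf(dataset) ~ log(chainLengths(dataset)))
    unname(coef(fit))
}

# Independent LOO oracle: the leverage identity for simple regression --
# held-out residual_i = fit residual_i / (1 - h_i) with
# h_i = 1/n + (x_i - xbar)^2 / Sxx.
looLeverageOracle <- function(dataset) {
    x <- log(chainLengths(dataset))
    y <- lnKf(dataset)
    n <- length(x)
    xc <- x - mean(x)
    a1 <- sum(xc * (y - mean(y))) / sum(xc^2)
    a0 <- mean(y) - a1 * mean(x)
    e <- y - (a0 + a1 * x)
    h <- 1 / n + xc^2 / sum(xc^2)
    e_loo <- e / (1 - h)
    held <- y - e_loo
    c(rmse = sqrt(mean(e_loo^2)), pcc = cor(y, held),
      mae = mean(abs(e_loo)))
}
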