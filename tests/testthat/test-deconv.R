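test_that("makeMixture is the per-gene convex combination", {
    A <- c(g1 = 100, g2 = 200)
    B <- c(g1 = 300, g2 = 0)
    expect_equal(makeMixture(A, B, 0.25), c(g1 = 250, g2 = 50))
    expect_equal(makeMixture(A, B, 1), A)
    expect_equal(makeMixture(A, B, 0), B)
    expect_error(makeMixture(A, B, 1.5), "alpha")
})

test_that("probe-set mismatches are rejected with the offending probes", {
    A <- c(g1 = 1, g2 = 2)
    expect_error(makeMixture(A, c(g1 = 1, g3 = 2), 0.5), "g3")
    expect_error(makeMixture(A, c(g2 = 2, g1 = 1), 0.5), "order")
})

test_that("the default grid spans 0.1% to 99.9% in 0.1% steps", {
    g <- defaultGrid()
    expect_equal(g[1], 0.001)
    expect_equal(g[length(g)], 0.999)
    expect_length(g, 999)
    expect_equal(unique(round(diff(g), 12)), 0.001)
})

test_that("scanAlpha recovers an exact grid member with perfect correlation", {
    cfg <- simConfig(nGenes = 300, seed = 11)
    mono <- genMonocultures(cfg)
    obs <- makeMixture(mono$A, mono$B, 0.400)
    s <- scanAlpha(mono$A, mono$B, obs)
    expect_equal(alphaHat(s), 0.400)
    expect_lt(abs(corrMax(s) - 1), 1e-12)
})

test_that("swapping the two monocultures reflects the estimate around 1/2", {
    cfg <- simConfig(nGenes = 250, seed = 13)
    mono <- genMonocultures(cfg)
    obs <- makeMixture(mono$A, mono$B, 0.317)
    sAB <- scanAlpha(mono$A, mono$B, obs)
    sBA <- scanAlpha(mono$B, mono$A, obs)
    expect_equal(alphaHat(sAB) + alphaHat(sBA), 1)
})

test_that("an off-grid mixture lands on the bracketing grid values and
           matches a finer brute-force search", {
    cfg <- simConfig(nGenes = 400, seed = 17)
    mono <- genMonocultures(cfg)
    A <- mono$A[, 1]
    B <- mono$B[, 1]
    obs <- 0.3517 * A + (1 - 0.3517) * B
    s <- scanAlpha(mono$A, mono$B, obs)
    expect_true(alphaHat(s) %in% c(0.351, 0.352))
    fine <- oracleAlphaSearch(A, B, obs, seq(0.0001, 0.9999, by = 1e-4))
    expect_equal(alphaHat(s), round(fine, 3))
})

test_that("scan argmax agrees exactly with an independent exhaustive search", {
    for (s in 1:6) {
        cfg <- simConfig(nGenes = 200, alphaTrue = runif(1, 0.1, 0.9),
                         noiseLogSd = 0.3, nReplicates = 1, seed = s)
        mono <- genMonocultures(cfg)
        cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
        got <- alphaHat(scanAlpha(mono$A, mono$B, cc[, 1]))
        want <- oracleAlphaSearch(mono$A[, 1], mono$B[, 1], cc[, 1],
                                  defaultGrid())
        expect_identical(got, want)
    }
})

test_that("zero-variance observations are rejected", {
    A <- c(g1 = 1, g2 = 5, g3 = 9)
    B <- c(g1 = 2, g2 = 4, g3 = 8)
    obs <- c(g1 = 3, g2 = 3, g3 = 3)
    expect_error(scanAlpha(A, B, obs), "zero variance")
})

test_that("expectedProfile floors at the pseudocount and flags floored genes", {
    A <- c(g1 = 0, g2 = 10)
    B <- c(g1 = 0, g2 = 30)
    e <- expectedProfile(A, B, 0.5)
    expect_equal(unname(e["g1"]), 1)
    expect_equal(unname(e["g2"]), 20)
    expect_identical(unname(attr(e, "atFloor")), c(TRUE, FALSE))
})

test_that("the scanned expected profile reproduces a noiseless mixture", {
    cfg <- simConfig(nGenes = 300, alphaTrue = 0.5, noiseLogSd = 0,
                     nReplicates = 1, seed = 19)
    mono <- genMonocultures(cfg)
    cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
    s <- scanAlpha(mono$A, mono$B, cc[, 1])
    e <- expectedProfile(mono$A, mono$B, alphaHat(s))
    relErr <- abs(e - cc[, 1]) / cc[, 1]
    expect_lt(max(relErr), 1e-9)
})

test_that("per-replicate deconvolution recovers alpha within the grid
           resolution under mild noise", {
    cfg <- simConfig(nGenes = 1000, alphaTrue = 0.5, noiseLogSd = 0.1,
                     nReplicates = 3, seed = 23)
    mono <- genMonocultures(cfg)
    cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
    dec <- perReplicateDeconvolve(mono$A, mono$B, cc)
    expect_length(dec$scans, 3)
    expect_true(all(abs(dec$alphaHats - 0.5) <= 0.02))
})

test_that("ratios are exactly one for a noiseless interaction-free mixture", {
    cfg <- simConfig(nGenes = 200, alphaTrue = 0.5, noiseLogSd = 0,
                     nReplicates = 2, seed = 29)
    mono <- genMonocultures(cfg)
    cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
    dec <- perReplicateDeconvolve(mono$A, mono$B, cc)
    expect_equal(unname(dec$ratios), matrix(1, 200, 2), tolerance = 1e-12)
})

test_that("zero co-culture replicates give an empty result without error", {
    cfg <- simConfig(nGenes = 50, seed = 2)
    mono <- genMonocultures(cfg)
    empty <- matrix(numeric(0), nrow = 50, ncol = 0,
                    dimnames = list(rownames(mono$A), NULL))
    dec <- perReplicateDeconvolve(mono$A, mono$B, empty)
    expect_length(dec$scans, 0)
    expect_length(dec$alphaHats, 0)
})

test_that("a replicate equal to one monoculture saturates at the grid edge", {
    cfg <- simConfig(nGenes = 120, seed = 31)
    mono <- genMonocultures(cfg)
    dec <- perReplicateDeconvolve(mono$A, mono$B,
                                  matrix(mono$A, ncol = 1,
                                         dimnames = list(rownames(mono$A),
                                                         "pureA")))
    expect_equal(dec$alphaHats, 0.999)
})

test_that("quantile normalization preserves shape and equalizes quantiles", {
    cfg <- simConfig(nGenes = 500, seed = 37)
    mono <- genMonocultures(cfg)
    x <- cbind(a = mono$A[, 1], b = 3 * mono$B[, 1])
    qn <- quantileNormalizeArrays(x)
    expect_identical(dimnames(qn), dimnames(x))
    expect_equal(sort(qn[, 1]), sort(qn[, 2]), ignore_attr = TRUE)
})
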