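test_that("configuration validation names the offending field", {
    expect_error(simConfig(nGenes = 0), "nGenes")
    expect_error(simConfig(nGenes = 10, alphaTrue = 1), "alphaTrue")
    expect_error(simConfig(nGenes = 10, alphaTrue = 0), "alphaTrue")
    expect_error(simConfig(nGenes = 10, baselineLogSd = -1), "baselineLogSd")
    expect_error(simConfig(nGenes = 10, noiseLogSd = -0.1), "noiseLogSd")
    expect_error(simConfig(nGenes = 10, nInteraction = 11, effectLog2 = 1),
                 "nInteraction")
    expect_error(simConfig(nGenes = 10, nInteraction = 2,
                           effectLog2 = c(1, 2, 3)), "effectLog2")
})

test_that("monoculture generation is deterministic and seed-sensitive", {
    cfg <- simConfig(nGenes = 200, seed = 42)
    m1 <- genMonocultures(cfg)
    m2 <- genMonocultures(cfg)
    expect_identical(m1, m2)
    m3 <- genMonocultures(simConfig(nGenes = 200, seed = 43))
    expect_false(identical(m1$A, m3$A))
    expect_true(all(m1$A > 0) && all(m1$B > 0))
    expect_identical(rownames(m1$A), rownames(m1$B))
})

test_that("zero cell-type divergence gives identical monoculture profiles", {
    mono <- genMonocultures(simConfig(nGenes = 100, betweenCelltypeSd = 0,
                                      seed = 1))
    expect_equal(unname(mono$A[, 1]), unname(mono$B[, 1]))
})

test_that("baseline log2 intensities match the generative model at large n", {
    cfg <- simConfig(nGenes = 10000, seed = 7)
    mono <- genMonocultures(cfg)
    se <- cfg@baselineLogSd / sqrt(cfg@nGenes)
    expect_lt(abs(mean(log2(mono$A[, 1])) - cfg@baselineLogMean), 3 * se)
})

test_that("noise-free co-culture equals the exact linear mixture", {
    cfg <- simConfig(nGenes = 150, alphaTrue = 0.3, noiseLogSd = 0,
                     nReplicates = 2, seed = 5)
    mono <- genMonocultures(cfg)
    cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
    mix <- 0.3 * mono$A[, 1] + 0.7 * mono$B[, 1]
    expect_equal(unname(cc[, 1]), unname(mix))
    expect_equal(unname(cc[, 2]), unname(mix))
})

test_that("a spiked gene multiplies the mixture by its effect, others do not", {
    cfg <- simConfig(nGenes = 50, alphaTrue = 0.4, noiseLogSd = 0,
                     nInteraction = 1, effectLog2 = 1, nReplicates = 1,
                     seed = 8)
    truth <- simTruth(cfg)
    mono <- genMonocultures(cfg)
    cc <- genCoculture(mono$A, mono$B, truth)
    mix <- 0.4 * mono$A[, 1] + 0.6 * mono$B[, 1]
    ratio <- cc[, 1] / mix
    spiked <- interactionGenes(truth)
    expect_equal(unname(ratio[spiked]), 2.0)
    expect_equal(unname(ratio[setdiff(names(ratio), spiked)]),
                 rep(1.0, cfg@nGenes - 1))
})

test_that("compartment-resolved effects act on a single compartment", {
    cfg <- simConfig(nGenes = 30, alphaTrue = 0.5, noiseLogSd = 0,
                     nInteraction = 1, effectLog2 = 1, nReplicates = 1,
                     seed = 12)
    truth <- simTruth(cfg)
    mono <- genMonocultures(cfg)
    g <- interactionGenes(truth)
    ccA <- genCoculture(mono$A, mono$B, truth, effectCompartment = "A")
    expect_equal(ccA[g, 1],
                 unname(0.5 * mono$A[g, 1] * 2 + 0.5 * mono$B[g, 1]))
    ccB <- genCoculture(mono$A, mono$B, truth, effectCompartment = "B")
    expect_equal(ccB[g, 1],
                 unname(0.5 * mono$A[g, 1] + 0.5 * mono$B[g, 1] * 2))
})

test_that("replicate random streams are split: earlier replicates unchanged", {
    cfg3 <- simConfig(nGenes = 80, noiseLogSd = 0.2, nReplicates = 3,
                      seed = 9)
    cfg4 <- simConfig(nGenes = 80, noiseLogSd = 0.2, nReplicates = 4,
                      seed = 9)
    mono <- genMonocultures(cfg3)
    cc3 <- genCoculture(mono$A, mono$B, simTruth(cfg3))
    cc4 <- genCoculture(mono$A, mono$B, simTruth(cfg4))
    expect_identical(cc3, cc4[, 1:3])
})

test_that("mixture closure: exact mixture lies between the monocultures", {
    for (s in 1:5) {
        cfg <- simConfig(nGenes = 60, alphaTrue = runif(1, 0.05, 0.95),
                         noiseLogSd = 0, nReplicates = 1, seed = s)
        mono <- genMonocultures(cfg)
        cc <- genCoculture(mono$A, mono$B, simTruth(cfg))[, 1]
        lo <- pmin(mono$A[, 1], mono$B[, 1])
        hi <- pmax(mono$A[, 1], mono$B[, 1])
        expect_true(all(cc >= lo - 1e-9) && all(cc <= hi + 1e-9))
    }
})

test_that("limiting-dilution plates honor the boundary frequencies", {
    allNeg <- genEldaPlates(0, nReplicates = 2, seed = 1)
    for (p in allNeg)
        expect_true(all(eldaSummary(p)$negative == eldaSummary(p)$tested))
    allPos <- genEldaPlates(1, nReplicates = 2, seed = 1)
    for (p in allPos)
        expect_true(all(eldaSummary(p)$negative == 0))
})

test_that("negative-well counts follow the binomial expectation", {
    plates <- genEldaPlates(1/9, nReplicates = 1000, seed = 77)
    fracNeg9 <- vapply(plates, function(p) {
        s <- eldaSummary(p)
        s$negative[s$dose == 9] / s$tested[s$dose == 9]
    }, numeric(1))
    p <- (8/9)^9
    se <- sqrt(p * (1 - p) / 12 / 1000)
    expect_lt(abs(mean(fracNeg9) - p), 3 * se)
})

test_that("noise-free Ct values encode relative expression exactly", {
    ct <- genCtTable(c(same = 1, dbl = 2), ctRefMean = 22, noiseSd = 0,
                     nSamples = 1, seed = 3)
    ref <- ct@data$ct[ct@data$gene == "GAPDH"]
    expect_equal(ct@data$ct[ct@data$gene == "same"], ref)
    expect_equal(ct@data$ct[ct@data$gene == "dbl"], ref - 1)
})

test_that("ddCt back-computation recovers true relative expression", {
    ct <- genCtTable(c(up = 2, down = 0.25), noiseSd = 0.2, nSamples = 50,
                     seed = 1)
    tab <- ddctTable(ct)
    ## geometric mean: the natural (and unbiased) average for expression
    ## ratios under multiplicative noise
    est <- tapply(tab$expression, tab$gene,
                  function(x) exp(mean(log(x)))) / ct@scaleUnits
    expect_lt(abs(est[["up"]] / 2 - 1), 0.05)
    expect_lt(abs(est[["down"]] / 0.25 - 1), 0.05)
})

test_that("Ct generation rejects invalid expression values", {
    expect_error(genCtTable(c(g = -1)), "positive")
    expect_error(genCtTable(c(2)), "named")
    expect_error(genCtTable(c(GAPDH = 2)), "reference")
})
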