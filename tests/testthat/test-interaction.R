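test_that("signed fold change follows the ratio convention", {
    expect_equal(signedFoldChange(2.20), 2.20)
    expect_equal(signedFoldChange(0.5), -2.0)
    expect_equal(signedFoldChange(1.0), 1.0)
    expect_error(signedFoldChange(0), "positive")
    expect_error(signedFoldChange(-2), "positive")
})

test_that("fold-change involution: r and 1/r map to opposite signs of equal
           magnitude", {
    set.seed(41)
    r <- exp(rnorm(200))
    r <- r[abs(log(r)) > 1e-6]
    expect_equal(signedFoldChange(r), -sign(signedFoldChange(1 / r)) *
                                       abs(signedFoldChange(r)))
    expect_equal(abs(signedFoldChange(r)), abs(signedFoldChange(1 / r)))
    expect_true(all(abs(signedFoldChange(r)) >= 1))
})

test_that("replicate t-test matches the closed-form t CDF and is two-sided", {
    expect_equal(unname(replicateTest(rbind(c(0, 0, 0)))), 1)
    set.seed(43)
    for (k in 1:20) {
        x <- rnorm(sample(3:6, 1), mean = runif(1, -1, 1))
        got <- unname(replicateTest(rbind(x)))
        expect_equal(got, oracleOneSampleP(x), tolerance = 1e-10)
        expect_equal(got, unname(replicateTest(rbind(-x))),
                     tolerance = 1e-12)
        expect_equal(got, stats::t.test(x)$p.value, tolerance = 1e-10)
    }
    expect_equal(unname(replicateTest(rbind(c(1.0, 1.1, 0.9)))),
                 oracleOneSampleP(c(1.0, 1.1, 0.9)), tolerance = 1e-10)
})

test_that("zero-variance nonzero-mean genes get a protected minimal p, not 0", {
    p <- unname(replicateTest(rbind(c(0.5, 0.5, 0.5))))
    expect_gt(p, 0)
    expect_lt(p, 1e-6)
})

test_that("a single replicate is rejected with guidance", {
    expect_error(replicateTest(rbind(c(1))), "single replicate")
})

test_that("moderated p-values exist, are valid and track the plain test", {
    set.seed(47)
    x <- matrix(rnorm(300 * 3, 0, 0.3), ncol = 3)
    x[1:10, ] <- x[1:10, ] + 2
    rownames(x) <- sprintf("g%03d", 1:300)
    p <- replicateTest(x, method = "moderated")
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(rank(p)[1:10] <= 20))
})

test_that("BH adjustment matches a hand-coded step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(53)
    for (k in 1:10) {
        p <- runif(sample(c(1, 5, 100), 1))
        adj <- bhAdjust(p)
        expect_equal(adj, oracleBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("the calling rule is strict on p and inclusive on fold change", {
    ratios <- rbind(a = c(2.2, 2.2, 2.2), b = c(1.99, 1.99, 1.99),
                    c = c(2.0, 2.0, 2.0), d = c(1.0, 1.0, 1.0))
    out <- callInteractionGenes(ratios)
    ## all three non-null genes have tiny p (floored variance)
    expect_true(out$called[out$probe == "a"])
    expect_false(out$called[out$probe == "b"])   # |FC| = 1.99 < 2
    expect_true(out$called[out$probe == "c"])    # |FC| = 2 exactly: >= rule
    expect_false(out$called[out$probe == "d"])
    ## strict inequality on the adjusted p-value
    expect_false(any(out$called & out$pBH >= 0.05))
})

test_that("empty input yields an empty table", {
    out <- callInteractionGenes(matrix(numeric(0), nrow = 0, ncol = 3))
    expect_equal(nrow(out), 0)
    expect_named(out, c("probe", "meanLog2Ratio", "foldChange", "pRaw",
                        "pBH", "called", "lowConfidence"))
})

test_that("called genes have fold-change signs coherent with their mean log2
           ratio", {
    set.seed(59)
    shift <- c(rep(c(2, -2), 25), rep(0, 450))
    ratios <- matrix(2^(rnorm(500 * 3, 0, 0.3) + rep(shift, 3)), ncol = 3,
                     dimnames = list(sprintf("g%03d", 1:500), NULL))
    out <- callInteractionGenes(ratios, qThreshold = 0.5, fcThreshold = 1.2)
    expect_true(any(out$called))
    expect_true(all(sign(out$foldChange[out$called]) ==
                    sign(out$meanLog2Ratio[out$called])))
    ## fold change never inside (-1, 1)
    expect_true(all(abs(out$foldChange) >= 1))
})

test_that("full pipeline calling equals an independently coded reference rule", {
    cfg <- simConfig(nGenes = 10000, alphaTrue = 0.5, nInteraction = 50,
                     effectLog2 = rep(c(2, -2), 25), noiseLogSd = 0.3,
                     nReplicates = 3, seed = 61)
    mono <- genMonocultures(cfg)
    cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
    res <- deconvolveCoculture(mono$A, mono$B, cc)
    ## reference implementation on the same per-replicate ratios
    lg <- log2(res$deconvolution$ratios)
    pRef <- apply(lg, 1, oracleOneSampleP)
    adjRef <- oracleBH(pRef)
    mRef <- rowMeans(lg)
    fcRef <- ifelse(2^mRef >= 1, 2^mRef, -2^(-mRef))
    calledRef <- adjRef < 0.05 & abs(fcRef) >= 2
    expect_identical(sum(res$table$called), sum(calledRef))
    expect_identical(res$table$probe[res$table$called],
                     names(calledRef)[calledRef])
})

test_that("sensitivity under variance moderation reaches the regression
           bound for four-fold spikes", {
    sens <- vapply(1:100, function(s) {
        cfg <- simConfig(nGenes = 2000, alphaTrue = 0.5, nInteraction = 50,
                         effectLog2 = 2, noiseLogSd = 0.25, nReplicates = 3,
                         seed = s)
        truth <- simTruth(cfg)
        mono <- genMonocultures(cfg)
        cc <- genCoculture(mono$A, mono$B, truth)
        res <- deconvolveCoculture(mono$A, mono$B, cc, method = "moderated")
        mean(interactionGenes(truth) %in% res$table$probe[res$table$called])
    }, numeric(1))
    expect_gte(mean(sens), 0.8)
})

test_that("low-confidence flags propagate from floored expected intensities", {
    A <- c(g1 = 0, g2 = 500, g3 = 800)
    B <- c(g1 = 0, g2 = 600, g3 = 100)
    cc <- cbind(rep1 = c(g1 = 2, g2 = 550, g3 = 400),
                rep2 = c(g1 = 2.2, g2 = 545, g3 = 410))
    res <- deconvolveCoculture(A, B, cc)
    expect_true(res$table$lowConfidence[res$table$probe == "g1"])
    expect_false(any(res$table$lowConfidence[res$table$probe != "g1"]))
})
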