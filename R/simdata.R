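#' Build a simulation configuration
#'
#' Constructor for \linkS4class{SimConfig}. Defaults emulate Illumina
#' BeadArray-style summary intensities: heavy-tailed (log-normal) per-gene
#' intensities around \eqn{2^8}, a broad per-gene divergence between the two
#' monoculture cell types so their profiles are clearly distinct, an equal
#' mixture, three co-culture replicates, and mild multiplicative measurement
#' noise.
#'
#' @param nGenes number of probes.
#' @param baselineLogMean mean of baseline log2 intensities (default 8).
#' @param baselineLogSd SD of baseline log2 intensities (default 2).
#' @param betweenCelltypeSd SD of the per-gene log2 offset distinguishing cell
#'   type B from cell type A (default 2).
#' @param alphaTrue true fraction of cell type A in the mixture (default 0.5).
#' @param nInteraction number of interaction-affected genes (default 0).
#' @param effectLog2 log2 effects for the interaction genes; a scalar is
#'   recycled to length \code{nInteraction}.
#' @param noiseLogSd log2-scale SD of per-replicate multiplicative noise
#'   (default 0.1).
#' @param nReplicates number of co-culture replicates (default 3).
#' @param seed integer seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 500, alphaTrue = 0.3, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes,
                      baselineLogMean = 8,
                      baselineLogSd = 2,
                      betweenCelltypeSd = 2,
                      alphaTrue = 0.5,
                      nInteraction = 0L,
                      effectLog2 = numeric(0),
                      noiseLogSd = 0.1,
                      nReplicates = 3L,
                      seed = 1L) {
    nInteraction <- as.integer(nInteraction)
    if (length(effectLog2) == 1L && nInteraction > 1L)
        effectLog2 <- rep(effectLog2, nInteraction)
    new("SimConfig",
        nGenes = as.integer(nGenes),
        baselineLogMean = as.numeric(baselineLogMean),
        baselineLogSd = as.numeric(baselineLogSd),
        betweenCelltypeSd = as.numeric(betweenCelltypeSd),
        alphaTrue = as.numeric(alphaTrue),
        nInteraction = nInteraction,
        effectLog2 = as.numeric(effectLog2),
        noiseLogSd = as.numeric(noiseLogSd),
        nReplicates = as.integer(nReplicates),
        seed = as.integer(seed))
}

#' Derive the ground-truth ledger of a configuration
#'
#' Chooses (reproducibly, from the configuration seed) which probes carry an
#' interaction effect and assigns them the configured log2 effects.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimTruth}.
#' @examples
#' tr <- simTruth(simConfig(nGenes = 100, nInteraction = 5,
#'                          effectLog2 = 2, seed = 3))
#' interactionGenes(tr)
#' @export
simTruth <- function(config) {
    validObject(config)
    probes <- probeIds(config@nGenes)
    genes <- character(0)
    eff <- numeric(0)
    if (config@nInteraction > 0L) {
        set.seed(childSeed(config@seed, 2L))
        genes <- sort(sample(probes, config@nInteraction))
        eff <- config@effectLog2
        names(eff) <- genes
    }
    new("SimTruth", alphaTrue = config@alphaTrue, interactionGenes = genes,
        perGeneEffect = eff, config = config)
}

#' Simulate the two monoculture expression profiles
#'
#' Per-gene intensities for cell type A are \eqn{2^{N(\mu, \sigma)}}; cell
#' type B applies an additional per-gene log2 offset \eqn{N(0, \tau)} to the
#' same baseline, so \code{betweenCelltypeSd = 0} makes the two profiles
#' identical. Intensities are strictly positive by construction.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{A} and \code{B}, each a single-column
#'   probes x 1 intensity matrix over the same probe set.
#' @examples
#' mono <- genMonocultures(simConfig(nGenes = 10, seed = 1))
#' head(mono$A)
#' @export
genMonocultures <- function(config) {
    validObject(config)
    n <- config@nGenes
    probes <- probeIds(n)
    set.seed(childSeed(config@seed, 1L))
    base <- stats::rnorm(n, config@baselineLogMean, config@baselineLogSd)
    offset <- if (config@betweenCelltypeSd > 0)
        stats::rnorm(n, 0, config@betweenCelltypeSd) else numeric(n)
    A <- matrix(2^base, ncol = 1, dimnames = list(probes, "monoA"))
    B <- matrix(2^(base + offset), ncol = 1, dimnames = list(probes, "monoB"))
    list(A = A, B = B)
}

#' Simulate co-culture replicate profiles
#'
#' Each replicate is the linear mixture of the two monoculture profiles at the
#' true fraction, with the interaction effect \eqn{2^{e_g}} applied to its
#' genes and independent multiplicative noise \eqn{2^{N(0,\sigma_\epsilon)}}
#' per gene and replicate. By default the effect multiplies the summed mixture
#' signal, since a bulk assay only sees the pooled RNA;
#' \code{effectCompartment} restricts it to one compartment's contribution for
#' sensitivity studies.
#'
#' @param monoA,monoB monoculture profiles from [genMonocultures()].
#' @param truth a \linkS4class{SimTruth} (carries alpha, effects, noise,
#'   replicate count and seed).
#' @param effectCompartment \code{"mixture"} (default), \code{"A"} or
#'   \code{"B"}.
#' @return probes x replicates intensity matrix (columns
#'   \code{coculture_1}, ...).
#' @examples
#' cfg <- simConfig(nGenes = 50, noiseLogSd = 0, seed = 2)
#' mono <- genMonocultures(cfg)
#' cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
#' @export
genCoculture <- function(monoA, monoB, truth,
                         effectCompartment = c("mixture", "A", "B")) {
    effectCompartment <- match.arg(effectCompartment)
    stopifnot(is(truth, "SimTruth"))
    validObject(truth)
    checkExpressionMatrix(monoA, "monoA")
    checkExpressionMatrix(monoB, "monoB")
    checkSharedProbes(monoA, monoB, "monoA", "monoB")
    cfg <- truth@config
    a <- truth@alphaTrue
    A <- monoA[, 1L]
    B <- monoB[, 1L]
    e <- numeric(length(A))
    names(e) <- rownames(monoA)
    if (length(truth@perGeneEffect)) {
        missing <- setdiff(names(truth@perGeneEffect), names(e))
        if (length(missing))
            stop("interaction genes absent from the monoculture probe set: ",
                 paste(missing, collapse = ", "))
        e[names(truth@perGeneEffect)] <- truth@perGeneEffect
    }
    clean <- switch(effectCompartment,
        mixture = (a * A + (1 - a) * B) * 2^e,
        A = a * A * 2^e + (1 - a) * B,
        B = a * A + (1 - a) * B * 2^e)
    out <- matrix(NA_real_, nrow = length(A), ncol = cfg@nReplicates,
                  dimnames = list(rownames(monoA),
                                  paste0("coculture_", seq_len(cfg@nReplicates))))
    for (r in seq_len(cfg@nReplicates)) {
        if (cfg@noiseLogSd > 0) {
            set.seed(childSeed(cfg@seed, 10L + r))
            eps <- 2^stats::rnorm(length(A), 0, cfg@noiseLogSd)
        } else {
            eps <- 1
        }
        out[, r] <- clean * eps
    }
    out
}

#' Simulate limiting-dilution plates
#'
#' Under the single-hit Poisson model a well seeded with \code{d} cells is
#' sphere-free with probability \eqn{(1-f)^d}; negative-well counts per dose
#' are Binomial(\code{wellsPerDose}, \eqn{(1-f)^d}).
#'
#' @param trueFreq true clonogenic frequency in [0, 1].
#' @param doses cells per well (default the 81/27/9/3/1 five-dose design).
#' @param wellsPerDose technical replicate wells per dose (default 12).
#' @param nReplicates number of plates (biological replicates) to simulate.
#' @param seed integer seed.
#' @param groupLabel label stored on each plate.
#' @return list of \linkS4class{EldaPlate}, length \code{nReplicates}.
#' @examples
#' genEldaPlates(1/9, nReplicates = 2, seed = 5)[[1]]
#' @export
genEldaPlates <- function(trueFreq, doses = c(81L, 27L, 9L, 3L, 1L),
                          wellsPerDose = 12L, nReplicates = 1L, seed = 1L,
                          groupLabel = "simulated") {
    if (length(trueFreq) != 1L || !is.finite(trueFreq) ||
        trueFreq < 0 || trueFreq > 1)
        stop("trueFreq must be a single value in [0, 1]")
    doses <- as.integer(doses)
    lapply(seq_len(nReplicates), function(r) {
        set.seed(childSeed(seed, 100L + r))
        pNeg <- (1 - trueFreq)^doses
        neg <- stats::rbinom(length(doses), wellsPerDose, pNeg)
        eldaPlate(doses = doses, tested = rep(as.integer(wellsPerDose),
                                              length(doses)),
                  negative = neg,
                  groupLabel = sprintf("%s_%d", groupLabel, r))
    })
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct values are \code{ctRefMean} plus Gaussian noise; a target
#' with true relative expression \eqn{x} sits \eqn{\log_2 x} cycles below the
#' reference (one cycle per doubling), plus independent noise.
#'
#' @param trueRelExpr named positive vector of true expression relative to the
#'   reference gene (reference = 1).
#' @param refGene reference gene name (default \code{"GAPDH"}).
#' @param ctRefMean mean reference Ct in cycles (default 20).
#' @param noiseSd Gaussian Ct noise SD in cycles (default 0).
#' @param nSamples number of samples (default 3).
#' @param seed integer seed.
#' @param scaleUnits arbitrary-unit scale stored on the table (default 10000).
#' @return a \linkS4class{CtTable}.
#' @examples
#' genCtTable(c(THBS1 = 2), noiseSd = 0.2, nSamples = 3, seed = 4)
#' @export
genCtTable <- function(trueRelExpr, refGene = "GAPDH", ctRefMean = 20,
                       noiseSd = 0, nSamples = 3L, seed = 1L,
                       scaleUnits = 10000) {
    if (is.null(names(trueRelExpr)) || any(!nzchar(names(trueRelExpr))))
        stop("trueRelExpr must be a named vector")
    if (any(!is.finite(trueRelExpr)) || any(trueRelExpr <= 0))
        stop("trueRelExpr values must be strictly positive")
    if (refGene %in% names(trueRelExpr))
        stop("the reference gene has relative expression 1 by definition; ",
             "do not include it in trueRelExpr")
    genes <- c(names(trueRelExpr), refGene)
    trueCt <- c(ctRefMean - log2(trueRelExpr), ctRefMean)
    names(trueCt) <- genes
    rows <- vector("list", nSamples)
    for (s in seq_len(nSamples)) {
        set.seed(childSeed(seed, 200L + s))
        noise <- if (noiseSd > 0)
            stats::rnorm(length(genes), 0, noiseSd) else numeric(length(genes))
        rows[[s]] <- data.frame(sample = sprintf("S%02d", s), gene = genes,
                                ct = trueCt + noise)
    }
    ctTable(do.call(rbind, rows), refGene = refGene, scaleUnits = scaleUnits)
}
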