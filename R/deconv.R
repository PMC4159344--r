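#' Computational mixture of two monoculture profiles
#'
#' Per-gene convex combination on linear intensities:
#' \eqn{m_g = \alpha A_g + (1-\alpha) B_g}.
#'
#' @param profileA,profileB single-sample profiles (named numeric vectors or
#'   1-column matrices) over the same probe set, in the same order.
#' @param alpha fraction of cell type A, in [0, 1].
#' @return named numeric vector of mixed intensities.
#' @examples
#' makeMixture(c(g1 = 100, g2 = 200), c(g1 = 300, g2 = 0), 0.25)
#' @export
makeMixture <- function(profileA, profileB, alpha) {
    A <- asProfile(profileA, "profileA")
    B <- asProfile(profileB, "profileB")
    checkSharedProbes(A, B, "profileA", "profileB")
    if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1)
        stop("alpha must be a single value in [0, 1]")
    alpha * A + (1 - alpha) * B
}

#' Default mixing-fraction grid
#'
#' Fractions 0.001 to 0.999 in 0.001 steps (999 candidate mixtures, from
#' 0.1\%/99.9\% to 99.9\%/0.1\%).
#'
#' @return numeric vector of length 999.
#' @export
defaultGrid <- function() seq_len(999L) / 1000

#' Scan candidate mixing fractions by Pearson correlation
#'
#' For every fraction on the grid, forms the computational mixture of the two
#' monoculture profiles and computes its Pearson correlation with the observed
#' mixed profile; the grid value with the highest correlation is the mixing
#' fraction estimate. The correlation is taken on log2(intensity +
#' pseudocount) by default so that it is not dominated by the brightest genes;
#' \code{scale = "linear"} computes it on raw intensities instead. Ties at the
#' maximum are broken toward the smallest fraction and reported via
#' \code{message()}.
#'
#' @param profileA,profileB monoculture profiles (cell types A and B).
#' @param observed measured mixed (co-culture) profile over the same probes.
#' @param grid candidate fractions, strictly increasing within (0, 1).
#' @param scale \code{"log2"} (default) or \code{"linear"}.
#' @param pseudocount added before the log2 transform (default 1).
#' @return a \linkS4class{MixtureScan}.
#' @examples
#' cfg <- simConfig(nGenes = 200, seed = 11)
#' mono <- genMonocultures(cfg)
#' obs <- makeMixture(mono$A, mono$B, 0.4)
#' alphaHat(scanAlpha(mono$A, mono$B, obs))
#' @export
scanAlpha <- function(profileA, profileB, observed, grid = defaultGrid(),
                      scale = c("log2", "linear"), pseudocount = 1) {
    scale <- match.arg(scale)
    A <- asProfile(profileA, "profileA")
    B <- asProfile(profileB, "profileB")
    obs <- asProfile(observed, "observed")
    checkSharedProbes(A, B, "profileA", "profileB")
    checkSharedProbes(A, obs, "profileA", "observed")
    if (length(grid) == 0L || any(grid <= 0) || any(grid >= 1) ||
        any(diff(grid) <= 0))
        stop("grid must be strictly increasing within (0, 1)")
    r <- as.vector(scanCurves(A, B, cbind(obs), grid, scale, pseudocount))
    hit <- which(r == max(r))
    if (length(hit) > 1L)
        message("scanAlpha: ", length(hit),
                " grid points tied at the maximum correlation; ",
                "reporting the smallest fraction")
    new("MixtureScan", alphas = as.numeric(grid), correlations = r,
        alphaHat = grid[hit[1L]], corrMax = r[hit[1L]], scale = scale,
        nTies = length(hit))
}

## Pearson correlation of every candidate mixture (one per grid point) with
## every observed column. Each mixture is formed once and correlated against
## all observations, keeping the working set to a single gene-length vector
## even for genome-sized probe sets and a dense grid.
scanCurves <- function(A, B, obsMat, grid, scale, pseudocount) {
    O <- unname(obsMat)
    if (scale == "log2") O <- log2(O + pseudocount)
    O <- sweep(O, 2L, colMeans(O))
    oNorm <- sqrt(colSums(O^2))
    if (any(oNorm == 0))
        stop("observed profile has zero variance after transform; ",
             "Pearson correlation is undefined")
    Au <- unname(A)
    Bu <- unname(B)
    r <- matrix(NA_real_, nrow = length(grid), ncol = ncol(obsMat))
    for (i in seq_along(grid)) {
        m <- grid[i] * Au + (1 - grid[i]) * Bu
        if (scale == "log2") m <- log2(m + pseudocount)
        m <- m - mean(m)
        mNorm <- sqrt(sum(m^2))
        if (mNorm == 0)
            stop("a candidate mixture has zero variance after transform; ",
                 "Pearson correlation is undefined")
        r[i, ] <- crossprod(O, m) / (mNorm * oNorm)
    }
    r
}

#' Expected (null-interaction) profile at the selected fraction
#'
#' The computational mixture at the estimated fraction, floored at a positive
#' pseudocount so downstream observed/expected ratios stay finite. Genes
#' sitting at the floor are low-confidence for ratio purposes; callers can
#' flag them via \code{attr(, "atFloor")}.
#'
#' @param profileA,profileB monoculture profiles.
#' @param alphaHat mixing fraction (typically from [scanAlpha()]).
#' @param floor minimum expected intensity (default 1 intensity unit).
#' @return named numeric vector with logical attribute \code{atFloor}.
#' @export
expectedProfile <- function(profileA, profileB, alphaHat, floor = 1) {
    if (!is.finite(floor) || floor <= 0)
        stop("floor must be a single positive number")
    m <- makeMixture(profileA, profileB, alphaHat)
    at <- m < floor
    m[at] <- floor
    attr(m, "atFloor") <- at
    m
}

#' Per-replicate deconvolution of co-culture profiles
#'
#' Each co-culture replicate gets its own mixing-fraction scan against the two
#' monoculture profiles, its own expected profile at the selected fraction,
#' and its own per-gene observed/expected ratio. Optionally all arrays
#' (monocultures plus co-cultures) are quantile-normalized together first, as
#' a preprocessing hook for raw array summaries; leave off for data already on
#' a shared scale (e.g. simulated or pre-normalized input).
#'
#' @param monoA,monoB single-sample monoculture matrices/profiles.
#' @param coculture probes x replicates matrix of co-culture profiles (zero
#'   columns allowed: returns an empty result).
#' @param grid,scale,pseudocount passed to [scanAlpha()].
#' @param floor expected-intensity floor, passed to [expectedProfile()].
#' @param normalize quantile-normalize all arrays together before scanning
#'   (default \code{FALSE}).
#' @return list with \code{scans} (list of \linkS4class{MixtureScan}),
#'   \code{alphaHats} (numeric), \code{ratios}, \code{expected} (probes x
#'   replicates matrices) and \code{lowConfidence} (logical vector: expected
#'   intensity at the floor in any replicate).
#' @examples
#' cfg <- simConfig(nGenes = 300, alphaTrue = 0.5, noiseLogSd = 0.05, seed = 9)
#' mono <- genMonocultures(cfg)
#' cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
#' dec <- perReplicateDeconvolve(mono$A, mono$B, cc)
#' dec$alphaHats
#' @export
perReplicateDeconvolve <- function(monoA, monoB, coculture,
                                   grid = defaultGrid(),
                                   scale = c("log2", "linear"),
                                   pseudocount = 1, floor = 1,
                                   normalize = FALSE) {
    scale <- match.arg(scale)
    if (!is.matrix(coculture))
        coculture <- as.matrix(coculture)
    A <- asProfile(monoA, "monoA")
    B <- asProfile(monoB, "monoB")
    checkSharedProbes(A, B, "monoA", "monoB")
    nRep <- ncol(coculture)
    if (nRep == 0L) {
        return(list(scans = list(), alphaHats = numeric(0),
                    ratios = coculture, expected = coculture,
                    lowConfidence = logical(length(A))))
    }
    checkExpressionMatrix(coculture, "coculture")
    checkSharedProbes(A, coculture, "monoA", "coculture")
    if (normalize) {
        all <- quantileNormalizeArrays(cbind(monoA = A, monoB = B, coculture))
        A <- all[, 1L]
        B <- all[, 2L]
        coculture <- all[, -(1:2), drop = FALSE]
    }
    if (length(grid) == 0L || any(grid <= 0) || any(grid >= 1) ||
        any(diff(grid) <= 0))
        stop("grid must be strictly increasing within (0, 1)")
    rmat <- scanCurves(A, B, coculture, grid, scale, pseudocount)
    scans <- vector("list", nRep)
    ratios <- expected <- matrix(NA_real_, nrow = length(A), ncol = nRep,
                                 dimnames = dimnames(coculture))
    atFloor <- matrix(FALSE, nrow = length(A), ncol = nRep)
    for (r in seq_len(nRep)) {
        rv <- rmat[, r]
        hit <- which(rv == max(rv))
        if (length(hit) > 1L)
            message("perReplicateDeconvolve: ", length(hit),
                    " grid points tied at the maximum correlation ",
                    "(replicate ", r, "); reporting the smallest fraction")
        scans[[r]] <- new("MixtureScan", alphas = as.numeric(grid),
                          correlations = rv, alphaHat = grid[hit[1L]],
                          corrMax = rv[hit[1L]], scale = scale,
                          nTies = length(hit))
        e <- expectedProfile(A, B, alphaHat(scans[[r]]), floor = floor)
        atFloor[, r] <- attr(e, "atFloor")
        expected[, r] <- e
        ratios[, r] <- coculture[, r] / e
    }
    list(scans = scans,
         alphaHats = vapply(scans, alphaHat, numeric(1)),
         ratios = ratios, expected = expected,
         lowConfidence = rowSums(atFloor) > 0)
}

#' Quantile-normalize a set of arrays together
#'
#' Thin wrapper mapping every column to the mean quantile profile (via
#' \code{limma::normalizeQuantiles}), preserving dimnames. Used as the
#' cross-array normalization hook for raw array summaries.
#'
#' @param x probes x samples intensity matrix.
#' @return matrix of the same shape.
#' @export
quantileNormalizeArrays <- function(x) {
    checkExpressionMatrix(x, "array matrix")
    out <- limma::normalizeQuantiles(x)
    dimnames(out) <- dimnames(x)
    out
}
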