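#' Construct a limiting-dilution plate
#'
#' @param doses cells seeded per well (positive, no duplicates).
#' @param tested wells tested per dose (scalar recycled).
#' @param negative sphere-free wells per dose.
#' @param groupLabel condition label (default \code{""}).
#' @return an \linkS4class{EldaPlate}.
#' @examples
#' eldaPlate(c(81, 27, 9, 3, 1), 12, c(0, 2, 5, 9, 11), "WT")
#' @export
eldaPlate <- function(doses, tested, negative, groupLabel = "") {
    if (length(tested) == 1L) tested <- rep(tested, length(doses))
    new("EldaPlate", doses = as.integer(doses), tested = as.integer(tested),
        negative = as.integer(negative),
        groupLabel = as.character(groupLabel))
}

#' Single-hit Poisson log-likelihood of a plate
#'
#' Under \eqn{P(\mathrm{negative}) = (1-f)^d}, the binomial log-likelihood of
#' the observed negative-well counts:
#' \deqn{\sum_i [\mathrm{neg}_i d_i \log(1-f) +
#'       (\mathrm{tested}_i - \mathrm{neg}_i)\log(1-(1-f)^{d_i})]}
#' (combinatorial constants omitted, as they do not depend on f).
#'
#' @param plate an \linkS4class{EldaPlate}.
#' @param f candidate frequency (vectorized), strictly inside (0, 1).
#' @return log-likelihood value(s); \code{-Inf} where a term vanishes.
#' @export
eldaLogLik <- function(plate, f) {
    stopifnot(is(plate, "EldaPlate"))
    validObject(plate)
    if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
        stop("f must lie strictly inside (0, 1); ",
             "boundary plates are handled by fitFrequency")
    pos <- plate@tested - plate@negative
    lq <- log1p(-f)                     # log(1 - f)
    ll <- numeric(length(f))
    for (i in seq_along(plate@doses)) {
        d <- plate@doses[i]
        ll <- ll + plate@negative[i] * d * lq +
            pos[i] * log(-expm1(d * lq))  # log(1 - (1-f)^d)
    }
    ll
}

#' Maximum-likelihood clonogenic frequency
#'
#' The single-hit model is the binomial complementary log-log model with a
#' log-dose offset: the per-well positive probability is
#' \eqn{1 - e^{-\lambda d}} with \eqn{\lambda = -\log(1-f)}, so
#' \eqn{\mathrm{cloglog}(p) = \log\lambda + \log d}. The log-likelihood is
#' concave in \eqn{\lambda}; the MLE is found by solving the score equation
#' (robust where iteratively-reweighted least squares stalls on plates with
#' saturated doses), and the 95\% Wald interval is formed on the cloglog
#' scale from the expected Fisher information before mapping back to a
#' frequency. Degenerate plates short-circuit: all wells negative gives f = 0
#' with an exact one-sided upper bound; all wells positive gives the boundary
#' estimate f = 1 with an exact one-sided lower bound.
#'
#' @param plate an \linkS4class{EldaPlate}.
#' @param conf confidence level (default 0.95).
#' @return an \linkS4class{EldaFit}.
#' @examples
#' fitFrequency(eldaPlate(c(81, 27, 9, 3, 1), 12, c(0, 1, 4, 9, 11)))
#' @export
fitFrequency <- function(plate, conf = 0.95) {
    stopifnot(is(plate, "EldaPlate"))
    validObject(plate)
    pos <- plate@tested - plate@negative
    cells <- sum(as.numeric(plate@doses) * plate@tested)
    alpha <- 1 - conf
    if (all(pos == 0L)) {
        ## every well sphere-free: MLE at f = 0; exact upper bound from
        ## (1 - f)^cells >= alpha
        up <- 1 - alpha^(1 / cells)
        return(new("EldaFit", freqHat = 0, ciLow = 0, ciHigh = up,
                   loglik = 0, boundaryFlag = "all_negative", plate = plate))
    }
    if (all(plate@negative == 0L)) {
        ## every well positive: likelihood increases toward f = 1; exact lower
        ## bound where P(all positive | f) = alpha
        pAll <- function(f)
            sum(plate@tested * log(-expm1(plate@doses * log1p(-f)))) -
                log(alpha)
        lo <- stats::uniroot(pAll, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
        return(new("EldaFit", freqHat = 1, ciLow = lo, ciHigh = 1,
                   loglik = 0, boundaryFlag = "all_positive", plate = plate))
    }
    d <- as.numeric(plate@doses)
    neg <- as.numeric(plate@negative)
    ## score in lambda: sum_i d_i [ pos_i e^(-lambda d_i)/(1 - e^(-lambda d_i))
    ##                              - neg_i ]; strictly decreasing
    score <- function(lam) {
        pneg <- exp(-lam * d)
        sum(d * (pos * pneg / (1 - pneg) - neg))
    }
    lo <- 1e-12
    hi <- 1
    while (score(hi) > 0 && hi < 1e6) hi <- hi * 4
    lam <- stats::uniroot(score, c(lo, hi), tol = 1e-14)$root
    beta <- log(lam)
    ## expected Fisher information for beta = log(lambda) under the binomial
    ## cloglog model: sum_i n_i (dp_i/dbeta)^2 / (p_i (1 - p_i))
    pneg <- exp(-lam * d)
    ppos <- 1 - pneg
    dpdb <- lam * d * pneg
    info <- sum(plate@tested * dpdb^2 / (ppos * pneg))
    se <- 1 / sqrt(info)
    z <- stats::qnorm(1 - alpha / 2)
    fOf <- function(b) -expm1(-exp(b))   # 1 - exp(-lambda)
    f <- min(max(fOf(beta), 0), 1)
    new("EldaFit", freqHat = f,
        ciLow = max(0, fOf(beta - z * se)),
        ciHigh = min(1, fOf(beta + z * se)),
        loglik = eldaLogLik(plate, min(max(f, 1e-15), 1 - 1e-15)),
        boundaryFlag = "interior", plate = plate)
}

#' Merge limiting-dilution plates of one condition
#'
#' Sums tested and negative wells per dose across plates, yielding a single
#' pooled design.
#'
#' @param plates list of \linkS4class{EldaPlate}.
#' @param groupLabel label for the merged plate; defaults to the first
#'   plate's label.
#' @return an \linkS4class{EldaPlate}.
#' @export
mergePlates <- function(plates, groupLabel = NULL) {
    stopifnot(length(plates) >= 1L,
              all(vapply(plates, is, logical(1), "EldaPlate")))
    doses <- sort(unique(unlist(lapply(plates, function(p) p@doses))))
    tested <- negative <- integer(length(doses))
    for (p in plates) {
        i <- match(p@doses, doses)
        tested[i] <- tested[i] + p@tested
        negative[i] <- negative[i] + p@negative
    }
    if (is.null(groupLabel)) groupLabel <- plates[[1L]]@groupLabel
    eldaPlate(doses, tested, negative, groupLabel)
}

#' Compare clonogenic frequencies between two groups
#'
#' Default: two-sided Welch t-test on the per-biological-replicate frequency
#' estimates (one fit per replicate plate). A pooled-variance Student test is
#' available via \code{varEqual = TRUE}. Degenerate inputs with zero variance
#' in both groups return p = 1 when the means agree and p = 0 otherwise.
#'
#' @param fitsA,fitsB lists of \linkS4class{EldaFit} (or numeric frequency
#'   vectors), at least 2 per group.
#' @param varEqual pool variances (classic Student test) instead of Welch.
#' @return list with \code{p}, \code{meanA}, \code{meanB}, \code{method}.
#' @seealso [compareFrequenciesLRT()] for the pooled likelihood-ratio
#'   alternative.
#' @export
compareReplicateFrequencies <- function(fitsA, fitsB, varEqual = FALSE) {
    getF <- function(x) {
        if (is.numeric(x)) return(x)
        vapply(x, function(f) { stopifnot(is(f, "EldaFit")); f@freqHat },
               numeric(1))
    }
    a <- getF(fitsA)
    b <- getF(fitsB)
    if (length(a) < 2L || length(b) < 2L)
        stop("need at least 2 replicate fits per group")
    method <- if (varEqual) "Student t" else "Welch t"
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
        p <- stats::t.test(a, b, var.equal = varEqual)$p.value
    }
    list(p = p, meanA = mean(a), meanB = mean(b), method = method)
}

#' Likelihood-ratio comparison of two limiting-dilution groups
#'
#' Pools the plates within each group, fits each group's frequency and a
#' common frequency, and refers twice the log-likelihood difference to a
#' chi-squared distribution with one degree of freedom.
#'
#' @param platesA,platesB lists of \linkS4class{EldaPlate}.
#' @return list with \code{p}, \code{statistic}, \code{freqA}, \code{freqB}.
#' @export
compareFrequenciesLRT <- function(platesA, platesB) {
    pa <- mergePlates(platesA)
    pb <- mergePlates(platesB)
    pooled <- mergePlates(list(pa, pb), groupLabel = "pooled")
    fa <- fitFrequency(pa)
    fb <- fitFrequency(pb)
    fp <- fitFrequency(pooled)
    stat <- 2 * (fa@loglik + fb@loglik - fp@loglik)
    list(p = stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE),
         statistic = stat, freqA = fa@freqHat, freqB = fb@freqHat)
}

#' Log fraction of sphere-free wells per dose
#'
#' The quantity plotted against dose in limiting-dilution figures: under the
#' single-hit model its expectation is the line \eqn{d \log(1-f)} through the
#' origin. Doses where every well is positive have an undefined log fraction;
#' they are flagged, not dropped.
#'
#' @param plate an \linkS4class{EldaPlate}.
#' @return data.frame with columns \code{dose}, \code{tested},
#'   \code{negative}, \code{fractionNegative}, \code{logFractionNegative}
#'   (natural log; NA when no well was negative) and \code{undefined}.
#' @export
eldaSummary <- function(plate) {
    stopifnot(is(plate, "EldaPlate"))
    validObject(plate)
    frac <- plate@negative / plate@tested
    lf <- ifelse(plate@negative == 0L, NA_real_, log(frac))
    data.frame(dose = plate@doses, tested = plate@tested,
               negative = plate@negative, fractionNegative = frac,
               logFractionNegative = lf, undefined = plate@negative == 0L)
}
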