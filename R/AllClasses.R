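#' @import methods
NULL

## Expression profiles travel as base numeric matrices (probes x samples,
## unique rownames, finite non-negative values) -- the limma convention.
## S4 classes below hold the structured results and simulation ground truth.

#' Simulation configuration for synthetic co-culture experiments
#'
#' Parameters of the generative model behind [genMonocultures()] and
#' [genCoculture()]: per-gene log2 intensities are drawn as
#' \eqn{2^{N(\mu, \sigma)}} for cell type A, cell type B receives an
#' independent per-gene log2 offset \eqn{N(0, \tau)}, the co-culture is the
#' linear mixture \eqn{\alpha A + (1-\alpha) B} with multiplicative
#' (log2-additive Gaussian) measurement noise per replicate, and a chosen set
#' of interaction genes is multiplied by \eqn{2^{e_g}}.
#'
#' @slot nGenes number of probes.
#' @slot baselineLogMean mean log2 intensity of the baseline profile.
#' @slot baselineLogSd SD of baseline log2 intensities across genes.
#' @slot betweenCelltypeSd SD of the per-gene log2 divergence of cell type B
#'   from cell type A.
#' @slot alphaTrue true fraction of cell type A in the mixture, in (0, 1).
#' @slot nInteraction number of interaction-affected genes.
#' @slot effectLog2 per-interaction-gene log2 effects (positive = induced);
#'   length \code{nInteraction}.
#' @slot noiseLogSd SD of replicate-level multiplicative noise on the log2
#'   scale (0 = noise-free).
#' @slot nReplicates number of co-culture replicates.
#' @slot seed integer seed; identical configurations give identical output.
#' @seealso [simConfig()]
#' @export
setClass("SimConfig", representation(
    nGenes = "integer",
    baselineLogMean = "numeric",
    baselineLogSd = "numeric",
    betweenCelltypeSd = "numeric",
    alphaTrue = "numeric",
    nInteraction = "integer",
    effectLog2 = "numeric",
    noiseLogSd = "numeric",
    nReplicates = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    scalarOk <- function(x) length(x) == 1L && is.finite(x)
    if (!scalarOk(object@nGenes) || object@nGenes < 1L)
        return("nGenes must be a single positive integer")
    if (!scalarOk(object@baselineLogMean))
        return("baselineLogMean must be a single finite number")
    if (!scalarOk(object@baselineLogSd) || object@baselineLogSd <= 0)
        return("baselineLogSd must be a single positive number")
    if (!scalarOk(object@betweenCelltypeSd) || object@betweenCelltypeSd < 0)
        return("betweenCelltypeSd must be a single non-negative number")
    if (!scalarOk(object@alphaTrue) ||
        object@alphaTrue <= 0 || object@alphaTrue >= 1)
        return("alphaTrue must lie strictly between 0 and 1")
    if (!scalarOk(object@nInteraction) || object@nInteraction < 0L)
        return("nInteraction must be a single non-negative integer")
    if (object@nInteraction > object@nGenes)
        return("nInteraction must not exceed nGenes")
    if (length(object@effectLog2) != object@nInteraction)
        return("effectLog2 must have length nInteraction")
    if (length(object@effectLog2) && !all(is.finite(object@effectLog2)))
        return("effectLog2 must be finite")
    if (!scalarOk(object@noiseLogSd) || object@noiseLogSd < 0)
        return("noiseLogSd must be a single non-negative number")
    if (!scalarOk(object@nReplicates) || object@nReplicates < 1L)
        return("nReplicates must be a single positive integer")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed must be a single integer")
    TRUE
})

#' Ground truth of a simulated co-culture experiment
#'
#' Records everything a recovery test needs: the true mixing fraction, which
#' probes carry an interaction effect and how large each effect is (log2), and
#' the full generating configuration.
#'
#' @slot alphaTrue true fraction of cell type A.
#' @slot interactionGenes probe identifiers of interaction-affected genes.
#' @slot perGeneEffect named numeric vector of log2 effects; names are
#'   exactly \code{interactionGenes}.
#' @slot config the [SimConfig-class] that produced the data.
#' @seealso [simTruth()]
#' @export
setClass("SimTruth", representation(
    alphaTrue = "numeric",
    interactionGenes = "character",
    perGeneEffect = "numeric",
    config = "SimConfig"
))

setValidity("SimTruth", function(object) {
    if (length(object@alphaTrue) != 1L ||
        object@alphaTrue <= 0 || object@alphaTrue >= 1)
        return("alphaTrue must lie strictly between 0 and 1")
    if (anyDuplicated(object@interactionGenes))
        return("interactionGenes must be unique")
    if (!identical(sort(as.character(names(object@perGeneEffect))),
                   sort(object@interactionGenes)))
        return("perGeneEffect names must equal interactionGenes")
    TRUE
})

#' Result of a mixing-fraction correlation scan
#'
#' For each candidate fraction \eqn{\alpha} on the grid, the Pearson
#' correlation between the observed mixed profile and the computational
#' mixture \eqn{\alpha A + (1-\alpha) B}; \code{alphaHat} is the grid value
#' attaining the maximum (smallest such value on ties).
#'
#' @slot alphas strictly increasing grid of candidate fractions in (0, 1).
#' @slot correlations Pearson correlations, one per grid point.
#' @slot alphaHat selected fraction.
#' @slot corrMax correlation at \code{alphaHat}.
#' @slot scale \code{"log2"} or \code{"linear"} -- the scale the correlation
#'   was computed on.
#' @slot nTies number of grid points attaining the maximum.
#' @seealso [scanAlpha()]
#' @export
setClass("MixtureScan", representation(
    alphas = "numeric",
    correlations = "numeric",
    alphaHat = "numeric",
    corrMax = "numeric",
    scale = "character",
    nTies = "integer"
))

setValidity("MixtureScan", function(object) {
    if (length(object@alphas) != length(object@correlations))
        return("alphas and correlations must have equal length")
    if (length(object@alphas) == 0L)
        return("empty grid")
    if (any(diff(object@alphas) <= 0))
        return("alphas must be strictly increasing")
    if (any(object@alphas <= 0 | object@alphas >= 1))
        return("alphas must lie strictly between 0 and 1")
    if (!isTRUE(all.equal(object@corrMax, max(object@correlations))))
        return("corrMax must equal max(correlations)")
    if (!object@alphaHat %in% object@alphas)
        return("alphaHat must be a grid value")
    if (!object@scale %in% c("log2", "linear"))
        return("scale must be 'log2' or 'linear'")
    TRUE
})

#' Limiting-dilution plate design and counts
#'
#' One extreme limiting dilution assay: for each seeding dose (cells per
#' well), the number of wells tested and the number without a sphere.
#'
#' @slot doses cells seeded per well; positive, no duplicates.
#' @slot tested wells tested per dose.
#' @slot negative wells without a sphere per dose.
#' @slot groupLabel free-text group / condition label.
#' @seealso [eldaPlate()], [fitFrequency()]
#' @export
setClass("EldaPlate", representation(
    doses = "integer",
    tested = "integer",
    negative = "integer",
    groupLabel = "character"
))

setValidity("EldaPlate", function(object) {
    n <- length(object@doses)
    if (n == 0L) return("plate must have at least one dose")
    if (length(object@tested) != n || length(object@negative) != n)
        return("doses, tested and negative must have equal length")
    if (any(object@doses <= 0L)) return("doses must be strictly positive")
    if (anyDuplicated(object@doses)) return("doses must not contain duplicates")
    if (any(object@tested <= 0L)) return("tested must be strictly positive")
    if (any(object@negative < 0L) || any(object@negative > object@tested))
        return("negative must lie in [0, tested] for every dose")
    if (length(object@groupLabel) != 1L)
        return("groupLabel must be a single string")
    TRUE
})

#' Single-hit Poisson fit of clonogenic frequency
#'
#' Maximum-likelihood estimate of the active (sphere-forming) cell frequency
#' under \eqn{P(\mathrm{negative\ at\ dose\ } d) = (1-f)^d}, with a Wald 95\%
#' interval formed on the complementary log-log scale and mapped back to
#' [0, 1]. Degenerate plates are flagged: all wells negative
#' (\code{"all_negative"}) or all wells positive (\code{"all_positive"}).
#'
#' @slot freqHat estimated frequency in [0, 1].
#' @slot ciLow,ciHigh confidence bounds.
#' @slot loglik log-likelihood at the estimate.
#' @slot boundaryFlag \code{"interior"}, \code{"all_negative"} or
#'   \code{"all_positive"}.
#' @slot plate the fitted [EldaPlate-class].
#' @seealso [fitFrequency()]
#' @export
setClass("EldaFit", representation(
    freqHat = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    loglik = "numeric",
    boundaryFlag = "character",
    plate = "EldaPlate"
))

setValidity("EldaFit", function(object) {
    if (!object@boundaryFlag %in% c("interior", "all_negative", "all_positive"))
        return("boundaryFlag must be interior, all_negative or all_positive")
    if (object@freqHat < 0 || object@freqHat > 1)
        return("freqHat must lie in [0, 1]")
    if (object@ciLow > object@freqHat || object@ciHigh < object@freqHat)
        return("confidence interval must contain freqHat")
    if (object@boundaryFlag == "interior" && !is.finite(object@loglik))
        return("loglik must be finite for interior fits")
    TRUE
})

#' Long-format qPCR Ct table
#'
#' Rows of (sample, gene, ct) with a designated reference gene and the
#' arbitrary-unit scale used by [ddctExpression()]: a target measured at the
#' reference Ct maps to \code{scaleUnits} units. Technical replicates may be
#' supplied; the constructor averages duplicate (sample, gene) Ct values.
#'
#' @slot data data.frame with columns \code{sample}, \code{gene}, \code{ct};
#'   one row per (sample, gene).
#' @slot refGene reference (housekeeping) gene, present in every sample.
#' @slot scaleUnits expression units assigned to the reference level
#'   (default 10000).
#' @seealso [ctTable()], [ddctExpression()]
#' @export
setClass("CtTable", representation(
    data = "data.frame",
    refGene = "character",
    scaleUnits = "numeric"
))

setValidity("CtTable", function(object) {
    d <- object@data
    if (!all(c("sample", "gene", "ct") %in% names(d)))
        return("data must have columns sample, gene, ct")
    if (!is.numeric(d$ct) || !all(is.finite(d$ct)))
        return("ct must be finite numeric")
    if (anyDuplicated(d[, c("sample", "gene")]))
        return("duplicate (sample, gene) pair in Ct data")
    if (length(object@refGene) != 1L)
        return("refGene must be a single gene identifier")
    bySample <- split(d$gene, d$sample)
    if (!all(vapply(bySample, function(g) object@refGene %in% g, logical(1))))
        return(sprintf("reference gene '%s' missing from at least one sample",
                       object@refGene))
    if (length(object@scaleUnits) != 1L || object@scaleUnits <= 0)
        return("scaleUnits must be a single positive number")
    TRUE
})
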