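#' Signed fold change of an observed/expected ratio
#'
#' A ratio r is reported as r when r >= 1 and as -(1/r) when r < 1, so up- and
#' down-regulation have symmetric magnitudes and no value falls inside
#' (-1, 1).
#'
#' @param ratio positive ratio(s) of co-culture to expected expression.
#' @return signed fold change(s), same length as \code{ratio}.
#' @examples
#' signedFoldChange(c(2.2, 0.5, 1))
#' @export
signedFoldChange <- function(ratio) {
    if (any(!is.finite(ratio)) || any(ratio <= 0))
        stop("ratio must be strictly positive and finite")
    ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Per-gene one-sample t-test of replicate log2 ratios
#'
#' Tests, for every gene, whether the mean log2 observed/expected ratio across
#' replicate deconvolutions differs from 0 (two-sided, df = n - 1). Genes with
#' (near-)identical ratios across replicates have their variance floored at
#' \code{varFloor} so that a zero sample variance yields a tiny-but-nonzero
#' p-value instead of p = 0, keeping the subsequent step-up adjustment
#' well-behaved.
#'
#' @param log2Ratios genes x replicates matrix of log2 ratios (>= 2 columns).
#' @param varFloor variance floor on the log2 scale (default 1e-8).
#' @param method \code{"t"} (default): plain per-gene one-sample t.
#'   \code{"moderated"}: empirical-Bayes variance moderation across genes
#'   (limma), which borrows strength when replicates are few; recommended for
#'   n = 3 designs where per-gene variance estimates are noisy.
#' @return named vector of raw two-sided p-values.
#' @examples
#' replicateTest(rbind(g1 = c(1, 1.1, 0.9), g2 = c(0, 0, 0)))
#' @export
replicateTest <- function(log2Ratios, varFloor = 1e-8,
                          method = c("t", "moderated")) {
    method <- match.arg(method)
    if (!is.matrix(log2Ratios))
        log2Ratios <- as.matrix(log2Ratios)
    n <- ncol(log2Ratios)
    if (n < 2L)
        stop("replicateTest needs at least 2 replicates per gene; ",
             "with a single replicate use callInteractionGenes(test = FALSE)")
    if (!all(is.finite(log2Ratios)))
        stop("log2Ratios must be finite")
    if (method == "moderated") {
        fit <- limma::eBayes(limma::lmFit(log2Ratios,
                                          design = matrix(1, n, 1)))
        p <- fit$p.value[, 1L]
        names(p) <- rownames(log2Ratios)
        return(p)
    }
    m <- rowMeans(log2Ratios)
    v <- (rowSums(log2Ratios^2) - n * m^2) / (n - 1)
    v <- pmax(v, varFloor)
    tstat <- m / sqrt(v / n)
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    names(p) <- rownames(log2Ratios)
    p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with monotonicity enforcement),
#' input order preserved.
#'
#' @param pRaw raw p-values in [0, 1].
#' @return adjusted p-values, same order and names.
#' @export
bhAdjust <- function(pRaw) {
    if (any(!is.finite(pRaw)) || any(pRaw < 0) || any(pRaw > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pRaw, method = "BH")
}

#' Call interaction genes from per-replicate ratios
#'
#' Turns a genes x replicates matrix of observed/expected ratios into the
#' interaction-gene table: geometric-mean ratio, signed fold change, raw
#' one-sample t p-value on the log2 ratios, BH-adjusted p-value, and the
#' conjunctive call (adjusted p strictly below \code{qThreshold} AND absolute
#' fold change at least \code{fcThreshold}).
#'
#' @param ratios genes x replicates matrix of positive linear ratios.
#' @param qThreshold adjusted-p cutoff (default 0.05, strict).
#' @param fcThreshold minimum absolute signed fold change (default 2,
#'   inclusive).
#' @param varFloor,method passed to [replicateTest()].
#' @param lowConfidence optional logical vector flagging genes whose expected
#'   intensity sat at the floor (from [perReplicateDeconvolve()]); flagged
#'   genes are retained and marked, never filtered here.
#' @param test set \code{FALSE} for single-replicate data: p-values are NA and
#'   calls use the fold-change rule only.
#' @return data.frame with columns \code{probe}, \code{meanLog2Ratio},
#'   \code{foldChange}, \code{pRaw}, \code{pBH}, \code{called},
#'   \code{lowConfidence}, in input gene order.
#' @examples
#' ratios <- rbind(up = c(4.1, 3.8, 4.3), null = c(1.02, 0.97, 1.01))
#' callInteractionGenes(ratios)
#' @export
callInteractionGenes <- function(ratios, qThreshold = 0.05, fcThreshold = 2,
                                 varFloor = 1e-8, lowConfidence = NULL,
                                 test = TRUE, method = c("t", "moderated")) {
    if (!is.matrix(ratios))
        ratios <- as.matrix(ratios)
    if (nrow(ratios) == 0L) {
        return(data.frame(probe = character(0), meanLog2Ratio = numeric(0),
                          foldChange = numeric(0), pRaw = numeric(0),
                          pBH = numeric(0), called = logical(0),
                          lowConfidence = logical(0)))
    }
    if (any(!is.finite(ratios)) || any(ratios <= 0))
        stop("ratios must be strictly positive and finite")
    if (qThreshold <= 0 || fcThreshold < 1)
        stop("qThreshold must be positive and fcThreshold at least 1")
    probes <- rownames(ratios)
    if (is.null(probes)) probes <- probeIds(nrow(ratios))
    lg <- log2(ratios)
    meanLog2 <- rowMeans(lg)
    fc <- signedFoldChange(2^meanLog2)
    if (test) {
        pRaw <- unname(replicateTest(lg, varFloor = varFloor,
                                     method = method))
        pBH <- bhAdjust(pRaw)
        called <- pBH < qThreshold & abs(fc) >= fcThreshold
    } else {
        pRaw <- pBH <- rep(NA_real_, nrow(ratios))
        called <- abs(fc) >= fcThreshold
    }
    if (is.null(lowConfidence)) lowConfidence <- rep(FALSE, nrow(ratios))
    data.frame(probe = probes, meanLog2Ratio = meanLog2, foldChange = fc,
               pRaw = pRaw, pBH = pBH, called = called,
               lowConfidence = lowConfidence, row.names = NULL)
}

#' Full co-culture deconvolution and interaction-gene calling
#'
#' Convenience pipeline: per-replicate mixing-fraction scans and
#' observed/expected ratios via [perReplicateDeconvolve()], then the
#' interaction-gene table via [callInteractionGenes()].
#'
#' @inheritParams perReplicateDeconvolve
#' @inheritParams callInteractionGenes
#' @return list with \code{deconvolution} (see [perReplicateDeconvolve()])
#'   and \code{table} (see [callInteractionGenes()]).
#' @examples
#' cfg <- simConfig(nGenes = 400, nInteraction = 10, effectLog2 = 2,
#'                  noiseLogSd = 0.1, seed = 21)
#' mono <- genMonocultures(cfg)
#' cc <- genCoculture(mono$A, mono$B, simTruth(cfg))
#' res <- deconvolveCoculture(mono$A, mono$B, cc)
#' sum(res$table$called)
#' @export
deconvolveCoculture <- function(monoA, monoB, coculture,
                                grid = defaultGrid(),
                                scale = c("log2", "linear"),
                                pseudocount = 1, floor = 1,
                                normalize = FALSE,
                                qThreshold = 0.05, fcThreshold = 2,
                                varFloor = 1e-8,
                                method = c("t", "moderated")) {
    dec <- perReplicateDeconvolve(monoA, monoB, coculture, grid = grid,
                                  scale = scale, pseudocount = pseudocount,
                                  floor = floor, normalize = normalize)
    nRep <- ncol(dec$ratios)
    tab <- callInteractionGenes(dec$ratios, qThreshold = qThreshold,
                                fcThreshold = fcThreshold,
                                varFloor = varFloor,
                                lowConfidence = dec$lowConfidence,
                                test = nRep >= 2L, method = method)
    list(deconvolution = dec, table = tab)
}
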