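#' Construct a Ct table
#'
#' Wraps a long-format data.frame of qPCR Ct measurements. Duplicate
#' (sample, gene) rows are treated as technical replicates and averaged when
#' \code{collapse = TRUE} (default); with \code{collapse = FALSE} duplicates
#' are an error.
#'
#' @param data data.frame with columns \code{sample}, \code{gene}, \code{ct}.
#' @param refGene reference gene, present in every sample.
#' @param scaleUnits arbitrary units assigned to the reference expression
#'   level (default 10000).
#' @param collapse average technical-replicate Ct values per (sample, gene).
#' @return a \linkS4class{CtTable}.
#' @export
ctTable <- function(data, refGene = "GAPDH", scaleUnits = 10000,
                    collapse = TRUE) {
    data <- as.data.frame(data)
    if (!all(c("sample", "gene", "ct") %in% names(data)))
        stop("data must have columns sample, gene, ct")
    data$sample <- as.character(data$sample)
    data$gene <- as.character(data$gene)
    if (collapse && anyDuplicated(data[, c("sample", "gene")])) {
        agg <- stats::aggregate(ct ~ sample + gene, data = data, FUN = mean)
        data <- agg[order(agg$sample, agg$gene), c("sample", "gene", "ct")]
        rownames(data) <- NULL
    }
    new("CtTable", data = data, refGene = as.character(refGene),
        scaleUnits = as.numeric(scaleUnits))
}

ctLookup <- function(ct, gene, sample) {
    hit <- ct@data$sample == sample & ct@data$gene == gene
    if (!any(hit)) return(NA_real_)
    ct@data$ct[hit][1L]
}

#' Delta-delta-Ct relative expression in arbitrary units
#'
#' Standard \eqn{\Delta\Delta}Ct quantification with amplification efficiency
#' 2, scaled so that the reference gene sits at \code{scaleUnits} (default
#' 10000) arbitrary units: \deqn{\mathrm{expr} = \mathrm{scaleUnits} \cdot
#' 2^{-(Ct_{gene} - Ct_{ref})}.} A target measured at the reference Ct
#' therefore reports exactly \code{scaleUnits}.
#'
#' @param ct a \linkS4class{CtTable}.
#' @param gene target gene.
#' @param sample sample identifier.
#' @return expression in arbitrary units (positive scalar).
#' @examples
#' tab <- ctTable(data.frame(sample = "s1", gene = c("THBS1", "GAPDH"),
#'                           ct = c(19, 20)))
#' ddctExpression(tab, "THBS1", "s1")
#' @export
ddctExpression <- function(ct, gene, sample) {
    stopifnot(is(ct, "CtTable"))
    ctRef <- ctLookup(ct, ct@refGene, sample)
    if (is.na(ctRef))
        stop("reference gene '", ct@refGene, "' not measured in sample '",
             sample, "'")
    ctGene <- ctLookup(ct, gene, sample)
    if (is.na(ctGene))
        stop("gene '", gene, "' not measured in sample '", sample, "'")
    ct@scaleUnits * 2^(-(ctGene - ctRef))
}

#' Delta-delta-Ct expression for every target gene and sample
#'
#' @param ct a \linkS4class{CtTable}.
#' @return data.frame with columns \code{sample}, \code{gene},
#'   \code{expression} (arbitrary units), excluding the reference gene.
#' @export
ddctTable <- function(ct) {
    stopifnot(is(ct, "CtTable"))
    d <- ct@data[ct@data$gene != ct@refGene, , drop = FALSE]
    expr <- mapply(function(g, s) ddctExpression(ct, g, s), d$gene, d$sample)
    data.frame(sample = d$sample, gene = d$gene,
               expression = unname(expr), row.names = NULL)
}

#' Per-sample subtype centroid scores
#'
#' A subtype's centroid profile is the per-sample average of its signature
#' genes; one score vector (over samples) per subtype.
#'
#' @param expr genes x samples expression matrix.
#' @param signatures named list: subtype label -> character vector of
#'   signature genes (all present in \code{expr}).
#' @return samples x subtypes numeric matrix.
#' @export
centroidScores <- function(expr, signatures) {
    checkExpressionMatrix(expr, "expr")
    stopifnot(is.list(signatures), !is.null(names(signatures)),
              !anyDuplicated(names(signatures)))
    out <- vapply(signatures, function(genes) {
        missing <- setdiff(genes, rownames(expr))
        if (length(missing))
            stop("signature genes absent from expr: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        colMeans(expr[genes, , drop = FALSE])
    }, numeric(ncol(expr)))
    rownames(out) <- colnames(expr)
    out
}

#' Correlation of a gene with each subtype centroid profile
#'
#' Pearson correlation, across samples, between one gene's expression and
#' each subtype's centroid score. A zero-variance side yields NA (flagged
#' undefined), not an error.
#'
#' @param geneValues named numeric vector: the gene's expression per sample.
#' @param scores samples x subtypes matrix from [centroidScores()] (sample
#'   order must match).
#' @return named vector of Pearson r, one per subtype (NA where undefined).
#' @export
centroidCorrelations <- function(geneValues, scores) {
    if (!is.matrix(scores) || is.null(colnames(scores)))
        stop("scores must be a samples x subtypes matrix with subtype names")
    if (length(geneValues) != nrow(scores))
        stop("geneValues length must equal the number of samples in scores")
    if (!is.null(names(geneValues)) && !is.null(rownames(scores)) &&
        !identical(names(geneValues), rownames(scores)))
        stop("sample order of geneValues and scores must match")
    apply(scores, 2L, function(s) {
        if (stats::sd(geneValues) == 0 || stats::sd(s) == 0)
            return(NA_real_)
        stats::cor(geneValues, s)
    })
}

#' Pairwise two-sample t-tests across subtypes with Bonferroni correction
#'
#' All unordered pairs of groups are tested two-sided; raw p-values are
#' multiplied by the number of pairs (capped at 1). Groups with fewer than 2
#' observations are excluded with a warning.
#'
#' @param values numeric observations (e.g. one gene's expression).
#' @param labels group (subtype) label per observation.
#' @param varEqual pool variances (classic Student test); default is Welch.
#' @return data.frame with columns \code{groupA}, \code{groupB}, \code{pRaw},
#'   \code{pBonferroni}; for k usable groups, choose(k, 2) rows.
#' @export
pairwiseSubtypeTests <- function(values, labels, varEqual = FALSE) {
    stopifnot(length(values) == length(labels))
    labels <- as.character(labels)
    groups <- split(values, labels)
    small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
    if (length(small)) {
        warning("excluding group(s) with fewer than 2 samples: ",
                paste(small, collapse = ", "))
        groups <- groups[setdiff(names(groups), small)]
    }
    if (length(groups) < 2L)
        stop("need at least 2 groups with >= 2 samples")
    pairs <- utils::combn(names(groups), 2L)
    nPairs <- ncol(pairs)
    pRaw <- vapply(seq_len(nPairs), function(i) {
        a <- groups[[pairs[1L, i]]]
        b <- groups[[pairs[2L, i]]]
        if (stats::sd(a) == 0 && stats::sd(b) == 0)
            return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
        stats::t.test(a, b, var.equal = varEqual)$p.value
    }, numeric(1))
    data.frame(groupA = pairs[1L, ], groupB = pairs[2L, ], pRaw = pRaw,
               pBonferroni = pmin(1, pRaw * nPairs), row.names = NULL)
}
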