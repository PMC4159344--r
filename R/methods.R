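#' @describeIn accessors selected mixing fraction of a scan.
#' @export
setMethod("alphaHat", "MixtureScan", function(object) object@alphaHat)

#' @describeIn accessors correlation at the selected fraction.
#' @export
setMethod("corrMax", "MixtureScan", function(object) object@corrMax)

#' @describeIn accessors the alpha grid of a scan.
#' @export
setMethod("scanGrid", "MixtureScan", function(object) object@alphas)

#' @describeIn accessors per-grid-point Pearson correlations.
#' @export
setMethod("scanCorrelations", "MixtureScan",
          function(object) object@correlations)

#' @describeIn accessors estimated clonogenic frequency.
#' @export
setMethod("freqHat", "EldaFit", function(object) object@freqHat)

#' @describeIn accessors 95\% confidence interval, c(low, high).
#' @export
setMethod("confInt", "EldaFit",
          function(object) c(low = object@ciLow, high = object@ciHigh))

#' @describeIn accessors boundary flag of an ELDA fit.
#' @export
setMethod("boundaryFlag", "EldaFit", function(object) object@boundaryFlag)

#' @describeIn accessors group label of a plate.
#' @export
setMethod("groupLabel", "EldaPlate", function(object) object@groupLabel)

#' @describeIn accessors true mixing fraction of a simulation.
#' @export
setMethod("alphaTrue", "SimTruth", function(object) object@alphaTrue)

#' @describeIn accessors true mixing fraction in a configuration.
#' @export
setMethod("alphaTrue", "SimConfig", function(object) object@alphaTrue)

#' @describeIn accessors probes carrying an interaction effect.
#' @export
setMethod("interactionGenes", "SimTruth",
          function(object) object@interactionGenes)

#' @describeIn accessors named log2 effects of the interaction genes.
#' @export
setMethod("perGeneEffect", "SimTruth", function(object) object@perGeneEffect)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes,",
        object@nReplicates, "replicate(s)\n")
    cat("  alphaTrue =", object@alphaTrue,
        "| interaction genes:", object@nInteraction,
        "| noiseLogSd =", object@noiseLogSd, "\n")
    cat("  baseline log2 ~ N(", object@baselineLogMean, ", ",
        object@baselineLogSd, "), cell-type divergence sd = ",
        object@betweenCelltypeSd, ", seed = ", object@seed, "\n", sep = "")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth: alphaTrue =", object@alphaTrue, "with",
        length(object@interactionGenes), "interaction gene(s)\n")
    if (length(object@interactionGenes)) {
        k <- utils::head(object@interactionGenes, 5L)
        cat("  e.g.", paste(sprintf("%s (%+.2f)", k, object@perGeneEffect[k]),
                            collapse = ", "), "\n")
    }
})

setMethod("show", "MixtureScan", function(object) {
    cat("MixtureScan over", length(object@alphas), "fractions (scale:",
        object@scale, ")\n")
    cat(sprintf("  alphaHat = %.4g (Pearson r = %.6f)\n",
                object@alphaHat, object@corrMax))
    if (object@nTies > 1L)
        cat("  note:", object@nTies,
            "grid points tied at the maximum; smallest reported\n")
})

setMethod("show", "EldaPlate", function(object) {
    cat("EldaPlate [", object@groupLabel, "]\n", sep = "")
    print(data.frame(dose = object@doses, tested = object@tested,
                     negative = object@negative))
})

setMethod("show", "EldaFit", function(object) {
    cat("EldaFit [", object@plate@groupLabel, "]: ", sep = "")
    if (object@freqHat > 0) {
        cat(sprintf("1 clonogenic cell in %d (f = %.4g)\n",
                    round(1 / object@freqHat), object@freqHat))
    } else {
        cat("no clonogenic cells detected (f = 0)\n")
    }
    cat(sprintf("  95%% CI: [%.4g, %.4g]", object@ciLow, object@ciHigh))
    if (object@boundaryFlag != "interior")
        cat("  <", object@boundaryFlag, ">")
    cat("\n")
})

setMethod("show", "CtTable", function(object) {
    cat("CtTable:", nrow(object@data), "measurements,",
        length(unique(object@data$sample)), "sample(s),",
        length(unique(object@data$gene)), "gene(s)\n")
    cat("  reference gene:", object@refGene,
        "-> scale", object@scaleUnits, "units\n")
})
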