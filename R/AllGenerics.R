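#' Accessors for scan, fit and simulation objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a \linkS4class{MixtureScan}, \linkS4class{EldaFit},
#'   \linkS4class{EldaPlate}, \linkS4class{SimTruth} or
#'   \linkS4class{SimConfig}, as documented per method.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphaHat", function(object) standardGeneric("alphaHat"))

#' @rdname accessors
#' @export
setGeneric("corrMax", function(object) standardGeneric("corrMax"))

#' @rdname accessors
#' @export
setGeneric("scanGrid", function(object) standardGeneric("scanGrid"))

#' @rdname accessors
#' @export
setGeneric("scanCorrelations",
           function(object) standardGeneric("scanCorrelations"))

#' @rdname accessors
#' @export
setGeneric("freqHat", function(object) standardGeneric("freqHat"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("boundaryFlag", function(object) standardGeneric("boundaryFlag"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("alphaTrue", function(object) standardGeneric("alphaTrue"))

#' @rdname accessors
#' @export
setGeneric("interactionGenes",
           function(object) standardGeneric("interactionGenes"))

#' @rdname accessors
#' @export
setGeneric("perGeneEffect", function(object) standardGeneric("perGeneEffect"))
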