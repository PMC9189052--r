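#' Accessors for hostcomp S4 objects
#'
#' Slot accessors for [SyntheticBundle-class],
#' [EnrichmentResult-class] and [RegressionPosterior-class] objects.
#' Always use these in preference to direct slot access.
#'
#' @param x a hostcomp S4 object.
#' @return the slot contents (see the individual class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("choCounts", function(x) standardGeneric("choCounts"))
#' @rdname accessors
#' @export
setMethod("choCounts", "SyntheticBundle", function(x) x@countsCHO)

#' @rdname accessors
#' @export
setGeneric("hekCounts", function(x) standardGeneric("hekCounts"))
#' @rdname accessors
#' @export
setMethod("hekCounts", "SyntheticBundle", function(x) x@countsHEK)

#' @rdname accessors
#' @export
setGeneric("orthologMap", function(x) standardGeneric("orthologMap"))
#' @rdname accessors
#' @export
setMethod("orthologMap", "SyntheticBundle", function(x) x@orthologMap)

#' @rdname accessors
#' @export
setGeneric("functionalAnnotation",
    function(x) standardGeneric("functionalAnnotation"))
#' @rdname accessors
#' @export
setMethod("functionalAnnotation", "SyntheticBundle", function(x) x@annotation)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "SyntheticBundle", function(x) x@geneSets)

#' @rdname accessors
#' @export
setGeneric("titerTable", function(x) standardGeneric("titerTable"))
#' @rdname accessors
#' @export
setMethod("titerTable", "SyntheticBundle", function(x) x@titers)

#' @rdname accessors
#' @export
setGeneric("ptmTable", function(x) standardGeneric("ptmTable"))
#' @rdname accessors
#' @export
setMethod("ptmTable", "SyntheticBundle", function(x) x@ptm)

#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setMethod("simTruth", "SyntheticBundle", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("simulationConfig", function(x) standardGeneric("simulationConfig"))
#' @rdname accessors
#' @export
setMethod("simulationConfig", "SyntheticBundle", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("enrichScore", function(x) standardGeneric("enrichScore"))
#' @rdname accessors
#' @export
setMethod("enrichScore", "EnrichmentResult", function(x) x@ES)

#' @rdname accessors
#' @export
setGeneric("normalizedScore", function(x) standardGeneric("normalizedScore"))
#' @rdname accessors
#' @export
setMethod("normalizedScore", "EnrichmentResult", function(x) x@NES)

#' @rdname accessors
#' @export
setGeneric("permPvalue", function(x) standardGeneric("permPvalue"))
#' @rdname accessors
#' @export
setMethod("permPvalue", "EnrichmentResult", function(x) x@pPerm)

#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
#' @rdname accessors
#' @export
setMethod("posteriorDraws", "RegressionPosterior", function(x) x@draws)

#' @rdname accessors
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))
#' @rdname accessors
#' @export
setMethod("acceptanceRate", "RegressionPosterior", function(x) x@acceptanceRate)

#' @rdname accessors
#' @export
setGeneric("splitRhat", function(x) standardGeneric("splitRhat"))
#' @rdname accessors
#' @export
setMethod("splitRhat", "RegressionPosterior", function(x) x@rhat)
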