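#' @rdname galactosylationIndex
#' @export
setGeneric("galactosylationIndex", function(dist, ...)
  standardGeneric("galactosylationIndex"))

#' @rdname sialylationIndex
#' @export
setGeneric("sialylationIndex", function(dist, ...)
  standardGeneric("sialylationIndex"))

#' @rdname fucosylationIndex
#' @export
setGeneric("fucosylationIndex", function(dist, ...)
  standardGeneric("fucosylationIndex"))

#' @rdname summativeIndices
#' @export
setGeneric("summativeIndices", function(dist, ...)
  standardGeneric("summativeIndices"))

#' @rdname computeIndexSet
#' @export
setGeneric("computeIndexSet", function(dist, ...)
  standardGeneric("computeIndexSet"))

#' @rdname enumerateDistribution
#' @export
setGeneric("enumerateDistribution", function(params, ...)
  standardGeneric("enumerateDistribution"))

#' @rdname sampleDistribution
#' @export
setGeneric("sampleDistribution", function(params, ...)
  standardGeneric("sampleDistribution"))

#' @rdname abundances
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname indexValues
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))

#' @rdname indexValues
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname pairConditions
#' @export
setGeneric("pairConditions", function(x, ...) standardGeneric("pairConditions"))
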