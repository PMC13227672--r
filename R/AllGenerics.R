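#' Accessor generics
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an omicBLUP object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x, ...) standardGeneric("animalIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("layerName", function(x, ...) standardGeneric("layerName"))

#' @rdname accessors
#' @export
setGeneric("ridgeApplied", function(x, ...) standardGeneric("ridgeApplied"))

#' @rdname accessors
#' @export
setGeneric("sigma2", function(x, ...) standardGeneric("sigma2"))

#' @rdname accessors
#' @export
setGeneric("blupEffects", function(x, ...) standardGeneric("blupEffects"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("modelLabel", function(x, ...) standardGeneric("modelLabel"))

#' @rdname accessors
#' @export
setGeneric("weightedAccuracy", function(x, ...)
    standardGeneric("weightedAccuracy"))

#' @rdname accessors
#' @export
setGeneric("pooledAUCValue", function(x, ...) standardGeneric("pooledAUCValue"))

#' @rdname accessors
#' @export
setGeneric("perFold", function(x, ...) standardGeneric("perFold"))
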