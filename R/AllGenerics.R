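#' @include AllClasses.R
NULL

#' Accessors for SpecSR objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("truth", function(object) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("support", function(object) standardGeneric("support"))
#' @rdname accessors
#' @export
setGeneric("lowres", function(object) standardGeneric("lowres"))
#' @rdname accessors
#' @export
setGeneric("sliceAxis", function(object) standardGeneric("sliceAxis"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(object) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("f0prime", function(object) standardGeneric("f0prime"))
#' @rdname accessors
#' @export
setGeneric("omegaMask", function(object) standardGeneric("omegaMask"))
#' @rdname accessors
#' @export
setGeneric("profileSpectrum", function(object) standardGeneric("profileSpectrum"))
#' @rdname accessors
#' @export
setGeneric("volume", function(object) standardGeneric("volume"))
#' @rdname accessors
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))
#' @rdname accessors
#' @export
setGeneric("costHistory", function(object) standardGeneric("costHistory"))
#' @rdname accessors
#' @export
setGeneric("residualHistory", function(object) standardGeneric("residualHistory"))
#' @rdname accessors
#' @export
setGeneric("isSymmetric3", function(object) standardGeneric("isSymmetric3"))

#' @rdname accessors
#' @export
setMethod("truth", "Phantom", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("support", "Phantom", function(object) object@support)
#' @rdname accessors
#' @export
setMethod("lowres", "Observation", function(object) object@lowres)
#' @rdname accessors
#' @export
setMethod("sliceAxis", "Observation", function(object) object@axis)
#' @rdname accessors
#' @export
setMethod("scaleFactor", "Observation", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("f0prime", "AssembledSpectrum", function(object) object@f0prime)
#' @rdname accessors
#' @export
setMethod("omegaMask", "AssembledSpectrum", function(object) object@omega)
#' @rdname accessors
#' @export
setMethod("profileSpectrum", "AssembledSpectrum", function(object) object@profileSpectrum)
#' @rdname accessors
#' @export
setMethod("volume", "PocsResult", function(object) object@volume)
#' @rdname accessors
#' @export
setMethod("volume", "SolverResult", function(object) object@volume)
#' @rdname accessors
#' @export
setMethod("iterations", "PocsResult", function(object) object@iterations)
#' @rdname accessors
#' @export
setMethod("iterations", "SolverResult", function(object) object@iterations)
#' @rdname accessors
#' @export
setMethod("costHistory", "SolverResult", function(object) object@costHistory)
#' @rdname accessors
#' @export
setMethod("residualHistory", "PocsResult", function(object) object@residualHistory)
#' @rdname accessors
#' @export
setMethod("residualHistory", "SolverResult", function(object) object@residualHistory)
#' @rdname accessors
#' @export
setMethod("isSymmetric3", "SpectrumVolume", function(object) object@symmetric)
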