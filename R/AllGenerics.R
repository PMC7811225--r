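#' Accessors for fitted models and results
#'
#' \code{purity}, \code{ploidy}, \code{periodDelta}, \code{noiseSd},
#' \code{mixtureWeights} and \code{modelBIC} extract the corresponding
#' parameter from a \code{\link{CopyNumberFit}} (or from the fit inside a
#' \code{\link{CopyNumberResult}}); \code{segmentCalls} and \code{modelFit}
#' extract the call track and the selected fit from a result.
#'
#' @param object a \code{CopyNumberFit} or \code{CopyNumberResult}.
#' @return a numeric scalar (or vector for \code{mixtureWeights}); for
#'   \code{segmentCalls} a \code{GRanges}; for \code{modelFit} a
#'   \code{CopyNumberFit}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))
#' @rdname accessors
#' @export
setGeneric("ploidy", function(object) standardGeneric("ploidy"))
#' @rdname accessors
#' @export
setGeneric("periodDelta", function(object) standardGeneric("periodDelta"))
#' @rdname accessors
#' @export
setGeneric("noiseSd", function(object) standardGeneric("noiseSd"))
#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @rdname accessors
#' @export
setGeneric("modelBIC", function(object) standardGeneric("modelBIC"))
#' @rdname accessors
#' @export
setGeneric("segmentCalls", function(object) standardGeneric("segmentCalls"))
#' @rdname accessors
#' @export
setGeneric("modelFit", function(object) standardGeneric("modelFit"))

#' @rdname accessors
setMethod("purity", "CopyNumberFit", function(object) object@purity)
#' @rdname accessors
setMethod("ploidy", "CopyNumberFit", function(object) object@ploidy)
#' @rdname accessors
setMethod("periodDelta", "CopyNumberFit", function(object) object@delta)
#' @rdname accessors
setMethod("noiseSd", "CopyNumberFit", function(object) object@sigma)
#' @rdname accessors
setMethod("mixtureWeights", "CopyNumberFit", function(object) object@theta)
#' @rdname accessors
setMethod("modelBIC", "CopyNumberFit", function(object) object@bic)

#' @rdname accessors
setMethod("purity", "CopyNumberResult", function(object) object@fit@purity)
#' @rdname accessors
setMethod("ploidy", "CopyNumberResult", function(object) object@fit@ploidy)
#' @rdname accessors
setMethod("periodDelta", "CopyNumberResult", function(object) object@fit@delta)
#' @rdname accessors
setMethod("segmentCalls", "CopyNumberResult", function(object) object@calls)
#' @rdname accessors
setMethod("modelFit", "CopyNumberResult", function(object) object@fit)
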