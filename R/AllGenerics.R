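#' @include AllClasses.R
NULL

#' @export
setGeneric("deltaF", function(fn, n) standardGeneric("deltaF"))

#' @export
setGeneric("evaluateF", function(fn, n) standardGeneric("evaluateF"))

#' @export
setGeneric("isLinear", function(fn) standardGeneric("isLinear"))

#' @export
setGeneric("minRunReaching", function(fn, threshold, strict = FALSE)
  standardGeneric("minRunReaching"))

#' @export
setGeneric("contiguityFn", function(x) standardGeneric("contiguityFn"))

#' @export
setGeneric("mismatchPenalty", function(x) standardGeneric("mismatchPenalty"))

#' @export
setGeneric("gapOpen", function(x) standardGeneric("gapOpen"))

#' @export
setGeneric("gapExtend", function(x) standardGeneric("gapExtend"))

#' @export
setGeneric("gapModel", function(x) standardGeneric("gapModel"))

#' @export
setGeneric("alignmentMode", function(x) standardGeneric("alignmentMode"))

#' @export
setGeneric("bandWidth", function(x) standardGeneric("bandWidth"))

#' @export
setGeneric("depthCap", function(x) standardGeneric("depthCap"))

#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @export
setGeneric("targetInterval", function(x) standardGeneric("targetInterval"))

#' @export
setGeneric("queryInterval", function(x) standardGeneric("queryInterval"))

#' @export
setGeneric("alignmentOperations", function(x)
  standardGeneric("alignmentOperations"))

#' @export
setGeneric("alignedTarget", function(x) standardGeneric("alignedTarget"))

#' @export
setGeneric("alignedQuery", function(x) standardGeneric("alignedQuery"))

#' @export
setGeneric("maxContiguity", function(x) standardGeneric("maxContiguity"))

#' @export
setGeneric("alignmentIdentity", function(x)
  standardGeneric("alignmentIdentity"))

#' @export
setGeneric("engineStats", function(x) standardGeneric("engineStats"))

#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))

#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
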