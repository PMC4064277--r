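#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' ContiguityFunction: nonlinear scoring of match runs
#'
#' A contiguity function \eqn{f(n)} maps the length \eqn{n} of a run of
#' consecutive matching bases to its cumulative score.  The alignment engine
#' only ever consumes the increments \eqn{\Delta f(n) = f(n) - f(n-1)}, the
#' score gained by extending a run from \eqn{n-1} to \eqn{n} matches.
#' \eqn{f(0) = 0} by definition and \eqn{f} must be non-decreasing.
#'
#' @slot name Text label ("linear:1", "cubic", ...).
#' @slot fun Vectorized function from non-negative run length to cumulative
#'   score.
#' @slot isLinear TRUE iff \eqn{f(n) = c n}; the engine then needs a single
#'   depth node per cell.
#' @slot increment The constant \eqn{c} when linear, NA otherwise.
#' @exportClass ContiguityFunction
setClass("ContiguityFunction",
  representation(name = "character", fun = "function",
                 isLinear = "logical", increment = "numeric"))

setValidity("ContiguityFunction", function(object) {
  f <- object@fun
  v <- f(0:8)
  if (abs(v[1]) > 1e-9)
    return("f(0) must be 0")
  if (any(diff(v) < -1e-9))
    return("f must be non-decreasing")
  if (object@isLinear) {
    if (!isTRUE(all.equal(v, object@increment * (0:8))))
      return("isLinear=TRUE but f(n) != c*n")
  }
  TRUE
})

#' ScoringScheme: the definition of alignment optimality
#'
#' Bundles a contiguity function with the mismatch penalty \eqn{\rho_m}, gap
#' opening penalty \eqn{\rho_o}, gap extension penalty \eqn{\rho_e}, the gap
#' model (linear gaps ignore \eqn{\rho_o}), the alignment mode
#' (local/global), an optional band half-width, and an optional cap on
#' contiguity depth.
#'
#' Under the affine model a gap of \eqn{k} columns costs
#' \eqn{\rho_o + k \rho_e}; under the linear model \eqn{k \rho_e}.
#'
#' @slot fn A [ContiguityFunction-class].
#' @slot mismatch Non-negative mismatch penalty \eqn{\rho_m}.
#' @slot gapOpen Non-negative gap opening penalty \eqn{\rho_o} (treated as 0
#'   when `gapModel == "linear"`).
#' @slot gapExtend Non-negative gap extension penalty \eqn{\rho_e}.
#' @slot gapModel `"linear"` or `"affine"`.
#' @slot mode `"local"` or `"global"`.
#' @slot bandWidth Band half-width around the resampled diagonal
#'   (`Inf` = unbanded).
#' @slot depthCap Cap on contiguity depth nodes per cell; beyond the cap
#'   \eqn{\Delta f(n) = \Delta f(cap)} (`Inf` = uncapped).
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(fn = "ContiguityFunction", mismatch = "numeric",
                 gapOpen = "numeric", gapExtend = "numeric",
                 gapModel = "character", mode = "character",
                 bandWidth = "numeric", depthCap = "numeric"))

setValidity("ScoringScheme", function(object) {
  if (object@mismatch < 0 || object@gapOpen < 0 || object@gapExtend < 0)
    return("penalties must be non-negative")
  if (!object@gapModel %in% c("linear", "affine"))
    return("gapModel must be 'linear' or 'affine'")
  if (!object@mode %in% c("local", "global"))
    return("mode must be 'local' or 'global'")
  if (!is.infinite(object@bandWidth) &&
      (object@bandWidth < 1 || object@bandWidth != round(object@bandWidth)))
    return("bandWidth must be a positive integer or Inf")
  if (!is.infinite(object@depthCap) &&
      (object@depthCap < 1 || object@depthCap != round(object@depthCap)))
    return("depthCap must be a positive integer or Inf")
  TRUE
})

#' CellState: per-cell dynamic-programming state
#'
#' The state of one cell (i,j) of the 3D edit graph: the depth-indexed
#' contiguity scores \eqn{S_{i,j,n}}, the horizontal and vertical gap states,
#' the cell best \eqn{S_{i,j}}, and the contiguity depth \eqn{d_{i,j}}
#' (length of the matching suffix ending at the cell).
#'
#' `depthScores[1]` is the zero-contiguity state n = 0 (the best of mismatch
#' arrival, gap states and, in local mode, the restart 0); `depthScores[k]`
#' for k > 1 is the depth node n = k-1.  For a linear contiguity function a
#' single entry holds the merged diagonal state.
#'
#' @slot best Cell best score.
#' @slot depthScores Numeric vector of depth-indexed scores (see above).
#' @slot gapH Horizontal gap state (gap in target, consumes query).
#' @slot gapV Vertical gap state (gap in query, consumes target).
#' @slot depth Contiguity depth \eqn{d_{i,j}}.
#' @exportClass CellState
setClass("CellState",
  representation(best = "numeric", depthScores = "numeric",
                 gapH = "numeric", gapV = "numeric", depth = "integer"))

setValidity("CellState", function(object) {
  if (length(object@depthScores) < 1)
    return("depthScores must have at least the n = 0 entry")
  TRUE
})

#' AlignmentResult: an optimal pairwise alignment
#'
#' @slot score Alignment score under the scheme that produced it.
#' @slot targetId,queryId Sequence identifiers.
#' @slot targetInterval,queryInterval 0-based half-open aligned intervals.
#' @slot operations data.frame with columns `op` (one of M, X, I, D: match,
#'   mismatch, gap-in-target consuming query, gap-in-query consuming target)
#'   and `len` (run length).
#' @slot alignedTarget,alignedQuery Gapped text renderings.
#' @slot maxContiguity Longest match run length.
#' @slot identity Fraction of alignment columns that are matches.
#' @slot stats Engine instrumentation (max depth nodes per cell, cells
#'   computed, peak retained rows).
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(score = "numeric", targetId = "character",
                 queryId = "character", targetInterval = "integer",
                 queryInterval = "integer", operations = "data.frame",
                 alignedTarget = "character", alignedQuery = "character",
                 maxContiguity = "integer", identity = "numeric",
                 stats = "list"))

setValidity("AlignmentResult", function(object) {
  ops <- object@operations
  if (nrow(ops) > 0) {
    if (!all(ops$op %in% c("M", "X", "I", "D")))
      return("operations must be M, X, I or D")
    if (any(ops$len < 1))
      return("operation run lengths must be positive")
  }
  tlen <- sum(ops$len[ops$op %in% c("M", "X", "D")])
  qlen <- sum(ops$len[ops$op %in% c("M", "X", "I")])
  if (tlen != diff(object@targetInterval))
    return("operation lengths inconsistent with target interval")
  if (qlen != diff(object@queryInterval))
    return("operation lengths inconsistent with query interval")
  TRUE
})

#' MatchMatrix: cross-genome per-position agreement with a reference
#'
#' Boolean masks over reference positions for a set of genomes aligned to
#' the same reference: `covered` marks positions inside a genome's reported
#' alignment interval, `matched` marks covered positions where the aligned
#' bases are identical.  Matched implies covered everywhere.
#'
#' @slot referenceId Reference sequence identifier.
#' @slot matched,covered Logical genome x position matrices with genome ids
#'   as rownames.
#' @exportClass MatchMatrix
setClass("MatchMatrix",
  representation(referenceId = "character", matched = "matrix",
                 covered = "matrix"))

setValidity("MatchMatrix", function(object) {
  if (!identical(dim(object@matched), dim(object@covered)))
    return("matched and covered must have identical dimensions")
  if (is.null(rownames(object@matched)))
    return("matched must have genome ids as rownames")
  if (anyDuplicated(rownames(object@matched)))
    return("duplicate genome ids")
  if (any(object@matched & !object@covered))
    return("matched positions must be covered")
  TRUE
})
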