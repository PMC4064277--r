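#' @include scoring.R
#' @useDynLib contalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# normalise and validate an input sequence; returns uppercase character
prepSequence <- function(x, what = "sequence") {
  if (is(x, "XStringSet")) {
    if (length(x) != 1)
      stop(what, " must be a single sequence (got ", length(x), " records)")
    x <- as.character(x)
  }
  if (is(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1)
    stop(what, " must be a single character string, DNAString or ",
         "length-1 DNAStringSet")
  s <- toupper(x)
  if (nchar(s) == 0) stop(what, " is empty")
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0)
    stop("invalid character '", substr(s, bad, bad), "' in ", what,
         " at position ", bad, " (alphabet is A, C, G, T, N)")
  s
}

seqId <- function(x, default) {
  if (is(x, "XStringSet") && !is.null(names(x)) && nzchar(names(x)[1]))
    names(x)[1] else default
}

buildResult <- function(res, t, q, scheme, targetId, queryId) {
  ops <- data.frame(op = as.character(res$op), len = as.integer(res$len),
                    stringsAsFactors = FALSE)
  cols <- rep(ops$op, ops$len)
  tiv <- as.integer(c(res$t_start, res$t_end))
  qiv <- as.integer(c(res$q_start, res$q_end))
  tchars <- strsplit(substr(t, tiv[1] + 1, tiv[2]), "")[[1]]
  qchars <- strsplit(substr(q, qiv[1] + 1, qiv[2]), "")[[1]]
  at <- character(length(cols))
  aq <- character(length(cols))
  ct <- (cols %in% c("M", "X", "D"))
  cq <- (cols %in% c("M", "X", "I"))
  at[ct] <- tchars
  at[!ct] <- "-"
  aq[cq] <- qchars
  aq[!cq] <- "-"
  mruns <- ops$len[ops$op == "M"]
  new("AlignmentResult",
      score = res$score,
      targetId = targetId, queryId = queryId,
      targetInterval = tiv, queryInterval = qiv,
      operations = ops,
      alignedTarget = paste(at, collapse = ""),
      alignedQuery = paste(aq, collapse = ""),
      maxContiguity = if (length(mruns)) max(mruns) else 0L,
      identity = if (length(cols)) sum(cols == "M") / length(cols) else 0,
      stats = list(maxDepthNodes = res$max_depth_nodes,
                   cellsComputed = res$cells_computed,
                   peakRows = res$peak_rows))
}

#' Align two nucleotide sequences under a contiguity scoring scheme
#'
#' Computes the optimal pairwise alignment by dynamic programming over the
#' three-dimensional edit graph: each cell (i,j) carries one node per
#' contiguity depth n (the length of the matching suffix ending there), a
#' match arriving at depth n adds \eqn{\Delta f(n)}, a mismatch costs
#' \eqn{\rho_m}, and gaps are scored by the scheme's gap model via separate
#' horizontal/vertical gap states.  Local mode returns the maximal-scoring
#' local alignment (the empty alignment with score 0 is permitted); global
#' mode aligns both sequences end to end, charging boundary gaps.
#'
#' @param target,query Nucleotide sequences (character, DNAString or
#'   length-1 DNAStringSet) over A, C, G, T, N.  N never matches anything,
#'   including another N.
#' @param scheme A [ScoringScheme-class]; its `mode`, `bandWidth` and
#'   `depthCap` are honoured unless overridden.
#' @param bandWidth Optional band half-width override; cells farther than
#'   this from the resampled diagonal joining (0,0) and (N,M) are never
#'   created.
#' @param checkpointInterval Optional: run the check-pointed linear-space
#'   variant, retaining only every `checkpointInterval`-th full state row
#'   during the forward pass and recomputing blocks during traceback.  The
#'   result is identical to the full-matrix run.
#' @param targetId,queryId Identifiers recorded in the result (default from
#'   FASTA names or `"target"`/`"query"`).
#' @return An [AlignmentResult-class].
#' @examples
#' alignSequences("AAAA", "AAAA", schemePreset("swga_plus"))  # score 64
#' @seealso [alignBanded()], [alignLinearSpace()], [bruteForceAlign()],
#'   [rescoreAlignment()]
#' @export
alignSequences <- function(target, query, scheme = schemePreset("swga_plus"),
                           bandWidth = NULL, checkpointInterval = NULL,
                           targetId = NULL, queryId = NULL) {
  if (is.null(targetId)) targetId <- seqId(target, "target")
  if (is.null(queryId)) queryId <- seqId(query, "query")
  t <- prepSequence(target, "target")
  q <- prepSequence(query, "query")
  band <- if (is.null(bandWidth)) scheme@bandWidth else bandWidth
  if (!is.infinite(band) && (band < 1 || band != round(band)))
    stop("bandWidth must be a positive integer or Inf")
  cpi <- if (is.null(checkpointInterval)) 0L else as.integer(checkpointInterval)
  if (cpi < 0) stop("checkpointInterval must be >= 1")
  maxRun <- min(nchar(t), nchar(q))
  costs <- effGapCosts(scheme)
  res <- cpp_align(t, q, deltaFVector(scheme, maxRun),
                   effDepthCap(scheme, maxRun), scheme@mismatch,
                   costs[["open"]], costs[["extend"]],
                   scheme@mode == "local",
                   if (is.infinite(band)) -1 else band, cpi)
  buildResult(res, t, q, scheme, targetId, queryId)
}

#' Banded alignment
#'
#' Restricts the dynamic programme to a band of half-width `bandWidth`
#' around the resampled diagonal joining (0,0) and (N,M); off-band cells
#' are never created.  With `bandWidth >= max(N, M)` the result equals the
#' unbanded alignment exactly.  In global mode a band too narrow to connect
#' the corners raises an error.
#'
#' @inheritParams alignSequences
#' @param bandWidth Band half-width (positive integer).
#' @return An [AlignmentResult-class].
#' @export
alignBanded <- function(target, query, scheme = schemePreset("swga_plus"),
                        bandWidth, targetId = NULL, queryId = NULL) {
  stopifnot(!missing(bandWidth))
  alignSequences(target, query, scheme, bandWidth = bandWidth,
                 targetId = targetId, queryId = queryId)
}

#' Linear-space alignment with check-pointed traceback
#'
#' Memory-reduced alignment: the forward pass retains two rolling state
#' rows plus one full state row every `checkpointInterval` rows; during
#' traceback the blocks between checkpoints are recomputed exactly.  Scores,
#' intervals and operations are identical to [alignSequences()].
#'
#' @inheritParams alignSequences
#' @param checkpointInterval Rows between stored checkpoints (default
#'   `ceiling(sqrt(N))`, balancing recomputation and memory).
#' @return An [AlignmentResult-class]; `engineStats(x)$peakRows` reports the
#'   peak number of simultaneously retained full state rows.
#' @export
alignLinearSpace <- function(target, query,
                             scheme = schemePreset("swga_plus"),
                             checkpointInterval = NULL,
                             targetId = NULL, queryId = NULL) {
  if (is.null(checkpointInterval)) {
    N <- if (is(target, "XStringSet") || is(target, "XString"))
      nchar(as.character(target)[1]) else nchar(target)
    checkpointInterval <- max(1L, as.integer(ceiling(sqrt(N))))
  }
  if (checkpointInterval < 1) stop("checkpointInterval must be >= 1")
  alignSequences(target, query, scheme,
                 checkpointInterval = checkpointInterval,
                 targetId = targetId, queryId = queryId)
}

# ---------------------------------------------------------------------------
# single-cell recurrence (reference semantics, also used in tests)

#' Sentinel boundary cell
#'
#' The state fed to [computeCell()] for neighbours outside the matrix:
#' unreachable gap states and, in local mode, a zero restart.
#'
#' @param scheme A [ScoringScheme-class] (only the mode matters).
#' @return A [CellState-class].
#' @export
boundaryCell <- function(scheme = schemePreset("swga_plus")) {
  z <- if (scheme@mode == "local") 0 else -Inf
  new("CellState", best = z, depthScores = z, gapH = -Inf, gapV = -Inf,
      depth = 0L)
}

#' Compute one cell of the dynamic programme
#'
#' The per-cell recurrence, exposed for inspection and testing; the engine
#' applies the same rules in compiled code.  On a match, depth node n is the
#' diagonal predecessor's node n-1 plus \eqn{\Delta f(n)} (node 1 is seeded
#' from the predecessor's zero-contiguity state, so a match can follow a
#' gap).  The zero-contiguity state is the best of the mismatch arrival
#' (predecessor best minus \eqn{\rho_m}, only on a mismatch), the two gap
#' states, and the local restart 0.  Gap states open with cost
#' \eqn{\rho_o + \rho_e} from the neighbour's cell best and extend with
#' \eqn{\rho_e} from the neighbour's own gap state.
#'
#' @param prevDiag,prevUp,prevLeft Neighbour [CellState-class]s at
#'   (i-1,j-1), (i-1,j), (i,j-1); use [boundaryCell()] outside the matrix.
#' @param isMatch Do the target and query bases at (i,j) match?
#' @param scheme A [ScoringScheme-class].
#' @return The [CellState-class] at (i,j).
#' @export
computeCell <- function(prevDiag, prevUp, prevLeft, isMatch, scheme) {
  costs <- effGapCosts(scheme)
  open <- costs[["open"]]; e <- costs[["extend"]]
  local <- scheme@mode == "local"
  mism <- if (!isMatch) prevDiag@best - scheme@mismatch else -Inf
  gapH <- max(prevLeft@gapH - e, prevLeft@best - open)
  gapV <- max(prevUp@gapV - e, prevUp@best - open)
  z <- max(mism, gapH, gapV, if (local) 0 else -Inf)
  if (!isMatch) {
    return(new("CellState", best = max(z, -Inf), depthScores = z,
               gapH = gapH, gapV = gapV, depth = 0L))
  }
  d <- prevDiag@depth + 1L
  cap <- effDepthCap(scheme, d)
  if (scheme@fn@isLinear) {
    node <- max(prevDiag@depthScores) + scheme@fn@increment
    ds <- max(z, node)
  } else {
    nn <- min(d, cap)
    prev <- prevDiag@depthScores  # prev[k] = node n = k-1
    nodes <- numeric(nn)
    for (n in seq_len(nn))
      nodes[n] <- prev[n] + deltaF(scheme@fn, min(n, cap))
    if (d > cap && length(prev) >= cap + 1)
      nodes[cap] <- max(nodes[cap], prev[cap + 1] + deltaF(scheme@fn, cap))
    ds <- c(z, nodes)
  }
  new("CellState", best = max(ds), depthScores = ds,
      gapH = gapH, gapV = gapV, depth = d)
}

# ---------------------------------------------------------------------------
# rescoring (independent audit of engine output)

#' Re-score a run-length operation list
#'
#' Walks an alignment's operations accumulating \eqn{\Delta f} over each
#' match run (contiguity resets at every non-match column), \eqn{-\rho_m}
#' per mismatch column, and gap costs per the scheme's gap model
#' (affine: \eqn{-(\rho_o + L\rho_e)} per L-column gap run; linear:
#' \eqn{-\rho_e} per gap column).  For any engine output this reproduces
#' the reported score exactly.
#'
#' @param operations An [AlignmentResult-class] or its operations
#'   data.frame (columns `op` in M/X/I/D and `len`).
#' @param scheme The [ScoringScheme-class] to score under.
#' @return The score (numeric).
#' @export
rescoreAlignment <- function(operations, scheme) {
  if (is(operations, "AlignmentResult")) operations <- operations@operations
  if (!is.data.frame(operations) || !all(c("op", "len") %in% names(operations)))
    stop("operations must be a data.frame with columns 'op' and 'len'")
  if (nrow(operations) == 0) return(0)
  if (!all(operations$op %in% c("M", "X", "I", "D")) ||
      any(operations$len < 1) || any(operations$len != round(operations$len)))
    stop("malformed operation list")
  costs <- effGapCosts(scheme)
  maxRun <- max(operations$len[operations$op == "M"], 1)
  cap <- effDepthCap(scheme, maxRun)
  dfv <- if (scheme@fn@isLinear) rep(scheme@fn@increment, maxRun) else {
    inc <- diff(scheme@fn@fun(0:cap))
    c(inc, rep(inc[cap], max(0, maxRun - cap)))
  }
  cumf <- cumsum(dfv)
  score <- 0
  for (k in seq_len(nrow(operations))) {
    op <- operations$op[k]; len <- operations$len[k]
    score <- score + switch(op,
      M = cumf[len],
      X = -scheme@mismatch * len,
      -(costs[["open"]] + (len - 1) * costs[["extend"]]))
  }
  score
}

# ---------------------------------------------------------------------------
# result accessors and show

#' @describeIn alignSequences Alignment score.
#' @param x An AlignmentResult.
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @describeIn alignSequences 0-based half-open aligned interval on the
#'   target.
#' @export
setMethod("targetInterval", "AlignmentResult", function(x) x@targetInterval)

#' @describeIn alignSequences 0-based half-open aligned interval on the
#'   query.
#' @export
setMethod("queryInterval", "AlignmentResult", function(x) x@queryInterval)

#' @describeIn alignSequences Run-length operations (data.frame op/len).
#' @export
setMethod("alignmentOperations", "AlignmentResult", function(x) x@operations)

#' @describeIn alignSequences Gapped target rendering.
#' @export
setMethod("alignedTarget", "AlignmentResult", function(x) x@alignedTarget)

#' @describeIn alignSequences Gapped query rendering.
#' @export
setMethod("alignedQuery", "AlignmentResult", function(x) x@alignedQuery)

#' @describeIn alignSequences Longest match run length.
#' @export
setMethod("maxContiguity", "AlignmentResult", function(x) x@maxContiguity)

#' @describeIn alignSequences Fraction of alignment columns that are
#'   matches.
#' @export
setMethod("alignmentIdentity", "AlignmentResult", function(x) x@identity)

#' @describeIn alignSequences Engine instrumentation list (maxDepthNodes,
#'   cellsComputed, peakRows).
#' @export
setMethod("engineStats", "AlignmentResult", function(x) x@stats)

setMethod("show", "AlignmentResult", function(object) {
  cat("AlignmentResult: ", object@targetId, " [",
      object@targetInterval[1], ",", object@targetInterval[2], ") vs ",
      object@queryId, " [", object@queryInterval[1], ",",
      object@queryInterval[2], ")\n", sep = "")
  cat(sprintf("  score: %g  identity: %.3f  max contiguity: %d\n",
              object@score, object@identity, object@maxContiguity))
  cat("  cigar:", cigarString(object), "\n")
})

# CIGAR over M/X/I/D (X distinct from M so contiguity is recoverable)
cigarString <- function(result) {
  ops <- if (is(result, "AlignmentResult")) result@operations else result
  if (nrow(ops) == 0) return("*")
  paste0(ops$len, ops$op, collapse = "")
}
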