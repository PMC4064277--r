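#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# contiguity function constructors

newContiguityFunction <- function(name, fun, isLinear = FALSE, increment = NA_real_) {
  new("ContiguityFunction", name = name, fun = fun,
      isLinear = isLinear, increment = as.numeric(increment))
}

#' Contiguity scoring functions
#'
#' Constructors for the match-run scoring functions \eqn{f(n)} accepted by
#' [scoringScheme()].  All satisfy \eqn{f(0) = 0} and are non-decreasing.
#'
#' * `linearScoring(c)`: \eqn{f(n) = c n} — every match worth the same,
#'   recovering SW/SWGA behaviour.
#' * `quadraticScoring()`: \eqn{f(n) = n^2}.
#' * `cubicScoring()`: \eqn{f(n) = n^3}, the default; rewards contiguous
#'   motif-length runs strongly without the explosiveness of an exponential.
#' * `exponentialScoring(base)`: \eqn{f(n) = base^n - 1}.
#' * `tabulatedScoring(values)`: user-supplied \eqn{f(1), f(2), \ldots};
#'   beyond the table the last increment is extended indefinitely.
#'
#' @param c Linear increment per match (default 1).
#' @param base Exponential base (> 1).
#' @param values Non-decreasing numeric vector of cumulative scores
#'   \eqn{f(1..K)}.
#' @return A [ContiguityFunction-class].
#' @examples
#' f <- cubicScoring()
#' evaluateF(f, 4)   # 64
#' deltaF(f, 3)      # 19
#' @export
linearScoring <- function(c = 1) {
  stopifnot(is.numeric(c), length(c) == 1, c >= 0)
  force(c)
  newContiguityFunction(sprintf("linear:%g", c), function(n) c * n,
                        isLinear = TRUE, increment = c)
}

#' @rdname linearScoring
#' @export
quadraticScoring <- function() {
  newContiguityFunction("quadratic", function(n) n^2)
}

#' @rdname linearScoring
#' @export
cubicScoring <- function() {
  newContiguityFunction("cubic", function(n) n^3)
}

#' @rdname linearScoring
#' @export
exponentialScoring <- function(base = 2) {
  stopifnot(is.numeric(base), length(base) == 1, base > 1)
  force(base)
  newContiguityFunction(sprintf("exp:%g", base), function(n) base^n - 1)
}

#' @rdname linearScoring
#' @export
tabulatedScoring <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (any(values < 0) || any(diff(c(0, values)) < 0))
    stop("tabulated values must be non-negative and non-decreasing")
  vals <- as.numeric(values)
  K <- length(vals)
  lastInc <- if (K == 1) vals[1] else vals[K] - vals[K - 1]
  fun <- function(n) {
    ifelse(n <= 0, 0,
           ifelse(n <= K, c(0, vals)[pmin(n, K) + 1],
                  vals[K] + (n - K) * lastInc))
  }
  newContiguityFunction(paste0("tabulated:", paste(vals, collapse = ",")), fun)
}

#' Parse a textual contiguity-function specification
#'
#' Accepts `"cubic"`, `"quadratic"`, `"linear"` / `"linear:c"`,
#' `"exp:base"` and `"tabulated:v1,v2,..."` — the grammar used by scheme
#' config files and the command line's `--scoring` flag.
#'
#' @param text Specification string.
#' @return A [ContiguityFunction-class].
#' @export
parseContiguityFunction <- function(text) {
  text <- trimws(text)
  if (text == "cubic") return(cubicScoring())
  if (text == "quadratic") return(quadraticScoring())
  if (text == "linear") return(linearScoring(1))
  if (grepl("^linear:", text))
    return(linearScoring(as.numeric(sub("^linear:", "", text))))
  if (grepl("^exp:", text))
    return(exponentialScoring(as.numeric(sub("^exp:", "", text))))
  if (grepl("^tabulated:", text)) {
    vals <- as.numeric(strsplit(sub("^tabulated:", "", text), ",")[[1]])
    return(tabulatedScoring(vals))
  }
  stop("unknown contiguity function '", text,
       "' (expected cubic, quadratic, linear[:c], exp:b or tabulated:v1,v2,...)")
}

# ---------------------------------------------------------------------------
# f and delta-f

#' @describeIn linearScoring Evaluate \eqn{f(n)} (vectorized over `n`).
#' @param fn A [ContiguityFunction-class].
#' @param n Run length(s).
#' @export
setMethod("evaluateF", "ContiguityFunction", function(fn, n) {
  stopifnot(all(n >= 0))
  fn@fun(n)
})

#' @describeIn linearScoring The score increment
#'   \eqn{\Delta f(n) = f(n) - f(n-1)} gained by the n-th consecutive match
#'   (requires n >= 1).
#' @export
setMethod("deltaF", "ContiguityFunction", function(fn, n) {
  if (any(n < 1)) stop("deltaF is defined for n >= 1")
  fn@fun(n) - fn@fun(n - 1)
})

#' @describeIn linearScoring TRUE iff the function is linear.
#' @export
setMethod("isLinear", "ContiguityFunction", function(fn) fn@isLinear)

#' Smallest run length whose cumulative score reaches a threshold
#'
#' Returns the smallest n with \eqn{f(n) \ge threshold} (or strictly
#' \eqn{>} when `strict = TRUE`).  Under the default cubic function and
#' penalty set, two consecutive matches balance one mismatch penalty
#' (\eqn{f(2) = 8 = \rho_m}) and three consecutive matches outscore a
#' single gap extension (\eqn{f(3) = 27 > \rho_e = 20}).
#'
#' @param fn A [ContiguityFunction-class].
#' @param threshold Positive score threshold.
#' @param strict Require strict exceedance.
#' @return Smallest qualifying run length (positive integer).
#' @examples
#' minRunReaching(cubicScoring(), 8)               # 2
#' minRunReaching(cubicScoring(), 20, strict = TRUE)  # 3
#' @export
setMethod("minRunReaching", "ContiguityFunction",
          function(fn, threshold, strict = FALSE) {
  stopifnot(threshold > 0)
  stalled <- 0L
  prev <- 0
  for (n in seq_len(1000000L)) {
    v <- fn@fun(n)
    if (if (strict) v > threshold else v >= threshold) return(n)
    stalled <- if (v - prev <= 0) stalled + 1L else 0L
    if (stalled >= 1000L) stop("threshold unreachable: f has stopped increasing")
    prev <- v
  }
  stop("threshold unreachable")
})

# ---------------------------------------------------------------------------
# scoring schemes

#' Construct a scoring scheme
#'
#' @param fn A [ContiguityFunction-class] (default cubic).
#' @param mismatch Mismatch penalty \eqn{\rho_m} (default 8).
#' @param gapOpen Gap opening penalty \eqn{\rho_o} (default 200; ignored
#'   under the linear gap model).
#' @param gapExtend Gap extension penalty \eqn{\rho_e} (default 20).
#' @param gapModel `"affine"` (gap of k columns costs
#'   \eqn{\rho_o + k\rho_e}) or `"linear"` (\eqn{k\rho_e}).
#' @param mode `"local"` or `"global"`.
#' @param bandWidth Band half-width (Inf = unbanded).
#' @param depthCap Contiguity depth cap (Inf = uncapped).
#' @return A validated [ScoringScheme-class].
#' @seealso [schemePreset()] for the four named method presets.
#' @export
scoringScheme <- function(fn = cubicScoring(), mismatch = 8, gapOpen = 200,
                          gapExtend = 20, gapModel = c("affine", "linear"),
                          mode = c("local", "global"), bandWidth = Inf,
                          depthCap = Inf) {
  gapModel <- match.arg(gapModel)
  mode <- match.arg(mode)
  new("ScoringScheme", fn = fn, mismatch = as.numeric(mismatch),
      gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
      gapModel = gapModel, mode = mode, bandWidth = as.numeric(bandWidth),
      depthCap = as.numeric(depthCap))
}

#' Named method presets
#'
#' The four alignment schemes compared throughout the package:
#'
#' * `"sw"` — Smith-Waterman: linear match scoring (c = 1), linear gaps.
#' * `"swga"` — gap-affine Smith-Waterman: linear match scoring, affine gaps.
#' * `"sw_plus"` (alias `"sw+"`) — cubic contiguity scoring, linear gaps.
#' * `"swga_plus"` (alias `"swga+"`) — cubic contiguity scoring, affine
#'   gaps; the default method.
#'
#' The cubic presets use the empirically balanced penalty set
#' \eqn{\rho_m = 8}, \eqn{\rho_o = 200}, \eqn{\rho_e = 20}: two consecutive
#' matches balance one mismatch (\eqn{f(2) = 8}), three outscore a gap
#' extension (\eqn{f(3) = 27 > 20}), and a gap opening costs between six
#' and seven consecutive matches (\eqn{f(6) < \rho_o + \rho_e \le f(7)}).
#' The linear presets keep the match reward at c = 1 and rescale the
#' penalties so the same run-length relations hold under \eqn{f(n) = n}:
#' \eqn{\rho_m = 2}, \eqn{\rho_e = 2}, \eqn{\rho_o = 5}.  All presets are
#' local by default.
#'
#' @param name Preset name.
#' @return A [ScoringScheme-class].
#' @examples
#' schemePreset("swga_plus")
#' @export
schemePreset <- function(name) {
  key <- gsub("\\+", "_plus", tolower(trimws(name)))
  switch(key,
    sw = scoringScheme(linearScoring(1), mismatch = 2, gapOpen = 0,
                       gapExtend = 2, gapModel = "linear"),
    swga = scoringScheme(linearScoring(1), mismatch = 2, gapOpen = 5,
                         gapExtend = 2, gapModel = "affine"),
    sw_plus = scoringScheme(cubicScoring(), gapOpen = 0, gapModel = "linear"),
    swga_plus = scoringScheme(cubicScoring(), gapModel = "affine"),
    stop("unknown preset '", name,
         "'; valid presets: sw, swga, sw_plus (sw+), swga_plus (swga+)"))
}

# effective gap costs: first gap column, further columns
effGapCosts <- function(scheme) {
  e <- scheme@gapExtend
  o <- if (scheme@gapModel == "linear") 0 else scheme@gapOpen
  c(open = o + e, extend = e)
}

# effective depth cap for sequences allowing runs up to maxRun
effDepthCap <- function(scheme, maxRun) {
  if (scheme@fn@isLinear) return(1L)
  as.integer(min(scheme@depthCap, maxRun))
}

# increments delta_f(1..cap)
deltaFVector <- function(scheme, maxRun) {
  cap <- effDepthCap(scheme, maxRun)
  if (scheme@fn@isLinear) return(scheme@fn@increment)
  diff(scheme@fn@fun(0:cap))
}

# ---------------------------------------------------------------------------
# accessors and show

#' @describeIn scoringScheme The contiguity function.
#' @param x A ScoringScheme.
#' @export
setMethod("contiguityFn", "ScoringScheme", function(x) x@fn)

#' @describeIn scoringScheme Mismatch penalty.
#' @export
setMethod("mismatchPenalty", "ScoringScheme", function(x) x@mismatch)

#' @describeIn scoringScheme Gap opening penalty (0 under the linear model).
#' @export
setMethod("gapOpen", "ScoringScheme",
          function(x) if (x@gapModel == "linear") 0 else x@gapOpen)

#' @describeIn scoringScheme Gap extension penalty.
#' @export
setMethod("gapExtend", "ScoringScheme", function(x) x@gapExtend)

#' @describeIn scoringScheme Gap model.
#' @export
setMethod("gapModel", "ScoringScheme", function(x) x@gapModel)

#' @describeIn scoringScheme Alignment mode.
#' @export
setMethod("alignmentMode", "ScoringScheme", function(x) x@mode)

#' @describeIn scoringScheme Band half-width.
#' @export
setMethod("bandWidth", "ScoringScheme", function(x) x@bandWidth)

#' @describeIn scoringScheme Depth cap.
#' @export
setMethod("depthCap", "ScoringScheme", function(x) x@depthCap)

setMethod("show", "ContiguityFunction", function(object) {
  cat("ContiguityFunction:", object@name,
      if (object@isLinear) "(linear)" else "(nonlinear)", "\n")
  n <- 1:6
  cat("  f(1..6):    ", paste(object@fun(n), collapse = " "), "\n")
  cat("  deltaF(1..6):", paste(object@fun(n) - object@fun(n - 1),
                               collapse = " "), "\n")
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme (", object@mode, ", ", object@gapModel, " gaps)\n",
      sep = "")
  cat("  f:", object@fn@name, " mismatch:", object@mismatch,
      " gapOpen:", gapOpen(object), " gapExtend:", object@gapExtend, "\n")
  if (!is.infinite(object@bandWidth))
    cat("  band half-width:", object@bandWidth, "\n")
  if (!is.infinite(object@depthCap))
    cat("  depth cap:", object@depthCap, "\n")
})

# ---------------------------------------------------------------------------
# flat key/value serialization

#' Read and write scoring scheme configuration files
#'
#' Schemes serialize to a flat plain-text config with one `key=value` pair
#' per line: `function`, `mismatch`, `gap_open`, `gap_extend`, `gap_model`,
#' `mode`, `band`, `depth_cap`.  `band` and `depth_cap` accept `inf`.
#'
#' @param scheme A [ScoringScheme-class].
#' @param path File path.
#' @return `readScoringScheme` returns a [ScoringScheme-class];
#'   `writeScoringScheme` returns `path` invisibly.
#' @export
writeScoringScheme <- function(scheme, path) {
  lines <- c(
    paste0("function=", scheme@fn@name),
    paste0("mismatch=", scheme@mismatch),
    paste0("gap_open=", scheme@gapOpen),
    paste0("gap_extend=", scheme@gapExtend),
    paste0("gap_model=", scheme@gapModel),
    paste0("mode=", scheme@mode),
    paste0("band=", if (is.infinite(scheme@bandWidth)) "inf" else scheme@bandWidth),
    paste0("depth_cap=", if (is.infinite(scheme@depthCap)) "inf" else scheme@depthCap))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScoringScheme
#' @export
readScoringScheme <- function(path) {
  if (!file.exists(path)) stop("no such scheme file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed scheme line: '", lines[bad][1], "'")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  num <- function(v) if (tolower(v) %in% c("inf", "unbounded")) Inf else as.numeric(v)
  scoringScheme(
    fn = parseContiguityFunction(get("function", "cubic")),
    mismatch = as.numeric(get("mismatch", "8")),
    gapOpen = as.numeric(get("gap_open", "200")),
    gapExtend = as.numeric(get("gap_extend", "20")),
    gapModel = get("gap_model", "affine"),
    mode = get("mode", "local"),
    bandWidth = num(get("band", "inf")),
    depthCap = num(get("depth_cap", "inf")))
}
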