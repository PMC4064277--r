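#' @include consistency.R
#' @importFrom stats rgeom runif
NULL

# run code under a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

#' Uniform random nucleotide sequence
#'
#' i.i.d. uniform over A, C, G, T, reproducible from the seed; the global
#' RNG state is left untouched.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A character string.
#' @export
randomSequence <- function(length, seed) {
  if (length < 1) stop("length must be >= 1")
  withSeed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
}

substituteBase <- function(base) sample(setdiff(BASES, base), 1)

#' Simulate an ortholog family with planted conserved motifs
#'
#' Emulates the 3'UTR setting in which short, highly conserved recognition
#' motifs (the poly-adenylation signal AATAAA by default) sit inside
#' diverged flanks: a uniform random reference receives `nMotifs`
#' non-overlapping motif copies (starts at least two motif lengths apart),
#' and each ortholog is derived independently (star topology) by
#' per-position substitution — flanks at `flankSubRate`, motif positions at
#' `motifSubRate` — and indels at `flankIndelRate` per flank position with
#' geometric(`indelGeomP`) lengths.  Indels never touch motif positions
#' while `motifSubRate == 0`.  Fully reproducible from `seed`
#' (per-genome substreams are derived deterministically).
#'
#' The defaults are the package's reference study conditions for the
#' consistency experiments: 300 bp references, 10 genomes, 3 motifs, 30%
#' flank divergence, 2% indel rate, 1% motif divergence.
#'
#' @param refLength Reference length (>= `nMotifs * 2 * nchar(motif)`).
#' @param nGenomes Number of ortholog sequences.
#' @param motif Planted motif (default `"AATAAA"`).
#' @param nMotifs Number of planted copies.
#' @param flankSubRate,motifSubRate Per-position substitution probabilities
#'   in \[0, 1\].
#' @param flankIndelRate Per-position indel initiation probability in
#'   \[0, 1\].
#' @param indelGeomP Geometric length parameter (indel length is
#'   `1 + rgeom(indelGeomP)`).
#' @param seed Integer seed.
#' @return A list with `reference` (named character), `orthologs` (named
#'   [Biostrings::DNAStringSet]), `motifs` ([IRanges::IRanges] of planted
#'   intervals on the reference), and `preserved` (genome x motif logical
#'   matrix: TRUE when no substitution or indel touched the motif in that
#'   genome).
#' @export
simulateFamily <- function(refLength = 300, nGenomes = 10, motif = "AATAAA",
                           nMotifs = 3, flankSubRate = 0.3,
                           flankIndelRate = 0.02, motifSubRate = 0.01,
                           indelGeomP = 0.5, seed = 1) {
  rates <- c(flankSubRate, flankIndelRate, motifSubRate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]")
  if (indelGeomP <= 0 || indelGeomP > 1)
    stop("indelGeomP must lie in (0, 1]")
  mlen <- nchar(motif)
  if (refLength < nMotifs * 2 * mlen)
    stop("refLength must be at least nMotifs * 2 * motif length")
  withSeed(seed, {
    refChars <- sample(BASES, refLength, replace = TRUE)
    starts <- NULL
    for (try in seq_len(1000)) {
      cand <- sort(sample(seq_len(refLength - mlen + 1), nMotifs))
      if (nMotifs == 1 || all(diff(cand) >= 2 * mlen)) { starts <- cand; break }
    }
    if (is.null(starts))
      stop("could not place ", nMotifs, " non-overlapping motifs after ",
           "1000 attempts")
    motifChars <- strsplit(toupper(motif), "")[[1]]
    inMotif <- logical(refLength)
    for (s in starts) {
      refChars[s:(s + mlen - 1)] <- motifChars
      inMotif[s:(s + mlen - 1)] <- TRUE
    }
    reference <- paste(refChars, collapse = "")
  })
  motifsIR <- IRanges::IRanges(start = starts, width = mlen)
  whichMotif <- integer(refLength)
  for (k in seq_along(starts))
    whichMotif[starts[k]:(starts[k] + mlen - 1)] <- k

  indelsInMotifs <- motifSubRate > 0
  orth <- character(nGenomes)
  preserved <- matrix(TRUE, nGenomes, nMotifs,
                      dimnames = list(sprintf("genome_%02d", seq_len(nGenomes)),
                                      NULL))
  for (g in seq_len(nGenomes)) {
    gseed <- (seed + 7919 * g) %% 2147483647L
    withSeed(gseed, {
      out <- character(0)
      i <- 1L
      while (i <= refLength) {
        mot <- inMotif[i]
        # indel initiation (never inside motifs unless motifSubRate > 0)
        if ((!mot || indelsInMotifs) && runif(1) < flankIndelRate) {
          len <- 1L + rgeom(1, indelGeomP)
          if (runif(1) < 0.5) {
            out <- c(out, sample(BASES, len, replace = TRUE))  # insertion
            if (mot) preserved[g, whichMotif[i]] <- FALSE
          } else {
            del <- i:min(refLength, i + len - 1L)
            if (!indelsInMotifs && any(inMotif[del])) {
              del <- del[seq_len(match(TRUE, inMotif[del]) - 1L)]
            }
            hit <- unique(whichMotif[del][whichMotif[del] > 0])
            if (length(hit)) preserved[g, hit] <- FALSE
            i <- i + length(del)
            next
          }
        }
        subRate <- if (mot) motifSubRate else flankSubRate
        b <- refChars[i]
        if (subRate > 0 && runif(1) < subRate) {
          b <- substituteBase(b)
          if (mot) preserved[g, whichMotif[i]] <- FALSE
        }
        out <- c(out, b)
        i <- i + 1L
      }
      orth[g] <- paste(out, collapse = "")
    })
  }
  orthologs <- Biostrings::DNAStringSet(orth)
  names(orthologs) <- rownames(preserved)
  list(reference = c(reference = reference), orthologs = orthologs,
       motifs = motifsIR, preserved = preserved)
}

#' Align a family of orthologs to its reference
#'
#' Convenience pipeline: aligns every ortholog (query) to the reference
#' (target) under a scheme and assembles the [MatchMatrix-class] backing
#' the consistency metrics.
#'
#' @param reference Reference sequence.
#' @param orthologs Named [Biostrings::DNAStringSet] (or named character).
#' @param scheme A [ScoringScheme-class].
#' @param referenceId Id recorded in the matrix (default `"reference"`).
#' @return A [MatchMatrix-class].
#' @export
familyMatchMatrix <- function(reference, orthologs,
                              scheme = schemePreset("swga_plus"),
                              referenceId = "reference") {
  ids <- names(orthologs)
  if (is.null(ids)) stop("orthologs must be named")
  aln <- lapply(seq_along(orthologs), function(k)
    alignSequences(reference, as.character(orthologs[[k]]), scheme,
                   targetId = referenceId, queryId = ids[k]))
  names(aln) <- ids
  buildMatchMatrix(reference, aln, referenceId = referenceId)
}

#' Count planted motifs recovered as conserved elements
#'
#' A planted motif instance counts as recovered when its reference interval
#' lies entirely inside a conserved element.
#'
#' @param elements [IRanges::IRanges] from [findConservedElements()].
#' @param motifs [IRanges::IRanges] of planted motif intervals.
#' @return Number of recovered motif instances.
#' @export
countRecoveredMotifs <- function(elements, motifs) {
  if (length(motifs) == 0 || length(elements) == 0) return(0L)
  ov <- IRanges::countOverlaps(motifs, elements, type = "within")
  sum(ov > 0)
}

#' Brute-force alignment score by exhaustive path enumeration
#'
#' Enumerates every alignment (every monotone path of match, mismatch and
#' gap columns; in local mode, between all cell pairs, the empty alignment
#' included) and returns the maximum score under the rescoring semantics of
#' [rescoreAlignment()].  This is the validation oracle for the dynamic
#' programming engine and shares no code with it.  Guarded to tiny inputs:
#' `nchar(target) * nchar(query) <= 100`.
#'
#' @inheritParams alignSequences
#' @return The optimal score (numeric).
#' @examples
#' bruteForceAlign("AC", "AC", schemePreset("swga_plus"))  # 8
#' @export
bruteForceAlign <- function(target, query, scheme = schemePreset("swga_plus")) {
  t <- prepSequence(target, "target")
  q <- prepSequence(query, "query")
  if (nchar(t) * nchar(q) > 100)
    stop("brute-force oracle is guarded to nchar(target) * nchar(query) <= 100")
  maxRun <- min(nchar(t), nchar(q))
  costs <- effGapCosts(scheme)
  cpp_brute_force(t, q, deltaFVector(scheme, maxRun),
                  effDepthCap(scheme, maxRun), scheme@mismatch,
                  costs[["open"]], costs[["extend"]],
                  scheme@mode == "local")
}
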