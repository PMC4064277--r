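#' @include io.R
#' @importFrom IRanges IRanges
NULL

#' Build a cross-genome match matrix from pairwise alignments
#'
#' Walks each genome's alignment of the shared reference (the alignment
#' target), marking every reference position inside the aligned interval as
#' covered and every match column as matched.  Deletion columns (gap in the
#' genome, `D`) are covered but not matched; insertion columns (`I`)
#' consume no reference position.
#'
#' @param reference The reference sequence (character, DNAString or length-1
#'   DNAStringSet); only its length and id are used here.
#' @param alignments Named list of [AlignmentResult-class], one per genome,
#'   names are genome ids; each alignment's target must be the reference.
#' @param referenceId Optional id override.
#' @return A [MatchMatrix-class].
#' @export
buildMatchMatrix <- function(reference, alignments, referenceId = NULL) {
  if (is.null(referenceId)) referenceId <- seqId(reference, "reference")
  refLen <- if (is(reference, "XStringSet") || is(reference, "XString"))
    nchar(as.character(reference)[1]) else nchar(reference)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list (genome ids)")
  if (anyDuplicated(names(alignments)))
    stop("duplicate genome id '", names(alignments)[anyDuplicated(names(alignments))], "'")
  g <- length(alignments)
  matched <- matrix(FALSE, g, refLen, dimnames = list(names(alignments), NULL))
  covered <- matched
  for (k in seq_len(g)) {
    a <- alignments[[k]]
    iv <- a@targetInterval
    if (iv[2] > refLen)
      stop("alignment for genome '", names(alignments)[k],
           "' exceeds reference length (", iv[2], " > ", refLen, ")")
    if (iv[2] > iv[1]) covered[k, (iv[1] + 1):iv[2]] <- TRUE
    pos <- iv[1]
    ops <- a@operations
    for (r in seq_len(nrow(ops))) {
      op <- ops$op[r]; len <- ops$len[r]
      if (op == "M") matched[k, (pos + 1):(pos + len)] <- TRUE
      if (op %in% c("M", "X", "D")) pos <- pos + len
    }
  }
  new("MatchMatrix", referenceId = referenceId, matched = matched,
      covered = covered)
}

#' @describeIn buildMatchMatrix Number of reference positions.
#' @param x A MatchMatrix.
#' @export
setMethod("nPositions", "MatchMatrix", function(x) ncol(x@matched))

#' @describeIn buildMatchMatrix Genome ids.
#' @export
setMethod("genomeIds", "MatchMatrix", function(x) rownames(x@matched))

#' @describeIn buildMatchMatrix Reference id.
#' @export
setMethod("referenceId", "MatchMatrix", function(x) x@referenceId)

setMethod("show", "MatchMatrix", function(object) {
  cat("MatchMatrix: reference '", object@referenceId, "', ",
      ncol(object@matched), " positions, ", nrow(object@matched),
      " genomes\n", sep = "")
  cat(sprintf("  matched cells: %d / %d covered\n",
              sum(object@matched), sum(object@covered)))
})

#' Per-position cross-genome agreement
#'
#' The fraction of genomes whose aligned base matches the reference at each
#' position.  With `denominator = "covered_genomes"` (the default, reading
#' "90% of the aligned genomes" literally) the fraction is taken over the
#' genomes whose alignment covers the position; positions covered by no
#' genome are `NA` and are excluded from histograms.  With `"all_genomes"`
#' the denominator is the full genome count.
#'
#' @param mm A [MatchMatrix-class].
#' @param denominator `"covered_genomes"` or `"all_genomes"`.
#' @return Numeric vector of fractions (length `nPositions(mm)`), `NA`
#'   where undefined.
#' @export
agreementProfile <- function(mm, denominator = c("covered_genomes",
                                                 "all_genomes")) {
  denominator <- match.arg(denominator)
  if (nrow(mm@matched) < 1) stop("match matrix has no genomes")
  nm <- colSums(mm@matched)
  if (denominator == "all_genomes") return(nm / nrow(mm@matched))
  nc <- colSums(mm@covered)
  ifelse(nc > 0, nm / pmax(nc, 1), NA_real_)
}

#' Binned agreement histogram
#'
#' Counts reference positions per agreement-fraction bin (equal bins over
#' \[0,1\], the top bin right-closed), normalised by the total number of
#' covered positions.  When a `baseline` matrix is given, the returned
#' counts and fractions are differences (this matrix minus baseline), the
#' comparison used to contrast scoring schemes against plain SW.
#'
#' @param mm A [MatchMatrix-class].
#' @param bins Number of bins (>= 2).
#' @param baseline Optional baseline [MatchMatrix-class] over the same
#'   reference positions.
#' @param denominator Passed to [agreementProfile()].
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`, `fraction`
#'   (differences when `baseline` is given).
#' @export
agreementHistogram <- function(mm, bins = 10, baseline = NULL,
                               denominator = "covered_genomes") {
  stopifnot(bins >= 2)
  one <- function(m) {
    p <- agreementProfile(m, denominator)
    p <- p[!is.na(p)]
    idx <- pmin(floor(p * bins) + 1L, bins)
    counts <- tabulate(idx, nbins = bins)
    list(counts = counts, total = length(p))
  }
  a <- one(mm)
  out <- data.frame(bin_lo = (seq_len(bins) - 1) / bins,
                    bin_hi = seq_len(bins) / bins,
                    count = a$counts,
                    fraction = if (a$total > 0) a$counts / a$total else
                      rep(0, bins))
  if (!is.null(baseline)) {
    if (nPositions(baseline) != nPositions(mm))
      stop("baseline has a different number of reference positions")
    b <- one(baseline)
    out$count <- out$count - b$counts
    out$fraction <- out$fraction -
      (if (b$total > 0) b$counts / b$total else rep(0, bins))
  }
  out
}

#' Find conserved contiguous elements
#'
#' Maximal runs of consecutive reference positions whose cross-genome
#' agreement (denominator: covered genomes) is at least `minFrac`, reported
#' when at least `minLen` positions long — the "elements of n consecutive
#' nucleotides matched in most genomes" measure.  Positions whose agreement
#' equals `minFrac` exactly are inside elements.
#'
#' @param mm A [MatchMatrix-class].
#' @param minLen Minimum element length (default 6, the length of the
#'   poly-adenylation signal).
#' @param minFrac Minimum per-position agreement fraction (default 0.9).
#' @return An [IRanges::IRanges] (1-based, closed, per IRanges convention)
#'   with metadata column `minAgreement`; total conserved sequence is
#'   `sum(width(.))`.
#' @export
findConservedElements <- function(mm, minLen = 6, minFrac = 0.9) {
  stopifnot(minFrac > 0, minFrac <= 1, minLen >= 1)
  p <- agreementProfile(mm, "covered_genomes")
  ok <- !is.na(p) & p >= minFrac - 1e-12
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= minLen
  ir <- IRanges::IRanges(start = starts[keep], end = ends[keep])
  minAg <- vapply(which(keep), function(k)
    min(p[starts[k]:ends[k]]), numeric(1))
  S4Vectors::mcols(ir) <- S4Vectors::DataFrame(minAgreement = minAg)
  ir
}

#' k-mer frequencies inside conserved elements
#'
#' Counts every k-window lying fully inside an element, over the reference
#' sequence (reference strand only; overlapping windows counted).
#'
#' @param reference Reference sequence (character, DNAString or length-1
#'   DNAStringSet).
#' @param elements [IRanges::IRanges] of elements on the reference (1-based,
#'   as returned by [findConservedElements()]).
#' @param k Word size (default 6).
#' @return Named integer vector of counts, decreasing; k-mers never
#'   observed are omitted.  Elements shorter than k contribute nothing.
#' @export
kmerFrequencies <- function(reference, elements, k = 6) {
  stopifnot(k >= 1)
  refseq <- if (is(reference, "XStringSet") || is(reference, "XString"))
    as.character(reference)[1] else reference
  refseq <- toupper(refseq)
  counts <- integer(0)
  for (i in seq_along(elements)) {
    s <- IRanges::start(elements)[i]; e <- IRanges::end(elements)[i]
    if (e - s + 1 < k) next
    sub <- substr(refseq, s, e)
    kms <- substring(sub, 1:(nchar(sub) - k + 1), k:nchar(sub))
    tab <- table(kms)
    for (km in names(tab))
      counts[km] <- (if (km %in% names(counts)) counts[km] else 0L) +
        as.integer(tab[[km]])
  }
  sort(counts, decreasing = TRUE)
}

#' Restrict methods to their common coverage
#'
#' Intersects, per genome and reference position, the coverage masks of all
#' methods, so consistency measures compare the methods on the regions in
#' which every method reports alignments.  Idempotent; symmetric in the
#' methods.
#'
#' @param methodMatrices Named list: method -> list of
#'   [MatchMatrix-class] (one per reference).
#' @return The same structure with `covered` and `matched` masked to the
#'   common coverage.
#' @export
restrictToCommonCoverage <- function(methodMatrices) {
  refIds <- lapply(methodMatrices, function(l) vapply(l, referenceId, ""))
  base <- refIds[[1]]
  for (r in refIds[-1])
    if (!identical(sort(r), sort(base)))
      stop("methods cover different reference sets")
  methodMatrices <- lapply(methodMatrices, function(l) {
    names(l) <- vapply(l, referenceId, "")
    l[base]
  })
  for (ref in base) {
    mats <- lapply(methodMatrices, `[[`, ref)
    dims <- vapply(mats, function(m) ncol(m@covered), 0)
    if (length(unique(dims)) != 1)
      stop("inconsistent reference length for '", ref, "' across methods")
    gids <- lapply(mats, genomeIds)
    for (g in gids[-1])
      if (!identical(sort(g), sort(gids[[1]])))
        stop("inconsistent genome sets for '", ref, "' across methods")
    ord <- sort(gids[[1]])
    common <- Reduce(`&`, lapply(mats, function(m) m@covered[ord, , drop = FALSE]))
    for (meth in names(methodMatrices)) {
      m <- methodMatrices[[meth]][[ref]]
      cov <- m@covered[ord, , drop = FALSE] & common
      mat <- m@matched[ord, , drop = FALSE] & common
      methodMatrices[[meth]][[ref]] <-
        new("MatchMatrix", referenceId = m@referenceId,
            matched = mat, covered = cov)
    }
  }
  methodMatrices
}

#' Compare alignment methods on consistency measures
#'
#' For each method: total matched nucleotides (sum over genome x position
#' matched cells), number of conserved elements, total sequence in
#' elements, and the count of a focal k-mer inside elements — computed
#' after restricting every genome's coverage to the regions in which all
#' methods report alignments, so the methods are compared on identical
#' ground.
#'
#' @param methodMatrices Named list (method name -> [MatchMatrix-class] or
#'   list of them, one per reference).
#' @param references Named list / DNAStringSet of reference sequences keyed
#'   by reference id (needed for the k-mer tally).
#' @param minLen,minFrac Passed to [findConservedElements()].
#' @param focalKmer k-mer whose occurrences inside elements are counted
#'   (default the poly-adenylation signal AATAAA).
#' @param restrict Apply the common-coverage restriction (default TRUE;
#'   requires >= 2 methods).
#' @return data.frame with one row per method: `method`,
#'   `matched_nucleotides`, `n_elements`, `sequence_in_elements`,
#'   `focal_kmer_count`.
#' @export
summarizeMethods <- function(methodMatrices, references, minLen = 6,
                             minFrac = 0.9, focalKmer = "AATAAA",
                             restrict = TRUE) {
  methodMatrices <- lapply(methodMatrices, function(m)
    if (is(m, "MatchMatrix")) list(m) else m)
  if (restrict) {
    if (length(methodMatrices) < 2)
      stop("common-region restriction requires >= 2 methods")
    methodMatrices <- restrictToCommonCoverage(methodMatrices)
  }
  getRef <- function(id) {
    if (is.null(names(references)) && length(references) == 1)
      return(as.character(references)[1])
    if (!id %in% names(references))
      stop("no reference sequence for id '", id, "'")
    as.character(references[[id]])[1]
  }
  rows <- lapply(names(methodMatrices), function(meth) {
    mats <- methodMatrices[[meth]]
    matched <- 0; nel <- 0L; seqin <- 0L; fk <- 0L
    for (m in mats) {
      matched <- matched + sum(m@matched)
      el <- findConservedElements(m, minLen = minLen, minFrac = minFrac)
      nel <- nel + length(el)
      seqin <- seqin + sum(IRanges::width(el))
      if (length(el) > 0) {
        kf <- kmerFrequencies(getRef(referenceId(m)), el, k = nchar(focalKmer))
        if (focalKmer %in% names(kf)) fk <- fk + kf[[focalKmer]]
      }
    }
    data.frame(method = meth, matched_nucleotides = matched,
               n_elements = nel, sequence_in_elements = seqin,
               focal_kmer_count = fk, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write conserved elements as BED
#'
#' 0-based half-open intervals on the reference, score column carrying the
#' minimum agreement.
#'
#' @param elements [IRanges::IRanges] from [findConservedElements()].
#' @param referenceId Chromosome/reference name for the BED records.
#' @param file Optional output path.
#' @return Character vector of BED lines (invisibly when written).
#' @export
elementsToBed <- function(elements, referenceId, file = NULL) {
  n <- length(elements)
  lines <- if (n == 0) character(0) else
    sprintf("%s\t%d\t%d\telement_%d\t%.4g\t+",
            referenceId, IRanges::start(elements) - 1L,
            IRanges::end(elements), seq_len(n),
            S4Vectors::mcols(elements)$minAgreement)
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}
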