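mkResult <- function(ops, tStart = 0L, targetId = "ref", queryId = "g") {
  tlen <- sum(ops$len[ops$op %in% c("M", "X", "D")])
  qlen <- sum(ops$len[ops$op %in% c("M", "X", "I")])
  mruns <- ops$len[ops$op == "M"]
  new("AlignmentResult", score = 0, targetId = targetId, queryId = queryId,
      targetInterval = c(tStart, tStart + as.integer(tlen)),
      queryInterval = c(0L, as.integer(qlen)),
      operations = ops, alignedTarget = "", alignedQuery = "",
      maxContiguity = if (length(mruns)) max(mruns) else 0L,
      identity = 0, stats = list())
}

test_that("match matrices mark covered and matched positions from operations", {
  ref <- "ACGTAC"
  mm <- buildMatchMatrix(ref, list(g1 = mkResult(data.frame(op = "M", len = 4L))))
  expect_equal(unname(mm@matched[1, ]), c(T, T, T, T, F, F))
  expect_equal(unname(mm@covered[1, ]), c(T, T, T, T, F, F))

  mm2 <- buildMatchMatrix("ACGT", list(g1 = mkResult(
    data.frame(op = c("M", "X", "M"), len = c(2L, 1L, 1L)))))
  expect_equal(unname(mm2@matched[1, ]), c(T, T, F, T))
  expect_equal(unname(mm2@covered[1, ]), c(T, T, T, T))

  # deletion in the genome: reference positions covered but not matched
  mm3 <- buildMatchMatrix("ACGT", list(g1 = mkResult(
    data.frame(op = c("M", "D", "M"), len = c(1L, 2L, 1L)))))
  expect_equal(unname(mm3@matched[1, ]), c(T, F, F, T))
  expect_equal(unname(mm3@covered[1, ]), c(T, T, T, T))

  # insertion consumes no reference position
  mm4 <- buildMatchMatrix("ACG", list(g1 = mkResult(
    data.frame(op = c("M", "I", "M"), len = c(1L, 3L, 2L)))))
  expect_equal(unname(mm4@matched[1, ]), c(T, T, T))

  expect_error(buildMatchMatrix("ACG", list(g1 = mkResult(
    data.frame(op = "M", len = 5L)))), "exceeds reference length")
  expect_error(buildMatchMatrix("ACG", stats::setNames(
    list(mkResult(data.frame(op = "M", len = 1L)),
         mkResult(data.frame(op = "M", len = 1L))), c("a", "a"))),
    "duplicate genome")
  expect_true(methods::validObject(mm))
})

test_that("agreement profiles honour the denominator choice", {
  matched <- rbind(c(T, T, F, F), c(T, F, F, F))
  covered <- rbind(c(T, T, T, F), c(T, F, F, F))
  mm <- makeMatchMatrix(matched, covered)
  expect_equal(agreementProfile(mm, "covered_genomes"), c(1, 1, 0, NA))
  expect_equal(agreementProfile(mm, "all_genomes"), c(1, 0.5, 0, 0))
})

test_that("agreement histograms normalise and difference correctly", {
  full <- makeMatchMatrix(matrix(TRUE, 2, 10), matrix(TRUE, 2, 10))
  h <- agreementHistogram(full, bins = 10)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$fraction[10], 1)               # all mass in the top bin

  d <- agreementHistogram(full, bins = 10, baseline = full)
  expect_equal(d$count, rep(0L, 10))
  expect_equal(d$fraction, rep(0, 10))

  other <- makeMatchMatrix(matrix(c(TRUE, FALSE), 2, 10), matrix(TRUE, 2, 10))
  d2 <- agreementHistogram(full, bins = 10, baseline = other)
  expect_equal(sum(d2$fraction), 0)             # same denominators cancel
  short <- makeMatchMatrix(matrix(TRUE, 2, 5), matrix(TRUE, 2, 5))
  expect_error(agreementHistogram(full, baseline = short), "different number")
})

test_that("conserved elements are maximal threshold runs", {
  profToMM <- function(p, genomes = 10) {
    matched <- vapply(p, function(pp) seq_len(genomes) <= round(pp * genomes),
                      logical(genomes))
    makeMatchMatrix(matched, matrix(TRUE, genomes, length(p)))
  }
  mm <- profToMM(c(1, 1, 1, 1, 1, 1, .5, .5))
  el <- findConservedElements(mm, minLen = 6, minFrac = 0.9)
  expect_length(el, 1)
  expect_equal(IRanges::start(el), 1)
  expect_equal(IRanges::width(el), 6)

  expect_length(findConservedElements(profToMM(rep(0.89, 12), genomes = 100),
                                      minLen = 6, minFrac = 0.9), 0)

  # exact-threshold positions belong inside elements
  mm3 <- profToMM(c(rep(1, 5), 0.9, rep(1, 5)))
  el3 <- findConservedElements(mm3, minLen = 6, minFrac = 0.9)
  expect_length(el3, 1)
  expect_equal(IRanges::width(el3), 11)
  expect_equal(S4Vectors::mcols(el3)$minAgreement, 0.9)
})

test_that("element counts shrink as thresholds tighten", {
  set.seed(59)
  matched <- matrix(stats::runif(10 * 200) < 0.93, 10, 200)
  mm <- makeMatchMatrix(matched, matrix(TRUE, 10, 200))
  # total conserved sequence can only shrink as the agreement bar rises
  # (element count need not: one long run may split into several)
  prevS <- Inf
  for (mf in c(0.5, 0.7, 0.9, 1.0)) {
    el <- findConservedElements(mm, minLen = 6, minFrac = mf)
    expect_lte(sum(IRanges::width(el)), prevS)
    prevS <- sum(IRanges::width(el))
  }
  prevN <- Inf
  for (ml in c(3, 6, 10, 20)) {
    el <- findConservedElements(mm, minLen = ml, minFrac = 0.8)
    expect_lte(length(el), prevN)
    prevN <- length(el)
  }
})

test_that("k-mer tallies slide windows inside elements only", {
  ref <- "GGAATAAAGG"
  el <- IRanges::IRanges(start = 3, end = 8)        # AATAAA
  expect_equal(kmerFrequencies(ref, el, k = 6), c(AATAAA = 1L))

  # overlapping windows in a 7-mer element: one each
  kf <- kmerFrequencies("AATAAAA", IRanges::IRanges(1, 7), k = 6)
  expect_equal(kf[["AATAAA"]], 1L)
  expect_equal(kf[["ATAAAA"]], 1L)

  # a tandem arrangement yields an overlapping double count
  kf2 <- kmerFrequencies("AATAAATAAA", IRanges::IRanges(1, 10), k = 6)
  expect_equal(kf2[["AATAAA"]], 2L)

  expect_length(kmerFrequencies("ACGTT", IRanges::IRanges(1, 5), k = 6), 0)
})

test_that("method summaries compare on common coverage", {
  matched <- matrix(TRUE, 3, 30)
  covered <- matrix(TRUE, 3, 30)
  A <- makeMatchMatrix(matched, covered)
  B <- makeMatchMatrix(matched, covered)
  refs <- stats::setNames(list(paste(rep("ACGTA", 6), collapse = "")), "ref")
  s <- summarizeMethods(list(a = A, b = B), refs)
  expect_equal(s$matched_nucleotides[1], s$matched_nucleotides[2])
  expect_equal(s$n_elements[1], s$n_elements[2])
  expect_equal(s$sequence_in_elements[1], s$sequence_in_elements[2])

  # one extra matched position inside common coverage
  m2 <- matched; m2[1, 5] <- FALSE
  A2 <- makeMatchMatrix(m2, covered)
  s2 <- summarizeMethods(list(a = A2, b = B), refs)
  expect_equal(s2$matched_nucleotides[s2$method == "b"] -
                 s2$matched_nucleotides[s2$method == "a"], 1)

  # restriction: positions one method does not cover drop out everywhere
  c3 <- covered; c3[, 21:30] <- FALSE
  C <- makeMatchMatrix(matched & c3, c3)
  s3 <- summarizeMethods(list(a = A, c = C), refs)
  expect_equal(unique(s3$matched_nucleotides), 3 * 20)
})

test_that("common-coverage restriction is idempotent and symmetric", {
  set.seed(61)
  mk <- function() {
    cov <- matrix(stats::runif(4 * 50) < 0.8, 4, 50)
    makeMatchMatrix(cov & (matrix(stats::runif(4 * 50), 4, 50) < 0.9), cov)
  }
  mats <- list(a = list(mk()), b = list(mk()))
  r1 <- restrictToCommonCoverage(mats)
  r2 <- restrictToCommonCoverage(r1)
  expect_equal(r1$a[[1]]@covered, r2$a[[1]]@covered)
  expect_equal(r1$b[[1]]@matched, r2$b[[1]]@matched)
  # symmetry: both methods end with the same coverage mask
  expect_equal(r1$a[[1]]@covered, r1$b[[1]]@covered)
})

test_that("element BED output uses 0-based half-open coordinates", {
  el <- IRanges::IRanges(start = c(3, 10), end = c(8, 15))
  S4Vectors::mcols(el) <- S4Vectors::DataFrame(minAgreement = c(1, 0.9))
  bed <- elementsToBed(el, "ref")
  f <- strsplit(bed, "\t")
  expect_equal(as.integer(f[[1]][2:3]), c(2L, 8L))
  expect_equal(as.integer(f[[2]][2:3]), c(9L, 15L))
})
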