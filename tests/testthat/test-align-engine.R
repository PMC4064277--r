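test_that("worked examples score as the recurrences dictate", {
  sp <- schemePreset("swga_plus")
  r <- alignSequences("AAAA", "AAAA", sp)
  expect_equal(alignmentScore(r), 64)            # f(4) = 4^3
  expect_equal(alignmentOperations(r),
               data.frame(op = "M", len = 4L))
  expect_equal(maxContiguity(r), 4L)
  expect_equal(alignmentIdentity(r), 1)

  # no match anywhere: the local floor is the empty alignment at 0
  r2 <- alignSequences("AAAA", "CCCC", sp)
  expect_equal(alignmentScore(r2), 0)
  expect_equal(nrow(alignmentOperations(r2)), 0)
  expect_equal(targetInterval(r2), c(0L, 0L))

  # identity alignment under linear scoring
  r3 <- alignSequences("ACGT", "ACGT", schemePreset("sw"))
  expect_equal(alignmentScore(r3), 4)
  expect_equal(alignmentOperations(r3), data.frame(op = "M", len = 4L))

  # near-identical pair agrees with the exhaustive oracle
  r4 <- alignSequences("ACACAC", "ACGCAC", sp)
  expect_equal(alignmentScore(r4), bruteForceAlign("ACACAC", "ACGCAC", sp))
})

test_that("global mode spans both sequences and charges boundary gaps", {
  g <- scoringScheme(mode = "global")
  r <- alignSequences("AC", "C", g)
  expect_equal(alignmentScore(r), -219)          # f(1) - (rho_o + rho_e)
  expect_equal(targetInterval(r), c(0L, 2L))
  expect_equal(queryInterval(r), c(0L, 1L))
  for (k in 1:20) {
    t <- randomSequence(sample(2:25, 1), 6000 + k)
    q <- randomSequence(sample(2:25, 1), 6100 + k)
    rr <- alignSequences(t, q, g)
    expect_equal(targetInterval(rr), c(0L, nchar(t)))
    expect_equal(queryInterval(rr), c(0L, nchar(q)))
  }
})

test_that("computeCell implements the cell recurrences", {
  sp <- schemePreset("swga_plus")
  b <- boundaryCell(sp)

  # first cell of a run: depth node 1 scores deltaF(1) from the restart
  c1 <- computeCell(b, b, b, TRUE, sp)
  expect_equal(c1@depth, 1L)
  expect_equal(c1@best, 1)                       # deltaF(1) = 1
  expect_equal(c1@depthScores, c(0, 1))

  # mismatch arrival: predecessor best minus rho_m
  pd <- new("CellState", best = 10, depthScores = 10, gapH = -Inf,
            gapV = -Inf, depth = 0L)
  c2 <- computeCell(pd, boundaryCell(sp), boundaryCell(sp), FALSE, sp)
  expect_equal(c2@depthScores[1], 2)             # 10 - 8
  expect_equal(c2@depth, 0L)

  # gap continuation vs opening: max(100 - 20, 130 - 220) = 80
  pl <- new("CellState", best = 130, depthScores = 130, gapH = 100,
            gapV = -Inf, depth = 0L)
  c3 <- computeCell(boundaryCell(sp), boundaryCell(sp), pl, FALSE, sp)
  expect_equal(c3@gapH, 80)

  # depth chain: node n = prev node n-1 + deltaF(n)
  c4 <- computeCell(c1, b, b, TRUE, sp)
  expect_equal(c4@depth, 2L)
  expect_equal(max(c4@depthScores), 8)           # f(2)
})

test_that("engine and computeCell-based fill agree cell for cell", {
  set.seed(31)
  for (k in 1:12) {
    t <- randomSequence(sample(1:6, 1), 300 + k)
    q <- randomSequence(sample(1:6, 1), 400 + k)
    for (nm in c("sw", "swga_plus")) for (md in c("local", "global")) {
      s <- presetWithMode(nm, md)
      expect_equal(alignmentScore(alignSequences(t, q, s)),
                   referenceFillScore(t, q, s),
                   info = paste(t, q, nm, md))
    }
  }
})

test_that("engine equals the exhaustive oracle on random small pairs", {
  set.seed(17)
  for (k in 1:60) {
    t <- randomSequence(sample(1:8, 1), 2 * k)
    q <- randomSequence(sample(1:8, 1), 2 * k + 1)
    for (nm in presetNames) for (md in c("local", "global")) {
      s <- presetWithMode(nm, md)
      expect_equal(alignmentScore(alignSequences(t, q, s)),
                   bruteForceAlign(t, q, s),
                   info = paste(t, q, nm, md))
    }
  }
})

test_that("depth-capped schemes still match the oracle", {
  s <- scoringScheme(cubicScoring(), depthCap = 2)
  for (k in 1:25) {
    t <- randomSequence(7, 900 + k)
    q <- randomSequence(7, 950 + k)
    expect_equal(alignmentScore(alignSequences(t, q, s)),
                 bruteForceAlign(t, q, s), info = paste(t, q))
  }
})

test_that("alignment score is symmetric with transposed gap operations", {
  set.seed(23)
  for (k in 1:20) {
    t <- randomSequence(sample(3:30, 1), 500 + k)
    q <- randomSequence(sample(3:30, 1), 600 + k)
    for (nm in c("sw", "swga_plus")) {
      s <- schemePreset(nm)
      a <- alignSequences(t, q, s)
      b <- alignSequences(q, t, s)
      expect_equal(alignmentScore(a), alignmentScore(b))
      opsT <- alignmentOperations(b)
      opsT$op <- chartr("ID", "DI", opsT$op)
      expect_equal(rescoreAlignment(opsT, s),
                   rescoreAlignment(alignmentOperations(a), s))
    }
  }
})

test_that("local score dominates both zero and the global score", {
  set.seed(29)
  for (k in 1:25) {
    t <- randomSequence(sample(2:25, 1), 700 + k)
    q <- randomSequence(sample(2:25, 1), 800 + k)
    for (nm in presetNames) {
      loc <- alignmentScore(alignSequences(t, q, presetWithMode(nm, "local")))
      glo <- alignmentScore(alignSequences(t, q, presetWithMode(nm, "global")))
      expect_gte(loc, 0)
      expect_gte(loc, glo)
    }
  }
})

test_that("appending a common suffix never lowers the local score", {
  set.seed(37)
  sp <- schemePreset("swga_plus")
  for (k in 1:20) {
    t <- randomSequence(sample(4:20, 1), 100 + k)
    q <- randomSequence(sample(4:20, 1), 200 + k)
    sfx <- randomSequence(sample(2:6, 1), 300 + k)
    s0 <- alignmentScore(alignSequences(t, q, sp))
    s1 <- alignmentScore(alignSequences(paste0(t, sfx), paste0(q, sfx), sp))
    expect_gte(s1, s0)
  }
  # when the optimum already ends at the sequence ends, a suffix of s
  # identical bases adds at least the run's full delta-f sum
  s0 <- alignmentScore(alignSequences("ACGT", "ACGT", sp))
  s1 <- alignmentScore(alignSequences("ACGTAA", "ACGTAA", sp))
  expect_gte(s1 - s0, evaluateF(cubicScoring(), 2))
})

test_that("rescoring engine operations reproduces every reported score", {
  set.seed(41)
  for (k in 1:30) {
    t <- randomSequence(sample(5:50, 1), 1000 + k)
    q <- randomSequence(sample(5:50, 1), 2000 + k)
    for (nm in presetNames) for (md in c("local", "global")) {
      s <- presetWithMode(nm, md)
      a <- alignSequences(t, q, s)
      expect_equal(rescoreAlignment(a, s), alignmentScore(a),
                   info = paste(nm, md))
    }
  }
  # hand-built run lists against closed forms
  sp <- schemePreset("swga_plus")
  expect_equal(rescoreAlignment(data.frame(op = "M", len = 4L), sp), 64)
  expect_equal(rescoreAlignment(
    data.frame(op = c("M", "X", "M"), len = c(2L, 1L, 2L)), sp), 8)
  expect_equal(rescoreAlignment(
    data.frame(op = c("M", "I"), len = c(3L, 1L)), sp), 27 - 220)
  expect_error(rescoreAlignment(data.frame(op = "Z", len = 1L), sp),
               "malformed")
})

test_that("depth allocation is economical", {
  # a linear function needs exactly one depth node per cell
  for (nm in c("sw", "swga")) {
    r <- alignSequences(randomSequence(50, 5), randomSequence(50, 6),
                        schemePreset(nm))
    expect_equal(engineStats(r)$maxDepthNodes, 1)
  }
  # nonlinear: allocation tracks the realised contiguity depth
  r <- alignSequences("AAAAA", "AAAAA", schemePreset("swga_plus"))
  expect_equal(engineStats(r)$maxDepthNodes, 5)
  expect_lte(engineStats(r)$maxDepthNodes, maxContiguity(r) + 1)
})

test_that("input validation names the offence", {
  sp <- schemePreset("swga_plus")
  expect_error(alignSequences("", "ACGT", sp), "empty")
  expect_error(alignSequences("ACGT", "", sp), "empty")
  expect_error(alignSequences("ACGU", "ACGT", sp), "position 4")
  expect_error(alignSequences("ACGT", "ACRT", sp), "'R'")
  # lowercase is accepted and uppercased; N never matches, even N vs N
  expect_equal(alignmentScore(alignSequences("acgt", "ACGT", sp)), 64)
  expect_equal(alignmentScore(alignSequences("NNNN", "NNNN", sp)), 0)
  expect_equal(alignmentScore(alignSequences("ANA", "ANA", sp)),
               alignmentScore(alignSequences("ATA", "AGA", sp)))
})

test_that("AlignmentResult bookkeeping is internally consistent", {
  set.seed(43)
  for (k in 1:15) {
    t <- randomSequence(sample(5:40, 1), 3000 + k)
    q <- randomSequence(sample(5:40, 1), 4000 + k)
    a <- alignSequences(t, q, schemePreset("swga_plus"))
    ops <- alignmentOperations(a)
    expect_equal(sum(ops$len[ops$op %in% c("M", "X", "D")]),
                 diff(targetInterval(a)))
    expect_equal(sum(ops$len[ops$op %in% c("M", "X", "I")]),
                 diff(queryInterval(a)))
    expect_equal(nchar(alignedTarget(a)), sum(ops$len))
    expect_equal(nchar(alignedQuery(a)), sum(ops$len))
    expect_true(methods::validObject(a))
  }
})
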