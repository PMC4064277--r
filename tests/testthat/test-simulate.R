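test_that("random sequences are deterministic and roughly uniform", {
  expect_identical(randomSequence(5, 99), randomSequence(5, 99))
  expect_false(identical(randomSequence(50, 1), randomSequence(50, 2)))
  expect_true(randomSequence(1, 7) %in% c("A", "C", "G", "T"))
  s <- randomSequence(10000, 123)
  freq <- table(strsplit(s, "")[[1]]) / 10000
  expect_true(all(freq > 0.22 & freq < 0.28))
  expect_error(randomSequence(0, 1), ">= 1")
  # global RNG state is untouched
  set.seed(555); before <- .Random.seed
  invisible(randomSequence(10, 9))
  expect_identical(.Random.seed, before)
})

test_that("an undiverged family is a set of perfect copies", {
  fam <- simulateFamily(refLength = 120, nGenomes = 4, nMotifs = 2,
                        flankSubRate = 0, flankIndelRate = 0,
                        motifSubRate = 0, seed = 5)
  ref <- unname(fam$reference)
  expect_true(all(as.character(fam$orthologs) == ref))
  expect_true(all(fam$preserved))
  expect_length(fam$motifs, 2)
  # motifs are planted verbatim, non-overlapping, a motif length apart
  for (i in seq_along(fam$motifs))
    expect_equal(substr(ref, IRanges::start(fam$motifs)[i],
                        IRanges::end(fam$motifs)[i]), "AATAAA")
  expect_true(all(diff(IRanges::start(fam$motifs)) >= 12))
})

test_that("rate boundaries behave as stated", {
  fam <- simulateFamily(refLength = 100, nGenomes = 2, nMotifs = 2,
                        flankSubRate = 1, flankIndelRate = 0,
                        motifSubRate = 0, seed = 8)
  ref <- strsplit(unname(fam$reference), "")[[1]]
  inMotif <- logical(100)
  for (i in seq_along(fam$motifs))
    inMotif[IRanges::start(fam$motifs)[i]:IRanges::end(fam$motifs)[i]] <- TRUE
  for (g in 1:2) {
    ort <- strsplit(as.character(fam$orthologs[[g]]), "")[[1]]
    expect_length(ort, 100)                  # no indels planted
    expect_true(all(ort[!inMotif] != ref[!inMotif]))
    expect_true(all(ort[inMotif] == ref[inMotif]))
  }
  expect_error(simulateFamily(flankSubRate = 1.2, seed = 1), "rates")
  expect_error(simulateFamily(refLength = 20, nMotifs = 3, seed = 1),
               "at least")
})

test_that("families are bitwise reproducible from their seed", {
  a <- simulateFamily(refLength = 300, nGenomes = 10, nMotifs = 3,
                      flankSubRate = 0.3, flankIndelRate = 0.02,
                      motifSubRate = 0.01, seed = 7)
  b <- simulateFamily(refLength = 300, nGenomes = 10, nMotifs = 3,
                      flankSubRate = 0.3, flankIndelRate = 0.02,
                      motifSubRate = 0.01, seed = 7)
  expect_identical(a$reference, b$reference)
  expect_identical(as.character(a$orthologs), as.character(b$orthologs))
  expect_identical(a$motifs, b$motifs)
  expect_identical(a$preserved, b$preserved)
  d <- simulateFamily(seed = 8)
  expect_false(identical(unname(a$reference), unname(d$reference)))
})

test_that("preserved flags track substitutions and indels hitting motifs", {
  fam <- simulateFamily(refLength = 200, nGenomes = 30, nMotifs = 2,
                        flankSubRate = 0.2, flankIndelRate = 0.05,
                        motifSubRate = 0.5, seed = 21)
  # a genome whose motif is flagged preserved carries it verbatim
  for (g in seq_len(30)) {
    ort <- as.character(fam$orthologs[[g]])
    for (m in seq_along(fam$motifs)) {
      if (fam$preserved[g, m])
        expect_true(grepl("AATAAA", ort, fixed = TRUE))
    }
  }
  # at motifSubRate 0.5 over 6 positions most copies are hit
  expect_lt(mean(fam$preserved), 0.5)
})

test_that("brute force enumeration reproduces closed-form path scores", {
  sp <- schemePreset("swga_plus")
  expect_equal(bruteForceAlign("AC", "AC", sp), 8)          # f(2)
  expect_equal(bruteForceAlign("A", "C", sp), 0)            # empty beats -8
  g <- scoringScheme(mode = "global")
  expect_equal(bruteForceAlign("AC", "C", g), -219)         # f(1) - 220
  expect_error(bruteForceAlign(randomSequence(11, 1), randomSequence(10, 2),
                               sp), "guard")
})

test_that("a pristine family feeds through to full motif recovery", {
  fam <- simulateFamily(refLength = 150, nGenomes = 5, nMotifs = 3,
                        flankSubRate = 0, flankIndelRate = 0,
                        motifSubRate = 0, seed = 33)
  mm <- familyMatchMatrix(fam$reference, fam$orthologs,
                          schemePreset("swga_plus"))
  el <- findConservedElements(mm, minLen = 6, minFrac = 1.0)
  expect_equal(countRecoveredMotifs(el, fam$motifs), 3L)
  # perfect copies: the whole reference is one conserved element
  expect_equal(sum(IRanges::width(el)), 150)
})
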