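# shared fixtures for the test suite: every fixture is built in code

presetNames <- c("sw", "swga", "sw_plus", "swga_plus")

presetWithMode <- function(name, mode) {
  s <- schemePreset(name)
  s@mode <- mode
  s
}

# all 4^L sequences of length L over ACGT
allSequences <- function(L) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)), 1,
        paste, collapse = "")
}

# a reference full-matrix fill built on computeCell (R, slow, tiny inputs
# only); independent of the compiled engine's code path
referenceFillScore <- function(t, q, scheme) {
  N <- nchar(t); M <- nchar(q)
  tb <- strsplit(t, "")[[1]]; qb <- strsplit(q, "")[[1]]
  local <- alignmentMode(scheme) == "local"
  unreachable <- new("CellState", best = -Inf, depthScores = -Inf,
                     gapH = -Inf, gapV = -Inf, depth = 0L)
  origin <- new("CellState", best = 0, depthScores = 0, gapH = -Inf,
                gapV = -Inf, depth = 0L)
  rows <- vector("list", N + 1)
  row0 <- vector("list", M + 1)
  row0[[1]] <- origin
  for (j in seq_len(M))
    row0[[j + 1]] <- if (local) origin else
      computeCell(unreachable, unreachable, row0[[j]], FALSE, scheme)
  rows[[1]] <- row0
  for (i in seq_len(N)) {
    cur <- vector("list", M + 1)
    cur[[1]] <- if (local) origin else
      computeCell(unreachable, rows[[i]][[1]], unreachable, FALSE, scheme)
    for (j in seq_len(M)) {
      isMatch <- tb[i] == qb[j] && tb[i] != "N"
      cur[[j + 1]] <- computeCell(rows[[i]][[j]], rows[[i]][[j + 1]],
                                  cur[[j]], isMatch, scheme)
    }
    rows[[i + 1]] <- cur
  }
  if (local) {
    max(0, vapply(rows, function(r) max(vapply(r, function(c) c@best,
                                               numeric(1))), numeric(1)))
  } else {
    rows[[N + 1]][[M + 1]]@best
  }
}

writeTempFasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", unname(seqs)), path)
  path
}

# a MatchMatrix built directly from masks (rows = genomes)
makeMatchMatrix <- function(matched, covered, referenceId = "ref") {
  ids <- sprintf("g%d", seq_len(nrow(matched)))
  dimnames(matched) <- list(ids, NULL)
  dimnames(covered) <- list(ids, NULL)
  new("MatchMatrix", referenceId = referenceId,
      matched = matched, covered = covered)
}
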