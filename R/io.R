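#' @include align.R
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom utils read.delim write.table
NULL

#' Read a nucleotide FASTA file
#'
#' Standard FASTA parsing (wrapped lines joined, sequences uppercased) with
#' strict validation: record ids must be non-empty and unique, records must
#' have non-empty sequences, and only the A, C, G, T, N alphabet is
#' accepted (other IUPAC ambiguity codes have no defined match semantics
#' under contiguity scoring and are rejected).
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with record descriptions (the
#'   header text after the first whitespace) in `mcols(x)$description`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("failed to parse FASTA '", path,
                                         "': ", conditionMessage(e)))
  if (length(x) == 0) stop("no records in FASTA file: ", path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(ids)))
    stop("record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[anyDuplicated(ids)], "' in ", path)
  empty <- Biostrings::width(x) == 0
  if (any(empty))
    stop("empty record '", ids[which(empty)[1]], "' in ", path)
  seqs <- toupper(as.character(x))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop("record '", ids[k], "' contains unsupported character '",
         substr(seqs[k], bad[k], bad[k]), "' at position ", bad[k],
         " (alphabet is A, C, G, T, N)")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

tsvColumns <- c("target_id", "query_id", "score", "t_start", "t_end",
                "q_start", "q_end", "identity", "max_contiguity", "cigar")

resultToTsvRow <- function(result) {
  data.frame(target_id = result@targetId, query_id = result@queryId,
             score = result@score,
             t_start = result@targetInterval[1],
             t_end = result@targetInterval[2],
             q_start = result@queryInterval[1],
             q_end = result@queryInterval[2],
             identity = result@identity,
             max_contiguity = result@maxContiguity,
             cigar = cigarString(result),
             stringsAsFactors = FALSE)
}

formatTextBlock <- function(result, width = 60) {
  cols <- rep(result@operations$op, result@operations$len)
  bars <- c(M = "|", X = ".", I = " ", D = " ")[cols]
  at <- strsplit(result@alignedTarget, "")[[1]]
  aq <- strsplit(result@alignedQuery, "")[[1]]
  out <- c(sprintf("# %s [%d,%d) vs %s [%d,%d)  score=%g identity=%.3f max_contiguity=%d",
                   result@targetId, result@targetInterval[1],
                   result@targetInterval[2], result@queryId,
                   result@queryInterval[1], result@queryInterval[2],
                   result@score, result@identity, result@maxContiguity))
  if (length(cols) == 0)
    return(c(out, "# (empty alignment)"))
  tpos <- result@targetInterval[1]
  qpos <- result@queryInterval[1]
  for (off in seq(1, length(cols), by = width)) {
    idx <- off:min(off + width - 1, length(cols))
    tseg <- at[idx]; qseg <- aq[idx]
    tadv <- sum(tseg != "-"); qadv <- sum(qseg != "-")
    out <- c(out,
      sprintf("T %8d %s", tpos, paste(tseg, collapse = "")),
      sprintf("  %8s %s", "", paste(bars[idx], collapse = "")),
      sprintf("Q %8d %s", qpos, paste(qseg, collapse = "")),
      "")
    tpos <- tpos + tadv
    qpos <- qpos + qadv
  }
  out
}

#' Format or write an alignment result
#'
#' Three output formats: `"text"` (human-readable pairwise block with match
#' bars, wrapped at 60 columns), `"tsv"` (one row with fixed columns
#' target_id, query_id, score, t_start, t_end, q_start, q_end, identity,
#' max_contiguity, cigar; intervals 0-based half-open), and `"cigar"`
#' (compact run-length string over M/X/I/D, X kept distinct from M so match
#' contiguity is recoverable).
#'
#' @param result An [AlignmentResult-class].
#' @param format One of `"text"`, `"tsv"`, `"cigar"`.
#' @param file Optional path; when given the text is also written there.
#' @param header For `"tsv"`: include the header line (default TRUE).
#' @return The formatted text as a character vector, invisibly when `file`
#'   is given.
#' @export
writeAlignment <- function(result, format = c("text", "tsv", "cigar"),
                           file = NULL, header = TRUE) {
  format <- match.arg(format)
  txt <- switch(format,
    cigar = cigarString(result),
    text = formatTextBlock(result),
    tsv = {
      row <- resultToTsvRow(result)
      body <- paste(vapply(tsvColumns, function(cn) as.character(row[[cn]]), ""),
                    collapse = "\t")
      if (header) c(paste(tsvColumns, collapse = "\t"), body) else body
    })
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# write many results as one TSV
writeAlignmentsTsv <- function(results, file = NULL) {
  rows <- do.call(rbind, lapply(results, resultToTsvRow))
  txt <- c(paste(tsvColumns, collapse = "\t"),
           vapply(seq_len(nrow(rows)), function(i)
             paste(vapply(tsvColumns, function(cn) as.character(rows[i, cn]), ""),
                   collapse = "\t"), ""))
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

parseCigar <- function(cigar) {
  if (cigar == "*" || !nzchar(cigar))
    return(data.frame(op = character(), len = integer(),
                      stringsAsFactors = FALSE))
  m <- gregexpr("[0-9]+[MXID]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MXID]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1, nchar(toks) - 1)),
             stringsAsFactors = FALSE)
}

#' Read alignment results from an engine TSV
#'
#' Reconstructs [AlignmentResult-class] objects (operations from the CIGAR
#' column; gapped renderings are left empty) from a TSV written by
#' [writeAlignment()] / the `align` subcommand, e.g. to feed the
#' consistency metrics.
#'
#' @param path TSV path.
#' @return A list of [AlignmentResult-class].
#' @export
readAlignmentTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(tsvColumns, names(tab))
  if (length(missing))
    stop("TSV ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    ops <- parseCigar(tab$cigar[i])
    mruns <- ops$len[ops$op == "M"]
    new("AlignmentResult",
        score = tab$score[i],
        targetId = tab$target_id[i], queryId = tab$query_id[i],
        targetInterval = as.integer(c(tab$t_start[i], tab$t_end[i])),
        queryInterval = as.integer(c(tab$q_start[i], tab$q_end[i])),
        operations = ops,
        alignedTarget = "", alignedQuery = "",
        maxContiguity = if (length(mruns)) max(mruns) else 0L,
        identity = tab$identity[i],
        stats = list())
  })
}
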