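#' @importFrom data.table fread fwrite setnames as.data.table setkeyv :=
NULL

ALN_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
.ALN_NUM <- ALN_COLS[3:12]

#' Normalize a table of pairwise alignment hits
#'
#' Canonical form: `qstart <= qend` and `sstart <= send`; hits whose
#' subject coordinates arrived reversed are flipped and flagged in the
#' logical column `subject_reversed`. Re-normalizing a normalized table is
#' a no-op (the flag is preserved, not toggled).
#'
#' @param hits data.frame with the 12 standard tabular-alignment columns
#'   (plus optionally `subject_reversed`).
#' @return the normalized data.frame, with `subject_reversed` present.
#' @export
normalizeAlignmentHits <- function(hits) {
  hits <- as.data.frame(hits)
  missing <- setdiff(ALN_COLS, names(hits))
  if (length(missing))
    stop("alignment table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(hits$subject_reversed))
    hits$subject_reversed <- FALSE
  flip <- hits$sstart > hits$send
  if (any(flip)) {
    tmp <- hits$sstart[flip]
    hits$sstart[flip] <- hits$send[flip]
    hits$send[flip] <- tmp
    hits$subject_reversed[flip] <- TRUE
  }
  qflip <- hits$qstart > hits$qend
  if (any(qflip)) {
    tmp <- hits$qstart[qflip]
    hits$qstart[qflip] <- hits$qend[qflip]
    hits$qend[qflip] <- tmp
  }
  if (nrow(hits) && (any(hits$pident < 0) || any(hits$pident > 100)))
    stop("pident outside [0, 100]")
  hits
}

#' Read a 12-column tabular alignment file
#'
#' Parses the tab-separated alignment dialect produced with
#' `-outfmt 6` (query, subject, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, e-value, bitscore).
#' Coordinates are normalized via [normalizeAlignmentHits()]; short rows
#' and non-numeric coordinates are hard errors naming the offending line.
#'
#' @param path path to the tab-separated file.
#' @return data.frame of normalized hits with a `subject_reversed` column.
#' @export
readAlignmentTable <- function(path) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", fill = TRUE,
                           data.table = TRUE)
  if (nrow(raw) == 0L)
    return(normalizeAlignmentHits(emptyAlignmentTable()))
  if (ncol(raw) < 12L) {
    nf <- lengths(strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE))
    stop(sprintf("alignment table %s: line %d has %d column(s), expected >= 12",
                 path, which(nf < 12L)[1L], min(nf)))
  }
  short <- which(raw[[12L]] == "" | is.na(raw[[12L]]))
  if (length(short))
    stop(sprintf("alignment table %s: line %d has fewer than 12 columns",
                 path, short[1L]))
  df <- as.data.frame(raw[, 1:12])
  names(df) <- ALN_COLS
  for (col in .ALN_NUM) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("alignment table %s: non-numeric '%s' in column %s, line %d",
                   path, df[[col]][bad[1L]], col, bad[1L]))
    df[[col]] <- val
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")
  for (col in int_cols) df[[col]] <- as.integer(round(df[[col]]))
  normalizeAlignmentHits(df)
}

#' Write alignment hits as a 12-column tab-separated table
#'
#' Rows flagged `subject_reversed` are written with their original
#' (descending) subject orientation so that write-then-read round-trips.
#'
#' @param hits data.frame of (normalized) alignment hits.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentTable <- function(hits, path) {
  hits <- normalizeAlignmentHits(hits)
  out <- hits[, ALN_COLS]
  rev <- hits$subject_reversed
  if (any(rev)) {
    tmp <- out$sstart[rev]
    out$sstart[rev] <- out$send[rev]
    out$send[rev] <- tmp
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build an alignment-hit table in code
#'
#' Convenience constructor used by the simulator and the test suite;
#' fills the bookkeeping columns with consistent defaults and normalizes.
#'
#' @param qseqid,sseqid,qstart,qend,sstart,send,pident vectors (recycled).
#' @param length alignment length; defaults to the query span.
#' @param mismatch,gapopen,evalue,bitscore optional columns.
#' @return normalized data.frame of hits.
#' @export
alignmentHits <- function(qseqid, sseqid, pident, qstart, qend, sstart, send,
                          length = NULL, mismatch = 0L, gapopen = 0L,
                          evalue = 1e-50, bitscore = 100) {
  if (is.null(length)) length <- abs(qend - qstart) + 1L
  df <- data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
                   length = as.integer(length), mismatch = as.integer(mismatch),
                   gapopen = as.integer(gapopen),
                   qstart = as.integer(qstart), qend = as.integer(qend),
                   sstart = as.integer(sstart), send = as.integer(send),
                   evalue = evalue, bitscore = bitscore,
                   stringsAsFactors = FALSE)
  normalizeAlignmentHits(df)
}

#' @rdname alignmentHits
#' @return `emptyAlignmentTable()`: a zero-row hit table.
#' @export
emptyAlignmentTable <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}
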