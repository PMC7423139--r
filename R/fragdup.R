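#' Keep alignment rows whose query is a reference protein
#'
#' @param hits all-vs-all protein alignment hits.
#' @param referenceIds character set of reference protein ids.
#' @return the subset of `hits` with `qseqid` in `referenceIds`, order
#'   preserved.
#' @export
filterReferenceQueries <- function(hits, referenceIds) {
  hits[hits$qseqid %in% referenceIds, , drop = FALSE]
}

#' Remove duplicate alignment rows
#'
#' Byte-identical rows collapse to one; among rows identical in
#' (query, subject, qstart, qend, sstart, send) only the highest-bitscore
#' row survives.
#'
#' @param hits normalized alignment hits.
#' @return deduplicated hits.
#' @export
dedupeHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- c("qseqid", "sseqid", "qstart", "qend", "sstart", "send")
  o <- order(hits$qseqid, hits$sseqid, hits$qstart, hits$qend,
             hits$sstart, hits$send, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[, key])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify paralogous reference proteins from reference self-alignments
#'
#' Any reference protein appearing as query or subject of a non-self hit
#' is a paralog-family member; both endpoints are excluded (symmetric
#' exclusion) so neither partner's assembly matches can be misread as
#' assembly duplications.
#'
#' @param referenceSelfHits hits where both query and subject are
#'   reference proteins.
#' @return character vector of paralogous reference ids.
#' @export
identifyParalogs <- function(referenceSelfHits) {
  ns <- referenceSelfHits[referenceSelfHits$qseqid !=
                          referenceSelfHits$sseqid, , drop = FALSE]
  sort(unique(c(ns$qseqid, ns$sseqid)))
}

#' Classify the matches of one reference protein
#'
#' Single-linkage clusters the query-side (reference protein) intervals
#' of the matches by overlap. With N matches in C clusters: duplication
#' events = N - C (for K mutually overlapping matches, K - 1 duplicates
#' plus one correct match — deliberately conservative), fragmentation
#' case = 1 if C > 1, one-to-one = 1 if N == 1. The two pure textbook
#' cases fall out directly: overlapping matches are N - 1 duplications
#' plus 1 correct match; non-overlapping matches are a fragmentation
#' case with 0 duplications.
#'
#' @param matches normalized hits sharing one query (reference protein)
#'   from one test assembly.
#' @param minOverlapFrac minimum overlap as a fraction of the shorter
#'   interval for two matches to cluster (default 0: any shared
#'   position counts).
#' @return list with `one_to_one` (0/1), `fragmentation_case` (0/1),
#'   `duplication_events`, `n_matches`, `n_clusters`.
#' @export
classifyMatches <- function(matches, minOverlapFrac = 0) {
  if (nrow(matches) == 0L) stop("classifyMatches needs at least one match")
  if (length(unique(matches$qseqid)) != 1L)
    stop("matches must share one reference protein (query)")
  o <- order(matches$qstart, matches$qend)
  qs <- matches$qstart[o]; qe <- matches$qend[o]
  n <- length(qs)
  clusters <- 1L
  cur_end <- qe[1L]
  if (n > 1L) for (i in 2:n) {
    ov <- cur_end - qs[i] + 1L
    need <- max(1, minOverlapFrac * min(qe[i] - qs[i] + 1L,
                                        cur_end - qs[i - 1L] + 1L))
    if (ov >= need) {
      cur_end <- max(cur_end, qe[i])
    } else {
      clusters <- clusters + 1L
      cur_end <- qe[i]
    }
  }
  list(one_to_one = as.integer(n == 1L),
       fragmentation_case = as.integer(clusters > 1L),
       duplication_events = n - clusters,
       n_matches = n, n_clusters = clusters)
}

#' Tally fragmentation and duplication for one test assembly
#'
#' Screens out paralogous reference proteins and self-matches, groups the
#' remaining rows by reference protein and sums the per-protein
#' classifier outputs. Per-protein raw counts (N matches, C clusters) are
#' returned alongside so either the case or the event counting
#' convention is recoverable.
#'
#' @param hits deduplicated, reference-query-filtered hits of one test
#'   assembly against the reference proteins.
#' @param referenceIds character set of reference protein ids.
#' @param paralogs character set from [identifyParalogs()].
#' @param label assembly label for the output row.
#' @param minOverlapFrac passed to [classifyMatches()].
#' @return list with `counts` (one-row data.frame: `assembly_label`,
#'   `one_to_one`, `fragmentation_cases`, `duplication_events`,
#'   `excluded_paralogs`, `n_proteins_matched`) and `perProtein`.
#' @export
tallyAssembly <- function(hits, referenceIds, paralogs = character(0),
                          label = "assembly", minOverlapFrac = 0) {
  hits <- filterReferenceQueries(hits, referenceIds)
  n_par <- length(intersect(unique(hits$qseqid), paralogs))
  hits <- hits[!hits$qseqid %in% paralogs, , drop = FALSE]
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  per <- list()
  for (pid in unique(hits$qseqid)) {
    cl <- classifyMatches(hits[hits$qseqid == pid, , drop = FALSE],
                          minOverlapFrac)
    per[[length(per) + 1L]] <- data.frame(
      protein = pid, n_matches = cl$n_matches, n_clusters = cl$n_clusters,
      one_to_one = cl$one_to_one,
      fragmentation_case = cl$fragmentation_case,
      duplication_events = cl$duplication_events, stringsAsFactors = FALSE)
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(protein = character(), n_matches = integer(),
               n_clusters = integer(), one_to_one = integer(),
               fragmentation_case = integer(),
               duplication_events = integer(), stringsAsFactors = FALSE)
  counts <- data.frame(
    assembly_label = label,
    one_to_one = sum(per$one_to_one),
    fragmentation_cases = sum(per$fragmentation_case),
    duplication_events = sum(per$duplication_events),
    excluded_paralogs = n_par,
    n_proteins_matched = nrow(per), stringsAsFactors = FALSE)
  list(counts = counts, perProtein = per)
}
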