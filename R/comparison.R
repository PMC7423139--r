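#' @importFrom GenomicRanges GRanges reduce
#' @importFrom IRanges IRanges
NULL

#' Percent of a reference with no qualifying alignment
#'
#' Merges the subject-side intervals of all hits at least
#' `minAlnLength` long and reports the uncovered fraction of the
#' reference as a percentage. Coverage is a property of the reference:
#' hits from different query contigs onto the same reference span count
#' once. No identity threshold is applied (any qualifying hit counts).
#'
#' @param hits normalized alignment hits onto the reference (subject side).
#' @param reference the reference [AssemblySeqs-class].
#' @param minAlnLength minimum alignment length in bp (default 24, the
#'   floor a local aligner with short seeds admits).
#' @return percent of reference bp without alignment, in `[0, 100]`.
#' @export
percentMissing <- function(hits, reference, minAlnLength = 24L) {
  total <- sum(Biostrings::width(reference))
  hits <- hits[hits$length >= minAlnLength, , drop = FALSE]
  if (nrow(hits) == 0L) return(100)
  unknown <- setdiff(unique(hits$sseqid), names(reference))
  if (length(unknown))
    stop("hit onto contig absent from the reference: '", unknown[1L], "'")
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  send <- pmin(hits$send, lens[hits$sseqid])
  sstart <- pmax(hits$sstart, 1L)
  covered <- GenomicRanges::reduce(GenomicRanges::GRanges(
    hits$sseqid, IRanges::IRanges(sstart, send)))
  100 * (total - sum(BiocGenerics::width(covered))) / total
}

#' Expansion accounting from totals and the missing fraction
#'
#' The expanded excess is the assembly length beyond what the recovered
#' part of the reference accounts for:
#' `excess = assembly_total - (1 - missing) * reference_total`. It is
#' reported both as a percent of the reference (the "excess over
#' reference" figure) and as a percent of the assembly itself (the share
#' of the assembly consisting of expanded sequence). A net-deficit
#' assembly (negative excess) reports 0 for both, flagged.
#'
#' @param assemblyTotal,referenceTotal total lengths in bp (positive).
#' @param missingFraction fraction of the reference missing from the
#'   assembly, in `[0, 1]` (see [percentMissing()]).
#' @return list with `percent_of_assembly`, `percent_excess_over_reference`
#'   and logical `net_deficit`.
#' @examples
#' # half again the reference with 10% missing: 40% of the assembly is
#' # expanded sequence, a 60% excess over the reference
#' percentExpanded(150, 100, 0.10)
#' @export
percentExpanded <- function(assemblyTotal, referenceTotal, missingFraction) {
  if (assemblyTotal <= 0 || referenceTotal <= 0)
    stop("totals must be positive")
  if (missingFraction < 0 || missingFraction > 1)
    stop("missingFraction must be in [0, 1]")
  excess <- assemblyTotal - (1 - missingFraction) * referenceTotal
  if (excess < 0)
    return(list(percent_of_assembly = 0,
                percent_excess_over_reference = 0, net_deficit = TRUE))
  list(percent_of_assembly = 100 * excess / assemblyTotal,
       percent_excess_over_reference = 100 * excess / referenceTotal,
       net_deficit = FALSE)
}

#' Fold change of a reference region set over its assembly counterpart
#'
#' Reference bp divided by assembly bp: values above 1 indicate
#' contraction of the region in the assembly. Output tables report it to
#' 2 decimals.
#'
#' @param referenceBp,assemblyBp unique aligned bp on each side (positive).
#' @return the fold value (full precision; round for display).
#' @examples
#' round(foldChange(153958, 43083), 2)  # 3.57
#' @export
foldChange <- function(referenceBp, assemblyBp) {
  if (assemblyBp == 0) stop("assembly bp is zero; fold change undefined")
  if (referenceBp <= 0 || assemblyBp < 0) stop("bp totals must be positive")
  referenceBp / assemblyBp
}
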