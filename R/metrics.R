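#' Filter an assembly by minimum sequence length
#'
#' The cutoff is inclusive: sequences of length `>= cutoff` are kept (the
#' usual assembly-stats convention), order preserved.
#'
#' @param seqs an [AssemblySeqs-class] object.
#' @param cutoff minimum length in bp (>= 0).
#' @return the filtered [AssemblySeqs-class].
#' @export
filterByLength <- function(seqs, cutoff) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  assemblySeqs(seqs[Biostrings::width(seqs) >= cutoff],
               label = seqLabel(seqs))
}

#' Compute the N50 of a set of sequence lengths
#'
#' The N50 is the length L, itself a member of the input, such that
#' sequences of length >= L sum to at least half the total. Ties are
#' resolved by a descending scan that stops as soon as the cumulative sum
#' reaches half the total (>=, not >).
#'
#' @param lengths numeric vector of positive sequence lengths.
#' @return the N50 in bp.
#' @examples
#' computeN50(c(2, 3, 4, 5, 6))  # 5
#' @export
computeN50 <- function(lengths) {
  if (length(lengths) == 0L) stop("cannot compute N50 of an empty set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Genome-wide heterozygosity of an assembly
#'
#' SNP sites divided by total assembly length (a read-based quantity: the
#' SNPs come from reads mapped back onto the assembly itself). The
#' denominator is the full sequence length including N runs.
#'
#' @param snps SNP data.frame as returned by [readVcfSnps()]/[snpTable()].
#' @param seqs an [AssemblySeqs-class] object.
#' @return heterozygosity as a fraction (SNP sites per bp).
#' @export
totalHeterozygosity <- function(snps, seqs) {
  unknown <- setdiff(unique(snps$contig), names(seqs))
  if (length(unknown))
    stop("SNP on contig absent from the assembly: '", unknown[1L], "'")
  nrow(snps) / sum(Biostrings::width(seqs))
}

#' Summarize an assembly after length filtering
#'
#' Applies the length cutoff, then computes sequence count, total length,
#' longest sequence, N50 and genome-wide heterozygosity on the filtered
#' set (SNPs on removed contigs drop out of the numerator together with
#' their contigs).
#'
#' @param seqs an [AssemblySeqs-class] object.
#' @param snps SNP data.frame ([snpTable()] layout).
#' @param cutoff length cutoff in bp (typical choices: 200 or 1000).
#' @return an [AssemblySummary-class] object.
#' @export
summarizeAssembly <- function(seqs, snps = emptySnpTable(), cutoff = 200L) {
  kept <- filterByLength(seqs, cutoff)
  if (length(kept) == 0L)
    stop("length cutoff ", cutoff, " bp removed every sequence of '",
         seqLabel(seqs), "'")
  snps_kept <- snps[snps$contig %in% names(kept), , drop = FALSE]
  w <- Biostrings::width(kept)
  new("AssemblySummary",
      label = seqLabel(seqs), lengthCutoff = as.numeric(cutoff),
      nSequences = length(kept), totalLength = sum(w),
      longest = max(w), n50 = as.numeric(computeN50(w)),
      totalHeterozygosity = totalHeterozygosity(snps_kept, kept))
}
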