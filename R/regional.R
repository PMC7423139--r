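#' @importFrom GenomicRanges GRanges reduce seqnames
#' @importFrom IRanges IRanges
NULL

#' Locate gene regions on an assembly from transcript alignments
#'
#' Per transcript, hits with identity `>= minIdentity` (strict threshold:
#' 91.9 is out at the default 92) are grouped by subject contig; each
#' (transcript, contig) pair defines one region spanning from the minimum
#' to the maximum subject coordinate of its kept hits. Regions spanning
#' more than `maxGeneSpan` are excluded as likely mapping errors, with the
#' reason recorded. Genes whose kept hits land on more than one contig
#' yield one region per contig and are reported in `multiContigGenes` —
#' on an allelically expanded assembly this is the expected signature of
#' a gene present on both haplotype contigs, and on a fragmented one, of
#' a gene split across contigs.
#'
#' @param hits normalized transcript-vs-assembly alignment hits.
#' @param minIdentity minimum percent identity for an exon hit (default 92).
#' @param maxGeneSpan maximum genomic span of a gene region in bp
#'   (default 10000).
#' @return list with `regions` (a [GenomicRanges::GRanges] on the
#'   assembly, names `<gene>@<contig>`, mcols `gene_id`, `n_exon_hits`),
#'   `excluded` (data.frame `gene_id`, `contig`, `span`, `reason`) and
#'   `multiContigGenes` (character).
#' @export
extractGeneRegions <- function(hits, minIdentity = 92, maxGeneSpan = 10000L) {
  hits <- hits[hits$pident >= minIdentity, , drop = FALSE]
  out <- list(); exc <- list()
  multi <- character(0)
  if (nrow(hits)) {
    dt <- data.table::as.data.table(hits)
    agg <- dt[, list(start = min(sstart), end = max(send),
                     n_exon_hits = .N),
              by = c("qseqid", "sseqid")]
    agg[, `:=`(span = end - start + 1L)]
    ngene <- table(agg$qseqid)
    multi <- names(ngene)[ngene > 1L]
    keep <- agg$span <= maxGeneSpan
    exc_df <- data.frame(gene_id = agg$qseqid[!keep],
                         contig = agg$sseqid[!keep],
                         span = agg$span[!keep],
                         reason = rep("span_over_max", sum(!keep)),
                         stringsAsFactors = FALSE)
    agg <- agg[keep, ]
    regions <- GenomicRanges::GRanges(
      agg$sseqid, IRanges::IRanges(agg$start, agg$end),
      gene_id = agg$qseqid, n_exon_hits = agg$n_exon_hits)
    if (nrow(agg))
      names(regions) <- paste0(agg$qseqid, "@", agg$sseqid)
  } else {
    regions <- GenomicRanges::GRanges()
    exc_df <- data.frame(gene_id = character(), contig = character(),
                         span = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  }
  list(regions = regions, excluded = exc_df, multiContigGenes = multi)
}

#' Heterozygosity of genomic regions
#'
#' SNP sites falling inside each region divided by the region length.
#'
#' @param snps SNP data.frame ([snpTable()] layout), coordinates on the
#'   same assembly as `regions`.
#' @param regions a [GenomicRanges::GRanges].
#' @return numeric vector of per-region heterozygosity (snps per bp).
#' @export
regionalHeterozygosity <- function(snps, regions) {
  countSnpsIn(snps, regions) / BiocGenerics::width(regions)
}

#' Count SNP sites falling inside each region
#'
#' @inheritParams regionalHeterozygosity
#' @return integer vector, parallel to `regions`.
#' @export
countSnpsIn <- function(snps, regions) {
  if (length(regions) == 0L) return(integer(0))
  ctg <- as.character(GenomicRanges::seqnames(regions))
  st <- BiocGenerics::start(regions)
  en <- BiocGenerics::end(regions)
  vapply(seq_along(regions), function(i)
    sum(snps$contig == ctg[i] & snps$pos >= st[i] & snps$pos <= en[i]),
    integer(1L))
}

#' Mean read depth of genomic regions, zero-filled
#'
#' Arithmetic mean of per-base depth over each region; positions absent
#' from the depth table count as depth 0.
#'
#' @param depth a [DepthTable-class].
#' @param regions a [GenomicRanges::GRanges] on the same assembly.
#' @return numeric vector of mean depths, parallel to `regions`.
#' @export
regionalDepth <- function(depth, regions) {
  if (length(regions) == 0L) return(numeric(0))
  tb <- depth@tbl
  ctg <- as.character(GenomicRanges::seqnames(regions))
  st <- BiocGenerics::start(regions)
  en <- BiocGenerics::end(regions)
  vapply(seq_along(regions), function(i) {
    sub <- tb[list(ctg[i]), nomatch = NULL]
    s <- sum(sub$depth[sub$pos >= st[i] & sub$pos <= en[i]])
    s / (en[i] - st[i] + 1L)
  }, numeric(1L))
}

#' Match extracted assembly regions onto the reference
#'
#' Keeps hits with identity `>= minIdentity` (default 98, a strict
#' threshold chosen to prevent comparison of paralogous regions) and
#' returns their subject intervals in forward orientation. Region ids
#' with hits but none qualifying are reported as unresolved.
#'
#' @param hits normalized region-vs-reference alignment hits (query ids
#'   are region ids).
#' @param minIdentity minimum percent identity (default 98).
#' @return list with `matches` (a [GenomicRanges::GRanges] on the
#'   reference, mcols `region_id`, `pident`) and `unresolved` (character
#'   region ids with no qualifying hit).
#' @export
matchReferenceRegions <- function(hits, minIdentity = 98) {
  all_ids <- unique(hits$qseqid)
  keep <- hits$pident >= minIdentity
  kept <- hits[keep, , drop = FALSE]
  matches <- if (nrow(kept)) {
    GenomicRanges::GRanges(kept$sseqid,
                           IRanges::IRanges(kept$sstart, kept$send),
                           region_id = kept$qseqid, pident = kept$pident)
  } else GenomicRanges::GRanges()
  list(matches = matches,
       unresolved = setdiff(all_ids, unique(kept$qseqid)))
}

#' Collapse overlapping or redundant HSP intervals
#'
#' Merges overlapping high-scoring-pair intervals per contig so each
#' reference base is counted once: unique assembly sequence mapped onto
#' unique reference sequence.
#'
#' @param intervals a [GenomicRanges::GRanges].
#' @return list with `intervals` (disjoint, sorted) and `uniqueBp`.
#' @export
collapseHsps <- function(intervals) {
  merged <- GenomicRanges::reduce(GenomicRanges::sort(intervals))
  list(intervals = merged, uniqueBp = sum(BiocGenerics::width(merged)))
}

#' Default classification thresholds for the ratio signatures
#'
#' A ratio at or above `hi` counts as elevated, at or below `lo` as
#' depressed; `[lo, hi]` is the normal band. The defaults (1.5 / 0.67)
#' bracket the neutral value symmetrically on the fold scale.
#'
#' @param lenHi,lenLo,covHi,covLo,hetHi,hetLo band edges per ratio.
#' @return named list of thresholds.
#' @export
classifyThresholds <- function(lenHi = 1.5, lenLo = 0.67, covHi = 1.5,
                               covLo = 0.67, hetHi = 1.5, hetLo = 0.67) {
  list(lenHi = lenHi, lenLo = lenLo, covHi = covHi, covLo = covLo,
       hetHi = hetHi, hetLo = hetLo)
}

#' Classify a region set from its three ratios
#'
#' The signature model: allelic expansion inflates regional length while
#' halving coverage and collapsing apparent heterozygosity
#' (`len >= lenHi`, `cov <= covLo`, `het <= hetLo`); repeat collapse does
#' the opposite (`len <= lenLo`, `cov >= covHi`, `het >= hetHi`); a
#' region set combining expansion and collapse shows inflated length
#' together with inflated heterozygosity (`mixed`); all three ratios
#' inside the band is `normal`; anything else `unresolved`. Undefined
#' (NA) ratios classify as `unresolved`.
#'
#' @param lenRatio,covRatio,hetRatio numeric vectors (test / reference).
#' @param thresholds a [classifyThresholds()] list.
#' @return character vector of labels.
#' @export
classifyRegion <- function(lenRatio, covRatio, hetRatio,
                           thresholds = classifyThresholds()) {
  t <- thresholds
  n <- max(length(lenRatio), length(covRatio), length(hetRatio))
  lenRatio <- rep_len(lenRatio, n)
  covRatio <- rep_len(covRatio, n)
  hetRatio <- rep_len(hetRatio, n)
  vapply(seq_len(n), function(i) {
    l <- lenRatio[i]; cv <- covRatio[i]; h <- hetRatio[i]
    if (anyNA(c(l, cv, h))) return("unresolved")
    if (l >= t$lenHi && cv <= t$covLo && h <= t$hetLo) return("expansion")
    if (l <= t$lenLo && cv >= t$covHi && h >= t$hetHi) return("collapse")
    if (l >= t$lenHi && h >= t$hetHi) return("mixed")
    if (l >= t$lenLo && l <= t$lenHi && cv >= t$covLo && cv <= t$covHi &&
        h >= t$hetLo && h <= t$hetHi) return("normal")
    "unresolved"
  }, character(1L))
}

#' Pooled ratios for one region set
#'
#' Pools counts before dividing (length-weighted): the heterozygosity
#' ratio divides pooled SNP density on the test side by pooled density on
#' the reference side; the coverage ratio divides length-weighted mean
#' depths; the length ratio divides unique test bp by unique reference
#' bp. Zero reference denominators leave the affected ratio NA and the
#' set flagged.
#'
#' @param testMetrics data.frame with columns `n_snps`, `length`,
#'   `mean_depth` (one row per test region).
#' @param refMetrics same layout, one row per merged reference interval.
#' @param testUniqueBp,refUniqueBp unique bp on each side; default to the
#'   summed lengths of the supplied rows.
#' @param thresholds a [classifyThresholds()] list.
#' @param region_set_id set label carried into the output row.
#' @return one-row data.frame: ids, ratios, `classification`, `flagged`.
#' @export
regionSetRatios <- function(testMetrics, refMetrics,
                            testUniqueBp = sum(testMetrics$length),
                            refUniqueBp = sum(refMetrics$length),
                            thresholds = classifyThresholds(),
                            region_set_id = "set") {
  t_bp <- sum(testMetrics$length); r_bp <- sum(refMetrics$length)
  het_t <- if (t_bp > 0) sum(testMetrics$n_snps) / t_bp else NA_real_
  het_r <- if (r_bp > 0) sum(refMetrics$n_snps) / r_bp else NA_real_
  cov_t <- if (t_bp > 0)
    sum(testMetrics$mean_depth * testMetrics$length) / t_bp else NA_real_
  cov_r <- if (r_bp > 0)
    sum(refMetrics$mean_depth * refMetrics$length) / r_bp else NA_real_
  het_ratio <- if (!is.na(het_r) && het_r > 0) het_t / het_r else NA_real_
  cov_ratio <- if (!is.na(cov_r) && cov_r > 0) cov_t / cov_r else NA_real_
  len_ratio <- if (refUniqueBp > 0) testUniqueBp / refUniqueBp else NA_real_
  data.frame(
    region_set_id = region_set_id,
    n_test_regions = nrow(testMetrics),
    test_bp = t_bp, ref_bp = r_bp,
    test_unique_bp = testUniqueBp, ref_unique_bp = refUniqueBp,
    het_ratio = het_ratio, cov_ratio = cov_ratio, len_ratio = len_ratio,
    fold_contraction = if (testUniqueBp > 0) refUniqueBp / testUniqueBp
      else NA_real_,
    classification = classifyRegion(len_ratio, cov_ratio, het_ratio,
                                    thresholds),
    flagged = anyNA(c(het_ratio, cov_ratio, len_ratio)),
    stringsAsFactors = FALSE)
}

#' Full regional ratio analysis across region sets
#'
#' Runs the regional pipeline: extract gene regions on the test assembly
#' from transcript alignments, measure per-region heterozygosity and
#' coverage, match regions onto the reference at high identity, measure
#' the matched reference intervals with the same code path on the
#' reference's own SNPs and depth, then pool per region set and classify.
#'
#' @param transcriptHits transcript-vs-test-assembly hits.
#' @param regionHits extracted-region-vs-reference hits (query ids must
#'   be the `<gene>@<contig>` region ids produced by
#'   [extractGeneRegions()]).
#' @param testSnps,testDepth SNPs and [DepthTable-class] on the test
#'   assembly.
#' @param refSnps,refDepth SNPs and depth on the reference.
#' @param geneSets data.frame mapping `gene_id` to `set_id`.
#' @param minExonIdentity,maxGeneSpan passed to [extractGeneRegions()].
#' @param minRefIdentity passed to [matchReferenceRegions()].
#' @param thresholds a [classifyThresholds()] list.
#' @return list with `ratios` (one row per region set), `regionMetrics`
#'   (per-region test metrics), `unresolvedRegions`, `multiContigGenes`
#'   and `excluded` (the span-based exclusions).
#' @export
regionSetAnalysis <- function(transcriptHits, regionHits, testSnps,
                              testDepth, refSnps, refDepth, geneSets,
                              minExonIdentity = 92, maxGeneSpan = 10000L,
                              minRefIdentity = 98,
                              thresholds = classifyThresholds()) {
  eg <- extractGeneRegions(transcriptHits, minExonIdentity, maxGeneSpan)
  regions <- eg$regions
  mm <- matchReferenceRegions(regionHits, minRefIdentity)
  matched_ids <- unique(mm$matches$region_id)
  unresolved <- union(mm$unresolved, setdiff(names(regions), matched_ids))

  rm_df <- if (length(regions)) data.frame(
    region_id = names(regions),
    gene_id = regions$gene_id,
    contig = as.character(GenomicRanges::seqnames(regions)),
    start = BiocGenerics::start(regions), end = BiocGenerics::end(regions),
    length = BiocGenerics::width(regions),
    n_snps = countSnpsIn(testSnps, regions),
    mean_depth = regionalDepth(testDepth, regions),
    resolved = names(regions) %in% matched_ids,
    stringsAsFactors = FALSE)
  else data.frame(region_id = character(), gene_id = character(),
                  contig = character(), start = integer(), end = integer(),
                  length = integer(), n_snps = integer(),
                  mean_depth = numeric(), resolved = logical(),
                  stringsAsFactors = FALSE)
  rm_df$heterozygosity <- ifelse(rm_df$length > 0,
                                 rm_df$n_snps / rm_df$length, NA_real_)

  sets <- unique(geneSets$set_id)
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    sid <- sets[k]
    genes <- geneSets$gene_id[geneSets$set_id == sid]
    tm <- rm_df[rm_df$gene_id %in% genes & rm_df$resolved, , drop = FALSE]
    if (nrow(tm) == 0L) {
      rows[[k]] <- regionSetRatios(
        data.frame(n_snps = integer(), length = integer(),
                   mean_depth = numeric()),
        data.frame(n_snps = integer(), length = integer(),
                   mean_depth = numeric()),
        testUniqueBp = 0, refUniqueBp = 0,
        thresholds = thresholds, region_set_id = sid)
      next
    }
    tgr <- GenomicRanges::GRanges(tm$contig, IRanges::IRanges(tm$start,
                                                              tm$end))
    test_unique <- collapseHsps(tgr)$uniqueBp
    rmm <- mm$matches[mm$matches$region_id %in% tm$region_id]
    red <- collapseHsps(rmm)
    ref_iv <- red$intervals
    ref_metrics <- data.frame(
      n_snps = countSnpsIn(refSnps, ref_iv),
      length = BiocGenerics::width(ref_iv),
      mean_depth = regionalDepth(refDepth, ref_iv))
    rows[[k]] <- regionSetRatios(
      tm[, c("n_snps", "length", "mean_depth")], ref_metrics,
      testUniqueBp = test_unique, refUniqueBp = red$uniqueBp,
      thresholds = thresholds, region_set_id = sid)
  }
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  list(ratios = ratios, regionMetrics = rm_df,
       unresolvedRegions = unresolved,
       multiContigGenes = eg$multiContigGenes, excluded = eg$excluded)
}
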