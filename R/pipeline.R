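#' Assemble a pipeline configuration
#'
#' Paths to every input file plus the thresholds of each stage; defaults
#' are the constants the individual stage functions document.
#'
#' @param ref_fasta,asm_fasta assembly FASTA paths (reference, test).
#' @param asm_vcf,ref_vcf,asm_depth,ref_depth SNP and depth files for the
#'   test assembly and the reference.
#' @param transcript_hits,region_hits,protein_hits,asmref_hits alignment
#'   tables (see [regionSetAnalysis()] and [tallyAssembly()]).
#' @param gene_sets TSV with columns `gene_id`, `set_id`.
#' @param ref_protein_ids text file with one reference protein id per line.
#' @param length_cutoff assembly length cutoff in bp (200 or 1000).
#' @param min_exon_identity,max_gene_span,min_ref_identity,min_aln_length
#'   stage thresholds.
#' @param thresholds a [classifyThresholds()] list.
#' @param seed RNG seed recorded in the outputs.
#' @return config list for [runPipeline()].
#' @export
pipelineConfig <- function(ref_fasta, asm_fasta, asm_vcf, ref_vcf,
                           asm_depth, ref_depth, transcript_hits,
                           region_hits, protein_hits, asmref_hits,
                           gene_sets, ref_protein_ids,
                           length_cutoff = 200L, min_exon_identity = 92,
                           max_gene_span = 10000L, min_ref_identity = 98,
                           min_aln_length = 24L,
                           thresholds = classifyThresholds(), seed = 1L) {
  if (!length_cutoff > 0) stop("length_cutoff must be positive")
  pct <- c(min_exon_identity, min_ref_identity)
  if (any(pct < 0 | pct > 100)) stop("identity thresholds are percentages")
  as.list(environment())
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.writeTsv <- function(df, path, config, extra = character(0)) {
  hdr <- c(sprintf("# hetscope %s",
                   as.character(utils::packageVersion("hetscope"))),
           sprintf("# length_cutoff=%d min_exon_identity=%g max_gene_span=%d min_ref_identity=%g min_aln_length=%d seed=%d",
                   as.integer(config$length_cutoff),
                   config$min_exon_identity,
                   as.integer(config$max_gene_span),
                   config$min_ref_identity,
                   as.integer(config$min_aln_length),
                   as.integer(config$seed)),
           extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full diagnostic pipeline
#'
#' Executes filter, summarize, compare, regional ratios and
#' fragmentation/duplication tallying over the configured inputs, and
#' writes `summary.tsv`, `comparison.tsv`, `fragdup.tsv`, `ratios.tsv`
#' and `exclusions.tsv` to `outDir` (each with a header comment embedding
#' the configuration and package version). Deterministic for fixed inputs
#' and config. Any stage failure aborts with the stage name.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if needed).
#' @return list with `summaryTest`, `summaryRef`, `comparison`, `ratios`,
#'   `fragdup`, `regional`, `warnings` and `files`, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ref <- .stage("read_reference", readFastaSeqs(config$ref_fasta, "reference"))
  asm <- .stage("read_assembly", readFastaSeqs(config$asm_fasta, "assembly"))
  asm_snps <- .stage("read_vcf", readVcfSnps(config$asm_vcf))
  ref_snps <- .stage("read_vcf", readVcfSnps(config$ref_vcf))
  asm_depth <- .stage("read_depth", readDepthTable(config$asm_depth))
  ref_depth <- .stage("read_depth", readDepthTable(config$ref_depth))
  thits <- .stage("read_alignments", readAlignmentTable(config$transcript_hits))
  rhits <- .stage("read_alignments", readAlignmentTable(config$region_hits))
  phits <- .stage("read_alignments", readAlignmentTable(config$protein_hits))
  ahits <- .stage("read_alignments", readAlignmentTable(config$asmref_hits))
  gene_sets <- .stage("read_gene_sets",
                      utils::read.delim(config$gene_sets,
                                        stringsAsFactors = FALSE))
  ref_ids <- .stage("read_protein_ids",
                    readLines(config$ref_protein_ids, warn = FALSE))

  sum_t <- .stage("summarize",
                  summarizeAssembly(asm, asm_snps, config$length_cutoff))
  sum_r <- .stage("summarize",
                  summarizeAssembly(ref, ref_snps, config$length_cutoff))

  comparison <- .stage("compare", {
    pm <- percentMissing(ahits, ref, config$min_aln_length)
    pe <- percentExpanded(sum_t@totalLength, sum_r@totalLength, pm / 100)
    data.frame(assembly_label = seqLabel(asm),
               percent_missing = pm,
               percent_expanded_of_assembly = pe$percent_of_assembly,
               percent_excess_over_reference =
                 pe$percent_excess_over_reference,
               net_deficit = pe$net_deficit,
               assembly_total = sum_t@totalLength,
               reference_total = sum_r@totalLength, stringsAsFactors = FALSE)
  })

  regional <- .stage("regions", regionSetAnalysis(
    thits, rhits, asm_snps, asm_depth, ref_snps, ref_depth, gene_sets,
    minExonIdentity = config$min_exon_identity,
    maxGeneSpan = config$max_gene_span,
    minRefIdentity = config$min_ref_identity,
    thresholds = config$thresholds))

  fragdup <- .stage("fragdup", {
    ph <- dedupeHits(filterReferenceQueries(phits, ref_ids))
    self_hits <- ph[ph$sseqid %in% ref_ids, , drop = FALSE]
    paralogs <- identifyParalogs(self_hits)
    test_hits <- ph[!ph$sseqid %in% ref_ids, , drop = FALSE]
    tallyAssembly(test_hits, ref_ids, paralogs, label = seqLabel(asm))
  })

  warn <- flagAssembly(sum_t, sum_r)

  exclusions <- rbind(
    data.frame(item = regional$excluded$gene_id,
               detail = regional$excluded$contig,
               reason = regional$excluded$reason, stringsAsFactors = FALSE),
    if (length(regional$unresolvedRegions))
      data.frame(item = regional$unresolvedRegions, detail = "",
                 reason = "no_reference_match", stringsAsFactors = FALSE),
    if (length(regional$multiContigGenes))
      data.frame(item = regional$multiContigGenes, detail = "",
                 reason = "multi_contig_gene", stringsAsFactors = FALSE),
    if (fragdup$counts$excluded_paralogs > 0)
      data.frame(item = seqLabel(asm),
                 detail = as.character(fragdup$counts$excluded_paralogs),
                 reason = "paralogous_reference_proteins",
                 stringsAsFactors = FALSE))

  files <- c(
    summary = .writeTsv(rbind(as.data.frame(sum_t), as.data.frame(sum_r)),
                        file.path(outDir, "summary.tsv"), config),
    comparison = .writeTsv(comparison, file.path(outDir, "comparison.tsv"),
                           config),
    fragdup = .writeTsv(fragdup$counts, file.path(outDir, "fragdup.tsv"),
                        config),
    ratios = .writeTsv(regional$ratios, file.path(outDir, "ratios.tsv"),
                       config),
    exclusions = .writeTsv(exclusions, file.path(outDir, "exclusions.tsv"),
                           config))
  invisible(list(summaryTest = sum_t, summaryRef = sum_r,
                 comparison = comparison, ratios = regional$ratios,
                 fragdup = fragdup, regional = regional,
                 warnings = warn, files = files))
}

#' Heuristic quality warnings for a test assembly
#'
#' Emits warnings when the test assembly's genome-wide heterozygosity
#' falls below `hetFactor` times the reference's (allelic splitting
#' depresses apparent heterozygosity), when total length exceeds the
#' reference by more than `lengthFactor` (regional expansion), and, if
#' supplied, when the share of gene predictions lacking evidentiary
#' support exceeds `nonevidenceBound`.
#'
#' @param summary,referenceSummary [AssemblySummary-class] objects at a
#'   common cutoff.
#' @param nonevidenceRatio optional fraction of non-evidence-supported
#'   gene predictions.
#' @param hetFactor,lengthFactor,nonevidenceBound warning thresholds
#'   (defaults 0.5, 1.2, 0.5).
#' @return character vector of warnings (empty when clean).
#' @export
flagAssembly <- function(summary, referenceSummary, nonevidenceRatio = NULL,
                         hetFactor = 0.5, lengthFactor = 1.2,
                         nonevidenceBound = 0.5) {
  w <- character(0)
  if (summary@totalHeterozygosity <
      hetFactor * referenceSummary@totalHeterozygosity)
    w <- c(w, sprintf(
      "heterozygosity %.5f is below %.2fx the reference (%.5f): allelic regions are likely split into separate contigs",
      summary@totalHeterozygosity, hetFactor,
      referenceSummary@totalHeterozygosity))
  if (summary@totalLength > lengthFactor * referenceSummary@totalLength)
    w <- c(w, sprintf(
      "total length %.0f exceeds %.2fx the reference (%.0f): regional expansion suspected",
      summary@totalLength, lengthFactor, referenceSummary@totalLength))
  if (!is.null(nonevidenceRatio) && nonevidenceRatio > nonevidenceBound)
    w <- c(w, sprintf(
      "%.0f%% of gene predictions lack evidentiary support (bound %.0f%%)",
      100 * nonevidenceRatio, 100 * nonevidenceBound))
  w
}
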