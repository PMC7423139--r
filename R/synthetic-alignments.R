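#' @importFrom GenomicRanges GRanges seqnames
NULL

# locate every contig-map row that fully contains [gs, ge] on src contig
.containingRows <- function(cm, src, gs, ge) {
  cm[cm$src_contig == src & cm$src_start <= gs & cm$src_end >= ge, ,
     drop = FALSE]
}

# split a 1..w span into exon-sized query chunks
.exonChunks <- function(w, exonLength) {
  starts <- seq.int(1L, w, by = exonLength)
  ends <- pmin(starts + exonLength - 1L, w)
  data.frame(qs = starts, qe = ends)
}

#' Emit the alignment tables a test assembly would produce
#'
#' Constructs, from the assembly's contig map and the genome's ground
#' truth, the three 12-column tabular alignment sets the diagnostic
#' pipeline consumes: transcripts-vs-assembly (`transcripts`), extracted
#' gene regions-vs-reference (`regions`, query ids `<gene>@<contig>`),
#' and a protein all-vs-all table (`proteins`, reference self-hits
#' included), plus whole-contig assembly-vs-reference hits (`asmref`).
#' Percent identities are the true identities of the aligned spans, so an
#' expanded allelic contig yields two overlapping hits to the same
#' reference span, one at 100 and one near `100 * (1 - hetRate)`.
#'
#' @param assembly a [SyntheticAssembly-class].
#' @param genome the [DiploidGenome-class] it derives from.
#' @param genes [GenomicRanges::GRanges] of gene spans on the consensus,
#'   with unique names. Genes must lie fully inside one contig-map segment
#'   (for collapse segments, inside a single repeat copy); others are
#'   skipped with a warning.
#' @param exonLength transcript hits are emitted in chunks of this size,
#'   emulating exon-wise local alignments (the region extractor re-joins
#'   them via its min/max rule).
#' @param seed unused (construction is deterministic); kept for interface
#'   stability.
#' @return list of data.frames: `transcripts`, `regions`, `proteins`,
#'   `asmref`, and the character vector `refProteinIds`.
#' @export
emitAlignmentTables <- function(assembly, genome, genes, exonLength = 700L,
                                seed = 1L) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("genes must carry unique names")
  cm <- assembly@contigMap
  asmStr <- as.character(assembly@seqs)
  refStr <- as.character(genome@hapA)

  tr <- list(); rg <- list(); pr <- list()
  skipped <- character(0)

  for (gi in seq_along(genes)) {
    gname <- names(genes)[gi]
    src <- as.character(GenomicRanges::seqnames(genes))[gi]
    gs <- BiocGenerics::start(genes)[gi]
    ge <- BiocGenerics::end(genes)[gi]
    w <- ge - gs + 1L
    gene_seq <- substr(refStr[[src]], gs, ge)
    rows <- .containingRows(cm, src, gs, ge)
    targets <- list()
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$role == "collapse") {
        fac <- as.integer(r$factor)
        unit <- (r$src_end - r$src_start + 1L) %/% fac
        ci <- (gs - r$src_start) %/% unit
        if ((ge - r$src_start) %/% unit != ci) next  # spans copies
        ts <- r$ctg_start + ((gs - r$src_start) %% unit)
      } else {
        ts <- gs - r$src_start + r$ctg_start
      }
      targets[[length(targets) + 1L]] <-
        list(contig = r$contig, ts = ts, role = r$role, row = r)
    }
    if (!length(targets)) { skipped <- c(skipped, gname); next }

    plen <- max(1L, w %/% 3L)
    pr[[length(pr) + 1L]] <- alignmentHits(
      qseqid = paste0("P_", gname), sseqid = paste0("P_", gname),
      pident = 100, qstart = 1L, qend = plen, sstart = 1L, send = plen,
      bitscore = 2 * plen)

    ex <- .exonChunks(w, exonLength)
    for (tg in targets) {
      tgt_seq <- substr(asmStr[[tg$contig]], tg$ts, tg$ts + w - 1L)
      # transcript-vs-assembly exon hits
      for (k in seq_len(nrow(ex))) {
        qs <- ex$qs[k]; qe <- ex$qe[k]
        pid <- strIdentity(substr(gene_seq, qs, qe), substr(tgt_seq, qs, qe))
        tr[[length(tr) + 1L]] <- alignmentHits(
          qseqid = gname, sseqid = tg$contig, pident = pid,
          qstart = qs, qend = qe,
          sstart = tg$ts + qs - 1L, send = tg$ts + qe - 1L,
          bitscore = 2 * (qe - qs + 1L))
      }
      # extracted region vs reference
      region_id <- paste0(gname, "@", tg$contig)
      if (tg$role == "collapse") {
        r <- tg$row
        fac <- as.integer(r$factor)
        unit <- (r$src_end - r$src_start + 1L) %/% fac
        off <- (gs - r$src_start) %% unit
        for (j in seq_len(fac) - 1L) {
          ss <- r$src_start + j * unit + off
          pid <- strIdentity(tgt_seq, substr(refStr[[src]], ss, ss + w - 1L))
          rg[[length(rg) + 1L]] <- alignmentHits(
            qseqid = region_id, sseqid = src, pident = pid,
            qstart = 1L, qend = w, sstart = ss, send = ss + w - 1L,
            bitscore = 2 * w)
        }
      } else {
        pid <- strIdentity(tgt_seq, gene_seq)
        rg[[length(rg) + 1L]] <- alignmentHits(
          qseqid = region_id, sseqid = src, pident = pid,
          qstart = 1L, qend = w, sstart = gs, send = ge, bitscore = 2 * w)
      }
      # protein match: reference protein vs this gene copy
      pid <- strIdentity(tgt_seq, gene_seq)
      pr[[length(pr) + 1L]] <- alignmentHits(
        qseqid = paste0("P_", gname), sseqid = paste0("T_", region_id),
        pident = pid, qstart = 1L, qend = plen, sstart = 1L, send = plen,
        bitscore = 2 * plen)
    }
  }
  if (length(skipped))
    warning("genes skipped (straddle a segment or repeat-copy boundary): ",
            paste(skipped, collapse = ", "))

  # whole-contig assembly-vs-reference hits
  ar <- list()
  for (i in seq_len(nrow(cm))) {
    r <- cm[i, ]
    qw <- r$ctg_end - r$ctg_start + 1L
    qseq <- substr(asmStr[[r$contig]], r$ctg_start, r$ctg_end)
    if (r$role == "collapse") {
      fac <- as.integer(r$factor)
      unit <- (r$src_end - r$src_start + 1L) %/% fac
      for (j in seq_len(fac) - 1L) {
        ss <- r$src_start + j * unit
        pid <- strIdentity(qseq, substr(refStr[[r$src_contig]], ss,
                                        ss + unit - 1L))
        ar[[length(ar) + 1L]] <- alignmentHits(
          qseqid = r$contig, sseqid = r$src_contig, pident = pid,
          qstart = r$ctg_start, qend = r$ctg_end,
          sstart = ss, send = ss + unit - 1L, bitscore = 2 * unit)
      }
    } else {
      pid <- strIdentity(qseq, substr(refStr[[r$src_contig]], r$src_start,
                                      r$src_end))
      ar[[length(ar) + 1L]] <- alignmentHits(
        qseqid = r$contig, sseqid = r$src_contig, pident = pid,
        qstart = r$ctg_start, qend = r$ctg_end,
        sstart = r$src_start, send = r$src_end, bitscore = 2 * qw)
    }
  }

  bindOrEmpty <- function(x)
    if (length(x)) do.call(rbind, x) else emptyAlignmentTable()
  list(transcripts = normalizeAlignmentHits(bindOrEmpty(tr)),
       regions = normalizeAlignmentHits(bindOrEmpty(rg)),
       proteins = normalizeAlignmentHits(bindOrEmpty(pr)),
       asmref = normalizeAlignmentHits(bindOrEmpty(ar)),
       refProteinIds = paste0("P_", names(genes)))
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the mapping profiles for the test assembly and for the
#' reference (rendered through the same code path with no artifacts) and
#' writes every file the pipeline consumes: FASTA for both assemblies,
#' VCF and per-base depth for both, the three alignment tables, the
#' assembly-vs-reference table, the gene-to-set map, the reference
#' protein id list and the artifact truth table.
#'
#' @param dir output directory (created if needed).
#' @param genome a [DiploidGenome-class].
#' @param assembly a [SyntheticAssembly-class] derived from it.
#' @param genes named [GenomicRanges::GRanges] of gene spans on the
#'   consensus.
#' @param geneSets data.frame mapping `gene_id` to `set_id`.
#' @param baseDepth,seed,mismapRate passed to [simulateMappingProfile()].
#' @return named list of file paths.
#' @export
writeSyntheticBundle <- function(dir, genome, assembly, genes, geneSets,
                                 baseDepth = 60, seed = 1L, mismapRate = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  ref <- referenceAssembly(genome)
  prof_t <- simulateMappingProfile(assembly, genome, baseDepth, seed = seed,
                                   mismapRate = mismapRate)
  prof_r <- simulateMappingProfile(ref, genome, baseDepth, seed = seed + 1L)
  tabs <- emitAlignmentTables(assembly, genome, genes, seed = seed)

  writeFastaSeqs(ref@seqs, p("ref.fa"))
  writeFastaSeqs(assembly@seqs, p("asm.fa"))
  wt <- setNames(Biostrings::width(assembly@seqs), names(assembly@seqs))
  wr <- setNames(Biostrings::width(ref@seqs), names(ref@seqs))
  writeVcfSnps(prof_t$snps, p("asm.vcf"), contigLengths = wt)
  writeVcfSnps(prof_r$snps, p("ref.vcf"), contigLengths = wr)
  writeDepthTable(prof_t$depth, p("asm.depth"))
  writeDepthTable(prof_r$depth, p("ref.depth"))
  writeAlignmentTable(tabs$transcripts, p("transcripts.tsv"))
  writeAlignmentTable(tabs$regions, p("regions.tsv"))
  writeAlignmentTable(tabs$proteins, p("proteins.tsv"))
  writeAlignmentTable(tabs$asmref, p("asmref.tsv"))
  utils::write.table(assembly@truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(geneSets, p("gene_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(tabs$refProteinIds, p("ref_proteins.txt"))
  list(ref_fasta = p("ref.fa"), asm_fasta = p("asm.fa"),
       asm_vcf = p("asm.vcf"), ref_vcf = p("ref.vcf"),
       asm_depth = p("asm.depth"), ref_depth = p("ref.depth"),
       transcript_hits = p("transcripts.tsv"),
       region_hits = p("regions.tsv"), protein_hits = p("proteins.tsv"),
       asmref_hits = p("asmref.tsv"), truth = p("truth.tsv"),
       gene_sets = p("gene_sets.tsv"), ref_protein_ids = p("ref_proteins.txt"))
}
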