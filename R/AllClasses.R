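#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom BiocGenerics width start end
NULL

.ALLOWED_BASES <- c("A", "C", "G", "T", "N")

#' Named nucleotide sequences of one assembly
#'
#' Thin extension of [Biostrings::DNAStringSet] carrying a free-text source
#' label. Sequence ids must be unique and non-empty, sequences non-empty,
#' and the alphabet restricted to A, C, G, T, N (input is upper-cased on
#' read; soft-masking state is discarded).
#'
#' @slot label single character string naming the assembly.
#' @export
setClass("AssemblySeqs",
  contains = "DNAStringSet",
  representation(label = "character")
)

setValidity("AssemblySeqs", function(object) {
  msg <- character()
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "'label' must be a single string")
  ids <- names(object)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    msg <- c(msg, "every sequence must have a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate sequence id: '%s'",
                          ids[duplicated(ids)][1L]))
  if (length(object) && any(Biostrings::width(object) == 0L))
    msg <- c(msg, "empty sequences are not allowed")
  if (length(object)) {
    af <- Biostrings::alphabetFrequency(object, collapse = TRUE)
    bad <- af[!names(af) %in% .ALLOWED_BASES]
    if (sum(bad) > 0)
      msg <- c(msg, sprintf("alphabet restricted to A/C/G/T/N; found '%s'",
                            names(bad)[bad > 0][1L]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AssemblySeqs object
#'
#' @param seqs a named [Biostrings::DNAStringSet], or a named character
#'   vector of sequences (upper-cased on construction).
#' @param label free-text source label for the assembly.
#' @return an [AssemblySeqs-class] object.
#' @examples
#' assemblySeqs(c(ctg1 = "ACGTACGT"), label = "demo")
#' @export
assemblySeqs <- function(seqs, label = "assembly") {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  new("AssemblySeqs", seqs, label = as.character(label))
}

#' @describeIn AssemblySeqs-class source label accessor.
#' @param object,x an `AssemblySeqs` object.
#' @export
setGeneric("seqLabel", function(x) standardGeneric("seqLabel"))

#' @rdname AssemblySeqs-class
#' @export
setMethod("seqLabel", "AssemblySeqs", function(x) x@label)

setMethod("show", "AssemblySeqs", function(object) {
  cat(sprintf("AssemblySeqs '%s': %d sequences, %s bp total\n",
              object@label, length(object),
              format(sum(Biostrings::width(object)), big.mark = ",")))
  if (length(object)) callNextMethod()
})

#' A simulated diploid genome with full ground truth
#'
#' Two haplotypes that differ only by single-base substitutions at recorded
#' heterozygous sites, plus tandem repeat-family annotations. `hapA` serves
#' as the haploid consensus all downstream coordinates refer to.
#'
#' @slot hapA,hapB [Biostrings::DNAStringSet]; identical names and widths.
#' @slot trueSnps data.frame with columns `contig`, `pos` (1-based),
#'   `ref` (hapA base), `alt` (hapB base).
#' @slot hetRate target heterozygous sites per bp.
#' @slot repeats [GenomicRanges::GRanges] of repeat copies with mcols
#'   `family`, `copy`, `divergence`, `consensus` (family consensus unit).
#' @slot gc target GC fraction of the background sequence.
#' @export
setClass("DiploidGenome",
  representation(
    hapA = "DNAStringSet",
    hapB = "DNAStringSet",
    trueSnps = "data.frame",
    hetRate = "numeric",
    repeats = "GRanges",
    gc = "numeric"
  )
)

setValidity("DiploidGenome", function(object) {
  msg <- character()
  if (!identical(names(object@hapA), names(object@hapB)))
    msg <- c(msg, "hapA and hapB must carry identical contig names")
  if (!identical(Biostrings::width(object@hapA),
                 Biostrings::width(object@hapB)))
    msg <- c(msg, "hapA and hapB must have identical widths (substitutions only)")
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(object@trueSnps)))
    msg <- c(msg, "trueSnps needs columns contig, pos, ref, alt")
  else if (nrow(object@trueSnps)) {
    w <- stats::setNames(Biostrings::width(object@hapA), names(object@hapA))
    if (any(!object@trueSnps$contig %in% names(w)))
      msg <- c(msg, "trueSnps on unknown contig")
    else if (any(object@trueSnps$pos < 1L |
                 object@trueSnps$pos > w[object@trueSnps$contig]))
      msg <- c(msg, "trueSnps position out of contig bounds")
  }
  if (length(object@hetRate) != 1L || object@hetRate < 0 || object@hetRate > 0.05)
    msg <- c(msg, "hetRate must be a single value in [0, 0.05]")
  if (length(msg)) msg else TRUE
})

#' @describeIn DiploidGenome-class haplotype A (the consensus) accessor.
#' @param x,object a `DiploidGenome`.
#' @export
setGeneric("hapA", function(x) standardGeneric("hapA"))
#' @rdname DiploidGenome-class
#' @export
setMethod("hapA", "DiploidGenome", function(x) x@hapA)

#' @describeIn DiploidGenome-class haplotype B accessor.
#' @export
setGeneric("hapB", function(x) standardGeneric("hapB"))
#' @rdname DiploidGenome-class
#' @export
setMethod("hapB", "DiploidGenome", function(x) x@hapB)

#' @describeIn DiploidGenome-class ground-truth heterozygous sites.
#' @export
setGeneric("trueSnps", function(x) standardGeneric("trueSnps"))
#' @rdname DiploidGenome-class
#' @export
setMethod("trueSnps", "DiploidGenome", function(x) x@trueSnps)

#' @describeIn DiploidGenome-class repeat-copy annotations.
#' @export
setGeneric("repeatAnnotations", function(x) standardGeneric("repeatAnnotations"))
#' @rdname DiploidGenome-class
#' @export
setMethod("repeatAnnotations", "DiploidGenome", function(x) x@repeats)

setMethod("show", "DiploidGenome", function(object) {
  cat(sprintf(
    "DiploidGenome: %d contig(s), %s bp, %s heterozygous sites (target rate %.4f)\n",
    length(object@hapA),
    format(sum(Biostrings::width(object@hapA)), big.mark = ","),
    format(nrow(object@trueSnps), big.mark = ","), object@hetRate))
  if (length(object@repeats))
    cat(sprintf("  repeats: %d copies in %d family(ies)\n",
                length(object@repeats),
                length(unique(object@repeats$family))))
})

#' A synthetic test assembly with artifact ground truth
#'
#' Output of [makeTestAssembly()]: the assembly sequences, a contig map
#' tying every assembly interval back to its source interval on the
#' consensus (with the role that segment plays), and the realized artifact
#' truth table.
#'
#' @slot seqs an [AssemblySeqs-class] object.
#' @slot contigMap data.frame with columns `contig`, `ctg_start`, `ctg_end`,
#'   `src_start`, `src_end` (1-based closed, on the consensus), `role`
#'   (`normal`, `collapse`, `exp_hapA`, `exp_hapB`, `bubble`), `artifact_id`,
#'   `factor`, `n_paths`.
#' @slot truth data.frame: `artifact_id`, `kind`, `contig`, `start`, `end`,
#'   `factor`, `n_snp_clusters`, `n_paths`, `unit`.
#' @export
setClass("SyntheticAssembly",
  representation(
    seqs = "AssemblySeqs",
    contigMap = "data.frame",
    truth = "data.frame"
  )
)

#' @describeIn SyntheticAssembly-class assembly sequences.
#' @param x,object a `SyntheticAssembly`.
#' @export
setGeneric("assemblySequences", function(x) standardGeneric("assemblySequences"))
#' @rdname SyntheticAssembly-class
#' @export
setMethod("assemblySequences", "SyntheticAssembly", function(x) x@seqs)

#' @describeIn SyntheticAssembly-class contig-to-consensus map.
#' @export
setGeneric("contigMap", function(x) standardGeneric("contigMap"))
#' @rdname SyntheticAssembly-class
#' @export
setMethod("contigMap", "SyntheticAssembly", function(x) x@contigMap)

#' @describeIn SyntheticAssembly-class realized artifact truth table.
#' @export
setGeneric("artifactTruth", function(x) standardGeneric("artifactTruth"))
#' @rdname SyntheticAssembly-class
#' @export
setMethod("artifactTruth", "SyntheticAssembly", function(x) x@truth)

setMethod("show", "SyntheticAssembly", function(object) {
  kinds <- table(object@truth$kind)
  cat(sprintf("SyntheticAssembly '%s': %d contigs, %s bp; artifacts: %s\n",
              seqLabel(object@seqs), length(object@seqs),
              format(sum(Biostrings::width(object@seqs)), big.mark = ","),
              if (length(kinds)) paste(names(kinds), kinds, sep = "=",
                                       collapse = ", ") else "none"))
})

#' Per-base read depth of one assembly
#'
#' Sparse per-base depth: positions absent from the table read as depth 0
#' (samtools depth omits zero rows by default). Backed by a keyed
#' data.table for fast regional lookups.
#'
#' @slot tbl keyed data.table with columns `contig`, `pos` (1-based),
#'   `depth`.
#' @export
setClass("DepthTable", representation(tbl = "data.table"))

setValidity("DepthTable", function(object) {
  tb <- object@tbl
  if (!all(c("contig", "pos", "depth") %in% names(tb)))
    return("depth table needs columns contig, pos, depth")
  if (nrow(tb) && any(tb$depth < 0)) return("negative depth")
  if (nrow(tb) && any(tb$pos < 1L)) return("positions are 1-based (>= 1)")
  TRUE
})

#' Construct a DepthTable from an in-memory data frame
#'
#' @param tbl data.frame with columns `contig`, `pos`, `depth`.
#' @return a [DepthTable-class] object.
#' @export
depthTable <- function(tbl) {
  tbl <- data.table::as.data.table(tbl)[, c("contig", "pos", "depth")]
  tbl[, `:=`(contig = as.character(contig), pos = as.integer(pos),
             depth = as.integer(depth))]
  data.table::setkeyv(tbl, c("contig", "pos"))
  new("DepthTable", tbl = tbl)
}

setMethod("show", "DepthTable", function(object) {
  cat(sprintf("DepthTable: %s positions on %d contig(s)\n",
              format(nrow(object@tbl), big.mark = ","),
              length(unique(object@tbl$contig))))
})

#' @describeIn DepthTable-class underlying (contig, pos, depth) table.
#' @param x a `DepthTable`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "DepthTable", function(x, ...) {
  as.data.frame(x@tbl)
})

#' Whole-assembly summary statistics
#'
#' Length-filtered assembly summary: sequence count, total length, longest
#' sequence, N50 and genome-wide heterozygosity (SNP sites per bp).
#'
#' @slot label assembly label.
#' @slot lengthCutoff minimum retained sequence length (bp, inclusive).
#' @slot nSequences,totalLength,longest,n50 integer/numeric statistics.
#' @slot totalHeterozygosity SNP sites per bp over the filtered assembly.
#' @export
setClass("AssemblySummary",
  representation(
    label = "character", lengthCutoff = "numeric", nSequences = "integer",
    totalLength = "numeric", longest = "numeric", n50 = "numeric",
    totalHeterozygosity = "numeric"
  )
)

setValidity("AssemblySummary", function(object) {
  msg <- character()
  if (object@longest > object@totalLength)
    msg <- c(msg, "longest sequence cannot exceed total length")
  if (object@n50 > object@longest)
    msg <- c(msg, "N50 cannot exceed the longest sequence")
  if (object@totalHeterozygosity < 0)
    msg <- c(msg, "heterozygosity must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssemblySummary", function(object) {
  cat(sprintf(
    paste0("AssemblySummary '%s' (cutoff %d bp):\n",
           "  %d sequences, %s bp total, longest %s, N50 %s\n",
           "  heterozygosity %.5f snps/bp (%.2f%%)\n"),
    object@label, as.integer(object@lengthCutoff), object@nSequences,
    format(object@totalLength, big.mark = ","),
    format(object@longest, big.mark = ","),
    format(object@n50, big.mark = ","),
    object@totalHeterozygosity, 100 * object@totalHeterozygosity))
})

#' @describeIn AssemblySummary-class flatten to a one-row data.frame
#'   (columns mirror the summary table written by [runPipeline()]).
#' @param x an `AssemblySummary`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "AssemblySummary", function(x, ...) {
  data.frame(
    label = x@label, length_cutoff = x@lengthCutoff,
    n_sequences = x@nSequences, total_length = x@totalLength,
    longest = x@longest, n50 = x@n50,
    total_heterozygosity = x@totalHeterozygosity,
    stringsAsFactors = FALSE
  )
})
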