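#' Read SNP sites from a VCF file
#'
#' Consumes only CHROM/POS/REF/ALT. Sites are retained only when REF and
#' every ALT allele are single A/C/G/T bases — indels and symbolic alleles
#' are dropped. A multiallelic SNP site yields one record (heterozygosity
#' is counted per segregating site, not per allele).
#'
#' @param path path to a VCF 4.x text file.
#' @return data.frame with columns `contig`, `pos` (1-based integer),
#'   `ref`, `alt` (comma-joined alternate alleles), `n_alt`.
#' @export
readVcfSnps <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !startsWith(first, "##fileformat=VCF"))
    stop("malformed VCF header in ", path,
         ": first line must be '##fileformat=VCFv4.x'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(emptySnpTable())
  snpTable(contig = fix$CHROM, pos = as.integer(fix$POS),
           ref = fix$REF, alt = fix$ALT)
}

#' Build a SNP table in code, applying the SNP-only filter
#'
#' @param contig,pos,ref,alt parallel vectors; `alt` may be comma-joined
#'   multiallelic strings.
#' @return filtered data.frame (`contig`, `pos`, `ref`, `alt`, `n_alt`).
#' @export
snpTable <- function(contig, pos, ref, alt) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stop("SNP positions must be integers >= 1")
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  base_ok <- function(a) length(a) > 0L && all(nchar(a) == 1L) &&
    all(a %in% c("A", "C", "G", "T"))
  keep <- nchar(df$ref) == 1L & df$ref %in% c("A", "C", "G", "T") &
    vapply(alts, base_ok, logical(1L))
  df <- df[keep, , drop = FALSE]
  df$n_alt <- lengths(strsplit(df$alt, ",", fixed = TRUE))
  rownames(df) <- NULL
  df
}

#' @rdname snpTable
#' @return `emptySnpTable()`: a zero-row SNP table.
#' @export
emptySnpTable <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), n_alt = integer(), stringsAsFactors = FALSE)
}

#' Write a SNP table as a minimal VCF 4.2 file
#'
#' @param snps data.frame as returned by [snpTable()].
#' @param path output path.
#' @param contigLengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
writeVcfSnps <- function(snps, path, contigLengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=hetscope")
  if (!is.null(contigLengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigLengths), as.integer(contigLengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) {
    sprintf("%s\t%d\t.\t%s\t%s\t30\t.\t.",
            snps$contig, snps$pos, snps$ref, snps$alt)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
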