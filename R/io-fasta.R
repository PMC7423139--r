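#' Read a FASTA file into an AssemblySeqs object
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' multi-line records are joined and bases upper-cased. Duplicate ids and
#' empty records are hard errors.
#'
#' @param path path to a FASTA file.
#' @param label source label; defaults to the file name.
#' @return an [AssemblySeqs-class] object.
#' @seealso [writeFastaSeqs()]
#' @export
readFastaSeqs <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id in ", path, ": '",
         names(x)[duplicated(names(x))][1L], "'")
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence in ", path, ": '",
         names(x)[Biostrings::width(x) == 0L][1L], "'")
  assemblySeqs(x, label = label)
}

#' Write an AssemblySeqs object as FASTA
#'
#' @param x an [AssemblySeqs-class] (or DNAStringSet).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaSeqs <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
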