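#' Read a per-base depth file
#'
#' Three tab/space-separated columns: contig, 1-based position, depth
#' (the `samtools depth` text format). Positions absent from the file are
#' readable as depth 0; negative depths are a hard error.
#'
#' @param path path to the depth file.
#' @return a [DepthTable-class] object.
#' @export
readDepthTable <- function(path) {
  if (!file.exists(path)) stop("no such depth file: ", path)
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("contig", "pos", "depth"))
  if (ncol(dt) != 3L) stop("depth file must have 3 columns: ", path)
  if (nrow(dt) && any(dt$depth < 0))
    stop("negative depth at ", dt$contig[dt$depth < 0][1L], ":",
         dt$pos[dt$depth < 0][1L], " in ", path)
  depthTable(dt)
}

#' Write a DepthTable as a 3-column text file
#'
#' @param x a [DepthTable-class] object.
#' @param path output path.
#' @param dropZeros omit zero-depth rows (the `samtools depth` default).
#' @return `path`, invisibly.
#' @export
writeDepthTable <- function(x, path, dropZeros = TRUE) {
  tb <- data.table::as.data.table(x@tbl)
  if (dropZeros) tb <- tb[tb$depth > 0L, ]
  data.table::fwrite(tb, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Look up per-base depth, zero-filled
#'
#' @param x a [DepthTable-class] object.
#' @param contig,pos parallel vectors of positions to query.
#' @return integer vector of depths (0 where the position is absent).
#' @export
depthAt <- function(x, contig, pos) {
  q <- data.table::data.table(contig = as.character(contig),
                              pos = as.integer(pos))
  tb <- x@tbl
  res <- tb[q, on = c("contig", "pos")]
  d <- res$depth
  d[is.na(d)] <- 0L
  as.integer(d)
}
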