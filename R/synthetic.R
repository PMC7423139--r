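#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom stats rbinom rpois setNames
NULL

.BASES <- c("A", "C", "G", "T")

randomBases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

# substitute positions idx with a uniformly-drawn *different* base
substituteBases <- function(chars, idx) {
  if (!length(idx)) return(chars)
  old <- chars[idx]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  pos <- match(old, .BASES)
  chars[idx] <- .BASES[((pos - 1L + shift) %% 4L) + 1L]
  chars
}

# percent identity of two equal-length strings, by byte comparison
strIdentity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  100 * mean(ra == rb)
}

#' Generate a synthetic diploid genome
#'
#' Draws a random background sequence at the requested GC content, embeds
#' tandem repeat-family arrays (each copy independently diverged from the
#' family consensus), then creates haplotype B by substituting a random
#' alternative base at heterozygous sites sampled at `hetRate` per bp.
#' Haplotype A doubles as the haploid consensus/reference. Deterministic
#' for a fixed seed.
#'
#' @param genomeLength total length in bp (>= 10 kb).
#' @param hetRate target heterozygous sites per bp, in `[0, 0.05]`.
#'   Default 0.0115 emulates a highly heterozygous nematode genome.
#' @param repeatSpec list with `nFamilies`, `copies`, `unitLength`,
#'   `divergence` (per-base divergence of each copy from the family
#'   consensus), or `NULL` for no repeats.
#' @param gc background GC fraction.
#' @param seed RNG seed.
#' @param contigName name of the single contig generated.
#' @return a [DiploidGenome-class] object.
#' @examples
#' g <- generateDiploid(genomeLength = 2e4, seed = 7)
#' g
#' @export
generateDiploid <- function(genomeLength = 1e6, hetRate = 0.0115,
                            repeatSpec = list(nFamilies = 2L, copies = 3L,
                                              unitLength = 2000L,
                                              divergence = 0.005),
                            gc = 0.40, seed = 1L, contigName = "ref1") {
  genomeLength <- as.integer(genomeLength)
  if (genomeLength < 1e4) stop("genomeLength must be >= 10 kb")
  if (hetRate < 0 || hetRate > 0.05) stop("hetRate must be in [0, 0.05]")
  set.seed(as.integer(seed))

  chars <- randomBases(genomeLength, gc)
  rep_gr <- GenomicRanges::GRanges()
  if (!is.null(repeatSpec) && repeatSpec$nFamilies > 0L) {
    nf <- as.integer(repeatSpec$nFamilies)
    nc <- as.integer(repeatSpec$copies)
    ul <- as.integer(repeatSpec$unitLength)
    dv <- repeatSpec$divergence
    arrayLen <- nc * ul
    if (nf * arrayLen > genomeLength)
      stop("repeat total (", nf * arrayLen, " bp) exceeds genome length")
    block <- genomeLength %/% nf
    if (arrayLen > block - 200L)
      stop("repeat arrays do not fit: shrink copies/unitLength or nFamilies")
    starts <- integer(nf); fams <- character(0)
    rows <- vector("list", nf * nc)
    k <- 0L
    for (f in seq_len(nf)) {
      fam <- sprintf("repfam%02d", f)
      lo <- (f - 1L) * block + 100L
      hi <- f * block - arrayLen - 100L
      astart <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      consensus <- randomBases(ul, gc)
      for (j in seq_len(nc)) {
        copy <- consensus
        nmut <- rbinom(1L, ul, dv)
        if (nmut > 0L) copy <- substituteBases(copy, sample.int(ul, nmut))
        s <- astart + (j - 1L) * ul
        chars[s:(s + ul - 1L)] <- copy
        k <- k + 1L
        rows[[k]] <- data.frame(
          contig = contigName, start = s, end = s + ul - 1L,
          family = fam, copy = j, divergence = dv,
          consensus = paste0(consensus, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    rd <- do.call(rbind, rows)
    rep_gr <- GenomicRanges::GRanges(rd$contig,
                                     IRanges::IRanges(rd$start, rd$end),
                                     family = rd$family, copy = rd$copy,
                                     divergence = rd$divergence,
                                     consensus = rd$consensus)
  }

  nsnp <- rbinom(1L, genomeLength, hetRate)
  snp_pos <- sort(sample.int(genomeLength, nsnp))
  charsB <- substituteBases(chars, snp_pos)
  snps <- data.frame(contig = rep(contigName, nsnp), pos = snp_pos,
                     ref = chars[snp_pos], alt = charsB[snp_pos],
                     stringsAsFactors = FALSE)

  hapA <- Biostrings::DNAStringSet(setNames(paste0(chars, collapse = ""),
                                            contigName))
  hapB <- Biostrings::DNAStringSet(setNames(paste0(charsB, collapse = ""),
                                            contigName))
  new("DiploidGenome", hapA = hapA, hapB = hapB, trueSnps = snps,
      hetRate = hetRate, repeats = rep_gr, gc = gc)
}

#' Build an artifact specification table
#'
#' Coordinates are 1-based closed intervals on the consensus (haplotype A).
#' Kinds: `expansion` (both haplotype copies of the region emitted as
#' separate contigs), `collapse` (`factor` adjacent repeat copies merged
#' into one consensus copy), `bubble_fragmentation` (up to
#' `2^n_snp_clusters` allelic path contigs emitted over the region) and
#' `none` (annotated but untouched).
#'
#' @param artifact_id,kind,contig,start,end parallel vectors.
#' @param factor fold value: copies emitted (expansion, default 2) or
#'   repeat copies merged (collapse); must be >= 2 for both kinds.
#' @param n_snp_clusters number of heterozygous-site clusters driving the
#'   bubble paths (>= 1 for `bubble_fragmentation`).
#' @return validated data.frame of artifacts.
#' @export
artifactTable <- function(artifact_id, kind, contig, start, end,
                          factor = NA_real_, n_snp_clusters = NA_integer_) {
  df <- data.frame(artifact_id = as.character(artifact_id),
                   kind = as.character(kind), contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   factor = as.numeric(factor),
                   n_snp_clusters = as.integer(n_snp_clusters),
                   stringsAsFactors = FALSE)
  ok_kind <- c("expansion", "collapse", "bubble_fragmentation", "none")
  if (any(!df$kind %in% ok_kind))
    stop("unknown artifact kind: ", setdiff(df$kind, ok_kind)[1L])
  df$factor[df$kind == "expansion" & is.na(df$factor)] <- 2
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("artifact regions need 1 <= start <= end")
  need_f <- df$kind %in% c("expansion", "collapse")
  if (any(need_f & (is.na(df$factor) | df$factor < 2)))
    stop("factor must be >= 2 for expansion/collapse artifacts")
  bub <- df$kind == "bubble_fragmentation"
  if (any(bub & (is.na(df$n_snp_clusters) | df$n_snp_clusters < 1L)))
    stop("bubble_fragmentation needs n_snp_clusters >= 1")
  if (anyDuplicated(df$artifact_id)) stop("artifact ids must be unique")
  .checkArtifactOverlap(df)
  df[order(df$contig, df$start), ]
}

.checkArtifactOverlap <- function(df) {
  for (ctg in unique(df$contig)) {
    d <- df[df$contig == ctg, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
      stop("artifact regions overlap on contig ", ctg)
  }
  invisible(df)
}

#' @rdname artifactTable
#' @return `emptyArtifactTable()`: a zero-row artifact table.
#' @export
emptyArtifactTable <- function() {
  data.frame(artifact_id = character(), kind = character(),
             contig = character(), start = integer(), end = integer(),
             factor = numeric(), n_snp_clusters = integer(),
             stringsAsFactors = FALSE)
}

#' Derive a collapse artifact from a genome's repeat array
#'
#' @param genome a [DiploidGenome-class].
#' @param family repeat family id (as in `repeatAnnotations(genome)`).
#' @param artifact_id id for the new artifact.
#' @return one-row artifact table collapsing all copies of the family.
#' @export
collapseArtifactFor <- function(genome, family, artifact_id = family) {
  rp <- genome@repeats[genome@repeats$family == family]
  if (!length(rp)) stop("no repeat family '", family, "' in genome")
  artifactTable(artifact_id, "collapse",
                as.character(GenomicRanges::seqnames(rp))[1L],
                min(BiocGenerics::start(rp)), max(BiocGenerics::end(rp)),
                factor = length(rp))
}

#' Find a window clear of repeat arrays and other regions
#'
#' Scans a contig left to right and returns the first `width`-bp window
#' that keeps `margin` bp clear of every repeat copy, every interval in
#' `avoid`, and both contig ends. Useful for placing artifacts on a
#' generated genome without colliding with its repeat arrays.
#'
#' @param genome a [DiploidGenome-class].
#' @param width window width in bp.
#' @param contig contig to scan (default: first).
#' @param avoid optional data.frame with `start`/`end` columns (e.g. an
#'   [artifactTable()]) of regions to stay clear of.
#' @param margin clearance in bp (default 500).
#' @return integer vector `c(start, end)`, 1-based closed.
#' @export
freeWindow <- function(genome, width, contig = names(genome@hapA)[1L],
                       avoid = NULL, margin = 500L) {
  L <- Biostrings::width(genome@hapA)[match(contig, names(genome@hapA))]
  busy <- data.frame(start = integer(0), end = integer(0))
  rp <- genome@repeats[as.character(GenomicRanges::seqnames(genome@repeats))
                       == contig]
  if (length(rp))
    busy <- rbind(busy, data.frame(start = BiocGenerics::start(rp),
                                   end = BiocGenerics::end(rp)))
  if (!is.null(avoid) && nrow(avoid)) {
    av <- if ("contig" %in% names(avoid))
      avoid[avoid$contig == contig, , drop = FALSE] else avoid
    busy <- rbind(busy, av[, c("start", "end")])
  }
  s <- margin + 1L
  while (s + width - 1L <= L - margin) {
    e <- s + width - 1L
    clash <- nrow(busy) && any(busy$start <= e + margin &
                               busy$end >= s - margin)
    if (!clash) return(c(start = s, end = e))
    s <- min(busy$end[busy$start <= e + margin & busy$end >= s - margin]) +
      margin + 1L
  }
  stop("no free ", width, " bp window on contig ", contig)
}

.BUBBLE_PATH_CAP <- 1024L  # 2^10 paths per region at most

#' Derive a test assembly carrying injected artifacts
#'
#' Outside artifact regions the assembly equals the consensus (haplotype
#' A). An expansion artifact excises its region from the backbone contig
#' (splitting it) and emits both haplotype copies as separate contigs, so
#' total length grows by the region length. A collapse artifact replaces
#' its `factor` adjacent repeat copies with one per-column majority
#' consensus copy inline, shedding `(factor-1) * unit` bp. A
#' bubble-fragmentation artifact excises its region and emits up to
#' `2^n_snp_clusters` allelic path contigs (capped at 1024), each a full
#' copy of the region with one combination of haplotype alleles.
#'
#' @param genome a [DiploidGenome-class].
#' @param artifacts an [artifactTable()] data.frame.
#' @param label assembly label.
#' @param seed unused at present (the construction is deterministic);
#'   retained for interface stability.
#' @return a [SyntheticAssembly-class] object.
#' @export
makeTestAssembly <- function(genome, artifacts = emptyArtifactTable(),
                             label = "synthetic-assembly", seed = 1L) {
  widths <- setNames(Biostrings::width(genome@hapA), names(genome@hapA))
  if (nrow(artifacts)) {
    if (any(!artifacts$contig %in% names(widths)))
      stop("artifact on unknown contig")
    if (any(artifacts$end > widths[artifacts$contig]))
      stop("artifact region extends past the end of its contig")
    .checkArtifactOverlap(artifacts)
    artifacts <- artifacts[order(artifacts$contig, artifacts$start), ,
                           drop = FALSE]
  }
  aChars <- lapply(as.character(genome@hapA), function(s) strsplit(s, "")[[1L]])
  bChars <- lapply(as.character(genome@hapB), function(s) strsplit(s, "")[[1L]])

  seq_out <- list(); map_rows <- list(); truth_rows <- list()
  mi <- 0L
  add_map <- function(contig, cs, ce, sc, ss, se, role, aid, fac, npaths) {
    mi <<- mi + 1L
    map_rows[[mi]] <<- data.frame(
      contig = contig, ctg_start = cs, ctg_end = ce, src_contig = sc,
      src_start = ss, src_end = se, role = role, artifact_id = aid,
      factor = fac, n_paths = npaths, stringsAsFactors = FALSE)
  }

  for (src in names(widths)) {
    L <- widths[[src]]
    arts <- artifacts[artifacts$contig == src & artifacts$kind != "none", ,
                      drop = FALSE]
    ca <- aChars[[src]]; cb <- bChars[[src]]
    # backbone accumulator: list of (chars, src_start, src_end, role, ...)
    segs <- list(); part <- 0L
    n_backbone_expected <- 1L +
      sum(arts$kind %in% c("expansion", "bubble_fragmentation"))
    bb_name <- function(i) {
      if (n_backbone_expected == 1L) src else sprintf("%s_part%d", src, i)
    }
    flush_backbone <- function() {
      if (!length(segs)) return(invisible())
      part <<- part + 1L
      nm <- bb_name(part)
      offs <- 1L
      chunks <- character(length(segs))
      for (i in seq_along(segs)) {
        sg <- segs[[i]]
        w <- length(sg$chars)
        add_map(nm, offs, offs + w - 1L, src, sg$ss, sg$se, sg$role,
                sg$aid, sg$fac, NA_integer_)
        offs <- offs + w
        chunks[i] <- paste0(sg$chars, collapse = "")
      }
      seq_out[[nm]] <<- paste0(chunks, collapse = "")
      segs <<- list()
    }
    push_normal <- function(s, e) {
      if (e >= s)
        segs[[length(segs) + 1L]] <<- list(chars = ca[s:e], ss = s, se = e,
                                           role = "normal", aid = NA_character_,
                                           fac = NA_real_)
    }

    pos <- 1L
    if (nrow(arts)) for (i in seq_len(nrow(arts))) {
      a <- arts[i, ]
      push_normal(pos, a$start - 1L)
      if (a$kind == "collapse") {
        span <- a$end - a$start + 1L
        fac <- as.integer(a$factor)
        if (span %% fac != 0L)
          stop("collapse region of ", a$artifact_id,
               " does not divide evenly into ", fac, " copies")
        unit <- span %/% fac
        copies <- matrix(ca[a$start:a$end], nrow = unit)
        kept <- apply(copies, 1L, function(col) names(which.max(table(col))))
        segs[[length(segs) + 1L]] <- list(chars = kept, ss = a$start,
                                          se = a$end, role = "collapse",
                                          aid = a$artifact_id, fac = a$factor)
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(a, n_paths = NA_integer_, unit = unit)
      } else if (a$kind == "expansion") {
        flush_backbone()
        for (hap in c("a", "b")) {
          nm <- sprintf("%s_%s", a$artifact_id, hap)
          chars <- if (hap == "a") ca[a$start:a$end] else cb[a$start:a$end]
          seq_out[[nm]] <- paste0(chars, collapse = "")
          add_map(nm, 1L, a$end - a$start + 1L, src, a$start, a$end,
                  sprintf("exp_hap%s", toupper(hap)), a$artifact_id,
                  a$factor, NA_integer_)
        }
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(a, n_paths = NA_integer_, unit = NA_integer_)
      } else if (a$kind == "bubble_fragmentation") {
        flush_backbone()
        snp_in <- genome@trueSnps[genome@trueSnps$contig == src &
                                  genome@trueSnps$pos >= a$start &
                                  genome@trueSnps$pos <= a$end, , drop = FALSE]
        ncl <- min(a$n_snp_clusters, max(1L, nrow(snp_in)))
        if (nrow(snp_in) == 0L) ncl <- 0L
        grp <- if (ncl > 0L)
          pmin(ncl, ceiling(seq_len(nrow(snp_in)) / (nrow(snp_in) / ncl)))
        npaths <- min(2L^ncl, .BUBBLE_PATH_CAP)
        base <- ca[a$start:a$end]
        for (k in seq_len(npaths)) {
          chars <- base
          if (ncl > 0L) {
            bits <- as.integer(intToBits(k - 1L))[seq_len(ncl)]
            use_b <- snp_in$pos[grp %in% which(bits == 1L)]
            if (length(use_b))
              chars[use_b - a$start + 1L] <- cb[use_b]
          }
          nm <- sprintf("%s_p%04d", a$artifact_id, k)
          seq_out[[nm]] <- paste0(chars, collapse = "")
          add_map(nm, 1L, a$end - a$start + 1L, src, a$start, a$end,
                  "bubble", a$artifact_id, NA_real_, npaths)
        }
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(a, n_paths = npaths, unit = NA_integer_)
      }
      pos <- a$end + 1L
    }
    push_normal(pos, L)
    flush_backbone()
  }
  none_rows <- artifacts[artifacts$kind == "none", , drop = FALSE]
  if (nrow(none_rows))
    truth_rows <- c(truth_rows,
                    list(cbind(none_rows, n_paths = NA_integer_,
                               unit = NA_integer_)))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    cbind(emptyArtifactTable(), n_paths = integer(), unit = integer())
  rownames(truth) <- NULL
  seqs <- assemblySeqs(unlist(seq_out), label = label)
  new("SyntheticAssembly", seqs = seqs,
      contigMap = do.call(rbind, map_rows), truth = truth)
}

#' The reference rendered as an artifact-free assembly
#'
#' Convenience wrapper: the consensus contigs with no artifacts, keeping
#' their original names, so the reference side of the pipeline runs
#' through the same code path as any test assembly.
#'
#' @param genome a [DiploidGenome-class].
#' @param label assembly label.
#' @return a [SyntheticAssembly-class].
#' @export
referenceAssembly <- function(genome, label = "reference") {
  makeTestAssembly(genome, emptyArtifactTable(), label = label)
}

# expected mean read depth for one contig-map row
.rowLambda <- function(role, factor, n_paths, baseDepth) {
  switch(role,
         normal = baseDepth,
         collapse = baseDepth * factor,
         exp_hapA = baseDepth / 2,
         exp_hapB = baseDepth / 2,
         bubble = baseDepth / n_paths,
         stop("unknown contig-map role: ", role))
}

#' Simulate the depth profile and SNP calls an assembly would produce
#'
#' Encodes the expansion/collapse signature model directly, bypassing
#' read-level simulation: per-base depth is Poisson around the base depth
#' in normal regions, around half of it on each contig of an expanded
#' allelic pair (reads split between the alleles; `base/n_paths` for
#' bubble paths), and around `factor` times it in collapsed regions.
#' Heterozygous calls are emitted at the genome's true SNPs in normal
#' regions, suppressed inside expanded/bubble regions (each allele has its
#' own contig to map to), and emitted inside collapsed regions wherever a
#' merged repeat copy disagrees with the kept consensus or a haplotype
#' difference projects onto the kept copy.
#'
#' @param assembly a [SyntheticAssembly-class].
#' @param genome the [DiploidGenome-class] it derives from.
#' @param baseDepth mean fold-coverage of a correctly assembled diploid
#'   region (>= 10); default 60.
#' @param seed RNG seed.
#' @param mismapRate residual rate at which suppressed heterozygous sites
#'   still produce a call inside expanded regions (default 0, the
#'   idealized limit of perfect allele-aware mapping).
#' @return list with `depth` (a [DepthTable-class]) and `snps`
#'   (data.frame in [snpTable()] layout, coordinates on the assembly).
#' @export
simulateMappingProfile <- function(assembly, genome, baseDepth = 60,
                                   seed = 1L, mismapRate = 0) {
  if (baseDepth < 10) stop("baseDepth must be >= 10")
  set.seed(as.integer(seed))
  cm <- assembly@contigMap
  aChars <- lapply(as.character(genome@hapA), function(s) strsplit(s, "")[[1L]])
  asmChars <- lapply(as.character(assembly@seqs),
                     function(s) strsplit(s, "")[[1L]])
  snpsrc <- genome@trueSnps

  depth_list <- vector("list", nrow(cm))
  snp_list <- list(); si <- 0L
  add_snps <- function(df) { si <<- si + 1L; snp_list[[si]] <<- df }

  for (i in seq_len(nrow(cm))) {
    r <- cm[i, ]
    w <- r$ctg_end - r$ctg_start + 1L
    lam <- .rowLambda(r$role, r$factor, r$n_paths, baseDepth)
    depth_list[[i]] <- data.frame(
      contig = r$contig, pos = seq.int(r$ctg_start, r$ctg_end),
      depth = rpois(w, lam), stringsAsFactors = FALSE)

    insrc <- snpsrc[snpsrc$contig == r$src_contig &
                    snpsrc$pos >= r$src_start & snpsrc$pos <= r$src_end, ,
                    drop = FALSE]
    if (r$role == "normal") {
      if (nrow(insrc))
        add_snps(data.frame(contig = r$contig,
                            pos = insrc$pos - r$src_start + r$ctg_start,
                            ref = insrc$ref, alt = insrc$alt,
                            stringsAsFactors = FALSE))
    } else if (r$role == "collapse") {
      span <- r$src_end - r$src_start + 1L
      fac <- as.integer(r$factor)
      unit <- span %/% fac
      kept <- asmChars[[r$contig]][r$ctg_start:r$ctg_end]
      copies <- matrix(aChars[[r$src_contig]][r$src_start:r$src_end],
                       nrow = unit)
      div_pos <- which(apply(copies != kept, 1L, any))
      upos <- integer(0); alts <- character(0)
      if (length(div_pos)) {
        upos <- div_pos
        alts <- vapply(div_pos, function(u) {
          dd <- copies[u, copies[u, ] != kept[u]]
          dd[1L]
        }, character(1L))
      }
      if (nrow(insrc)) {
        hp <- ((insrc$pos - r$src_start) %% unit) + 1L
        keep <- !(hp %in% upos)
        upos <- c(upos, hp[keep])
        alts <- c(alts, ifelse(insrc$alt[keep] != kept[hp[keep]],
                               insrc$alt[keep], insrc$ref[keep]))
      }
      if (length(upos)) {
        o <- order(upos)
        dup <- duplicated(upos[o])
        add_snps(data.frame(contig = r$contig,
                            pos = r$ctg_start + upos[o][!dup] - 1L,
                            ref = kept[upos[o][!dup]], alt = alts[o][!dup],
                            stringsAsFactors = FALSE))
      }
    } else {  # exp_hapA / exp_hapB / bubble: allele-split regions
      if (mismapRate > 0 && nrow(insrc)) {
        keep <- stats::runif(nrow(insrc)) < mismapRate
        if (any(keep))
          add_snps(data.frame(contig = r$contig,
                              pos = insrc$pos[keep] - r$src_start + r$ctg_start,
                              ref = insrc$ref[keep], alt = insrc$alt[keep],
                              stringsAsFactors = FALSE))
      }
    }
  }
  depth <- depthTable(data.table::rbindlist(depth_list))
  snps <- if (si) do.call(rbind, snp_list) else
    emptySnpTable()[, c("contig", "pos", "ref", "alt")]
  snps <- snpTable(snps$contig, snps$pos, snps$ref, snps$alt)
  list(depth = depth, snps = snps)
}
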