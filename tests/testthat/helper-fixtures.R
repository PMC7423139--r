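# Shared synthetic fixtures, built once per test run and cached.

gr <- function(contig, start, end) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
}

# small diploid genome at study-like settings
demoGenome <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 101L, genomeLength = 1e5) {
    key <- paste0(seed, "_", genomeLength)
    if (is.null(cache[[key]]))
      cache[[key]] <- generateDiploid(genomeLength = genomeLength,
                                      seed = seed)
    cache[[key]]
  }
})

# a full artifact scenario: expansion + collapse + bubble, genes in each,
# mapping profiles for test and reference, and emitted alignment tables
demoScenario <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- demoGenome(seed = 207L)
    ew <- freeWindow(g, 10000L)
    arts <- rbind(
      artifactTable("exp1", "expansion", "ref1", ew[1], ew[2]),
      collapseArtifactFor(g, "repfam01", "col1"))
    bw <- freeWindow(g, 800L, avoid = arts)
    arts <- rbind(arts, artifactTable("bub1", "bubble_fragmentation",
                                      "ref1", bw[1], bw[2],
                                      n_snp_clusters = 2L))
    asm <- makeTestAssembly(g, arts, label = "demo-test", seed = 207L)
    rp <- repeatAnnotations(g)
    r1 <- rp[rp$family == "repfam01"]
    nw1 <- freeWindow(g, 2500L, avoid = arts)
    nw2 <- freeWindow(g, 2500L,
                      avoid = rbind(arts[, c("contig", "start", "end")],
                                    data.frame(contig = "ref1",
                                               start = nw1[1],
                                               end = nw1[2])))
    genes <- c(
      gr("ref1", ew[1] + c(500L, 3500L, 6500L),
         ew[1] + c(500L, 3500L, 6500L) + 1999L),
      gr("ref1", BiocGenerics::start(r1)[1] + c(100L, 1100L),
         BiocGenerics::start(r1)[1] + c(100L, 1100L) + 799L),
      gr("ref1", c(nw1[1], nw2[1]), c(nw1[2], nw2[2])))
    names(genes) <- c("gE1", "gE2", "gE3", "gC1", "gC2", "gN1", "gN2")
    sets <- data.frame(
      gene_id = names(genes),
      set_id = rep(c("exp_set", "col_set", "norm_set"), c(3L, 2L, 2L)),
      stringsAsFactors = FALSE)
    ref <- referenceAssembly(g)
    cache <<- list(
      genome = g, artifacts = arts, assembly = asm, reference = ref,
      genes = genes, sets = sets,
      tabs = emitAlignmentTables(asm, g, genes, seed = 207L),
      profTest = simulateMappingProfile(asm, g, 60, seed = 207L),
      profRef = simulateMappingProfile(ref, g, 60, seed = 208L))
    cache
  }
})

# brute-force N50: the largest member length L with sum(lengths >= L)
# covering at least half the total
n50Oracle <- function(lengths) {
  ok <- vapply(lengths, function(L) sum(lengths[lengths >= L]) >=
                 sum(lengths) / 2, logical(1L))
  max(lengths[ok])
}

# per-base bitmap union of intervals on one or more contigs
bitmapUnionBp <- function(contig, start, end, maxPos = 2000L) {
  total <- 0L
  for (ctg in unique(contig)) {
    bits <- logical(maxPos)
    sel <- contig == ctg
    for (i in which(sel)) bits[start[i]:end[i]] <- TRUE
    total <- total + sum(bits)
  }
  total
}
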