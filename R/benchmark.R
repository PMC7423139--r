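#' One-call parameter-recovery benchmark on a synthetic genome
#'
#' Generates a diploid genome with one tandem repeat family, injects a
#' 12 kb two-fold allelic expansion and a three-copy repeat collapse,
#' places three genes inside the expansion, two inside the first repeat
#' copy and three in untouched sequence, simulates the mapping profiles
#' of the test assembly and of the reference, emits the alignment tables,
#' and runs the full regional ratio analysis. The returned ratios should
#' recover the injected factors: length ratio near 2 with coverage near
#' 0.5 and heterozygosity near 0 for the expansion set, length near 1/3
#' with coverage near 3 and elevated heterozygosity for the collapse set.
#'
#' @param genomeLength genome size in bp (>= 50 kb so every feature
#'   fits; default 1 Mb).
#' @param seed RNG seed driving the whole scenario.
#' @param baseDepth mean diploid fold-coverage (default 60).
#' @param hetRate heterozygous sites per bp (default 0.0115).
#' @return list with `genome`, `assembly`, `genes`, `sets`, `ratios`
#'   (per region set, with classifications) and `regional` (the full
#'   [regionSetAnalysis()] output).
#' @examples
#' b <- syntheticBenchmark(genomeLength = 8e4, seed = 1)
#' b$ratios[, c("region_set_id", "het_ratio", "cov_ratio", "len_ratio",
#'              "classification")]
#' @export
syntheticBenchmark <- function(genomeLength = 1e6, seed = 1L,
                               baseDepth = 60, hetRate = 0.0115) {
  if (genomeLength < 5e4) stop("genomeLength must be >= 50 kb")
  g <- generateDiploid(genomeLength, hetRate = hetRate,
                       repeatSpec = list(nFamilies = 1L, copies = 3L,
                                         unitLength = 2000L,
                                         divergence = 0.005),
                       seed = seed)
  ew <- freeWindow(g, 12000L)
  arts <- rbind(
    artifactTable("exp1", "expansion", "ref1", ew[1], ew[2]),
    collapseArtifactFor(g, "repfam01", "col1"))
  asm <- makeTestAssembly(g, arts, label = "benchmark", seed = seed)
  rp <- repeatAnnotations(g)
  c1 <- BiocGenerics::start(rp[rp$family == "repfam01"])[1L]
  nw <- freeWindow(g, 8500L, avoid = arts)
  starts <- c(ew[1] + c(500L, 4500L, 8500L), c1 + c(100L, 1100L),
              nw[1] + c(0L, 3000L, 6000L))
  widths <- c(2000L, 2000L, 2000L, 800L, 800L, 2500L, 2500L, 2500L)
  genes <- GenomicRanges::GRanges("ref1",
                                  IRanges::IRanges(starts,
                                                   starts + widths - 1L))
  names(genes) <- c("gE1", "gE2", "gE3", "gC1", "gC2", "gN1", "gN2", "gN3")
  sets <- data.frame(
    gene_id = names(genes),
    set_id = rep(c("exp_set", "col_set", "norm_set"), c(3L, 2L, 3L)),
    stringsAsFactors = FALSE)
  tabs <- emitAlignmentTables(asm, g, genes, seed = seed)
  prof_t <- simulateMappingProfile(asm, g, baseDepth, seed = seed)
  prof_r <- simulateMappingProfile(referenceAssembly(g), g, baseDepth,
                                   seed = seed + 1L)
  res <- regionSetAnalysis(tabs$transcripts, tabs$regions, prof_t$snps,
                           prof_t$depth, prof_r$snps, prof_r$depth, sets)
  list(genome = g, assembly = asm, genes = genes, sets = sets,
       ratios = res$ratios, regional = res)
}
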