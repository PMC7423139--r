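test_that("zero heterozygosity yields identical haplotypes", {
  g <- generateDiploid(genomeLength = 2e4, hetRate = 0, repeatSpec = NULL,
                       seed = 5)
  expect_identical(as.character(hapA(g)), as.character(hapB(g)))
  expect_equal(nrow(trueSnps(g)), 0L)
})

test_that("identical seeds reproduce the genome byte for byte", {
  g1 <- generateDiploid(genomeLength = 2e4, seed = 9)
  g2 <- generateDiploid(genomeLength = 2e4, seed = 9)
  expect_identical(as.character(hapA(g1)), as.character(hapA(g2)))
  expect_identical(as.character(hapB(g1)), as.character(hapB(g2)))
  expect_identical(trueSnps(g1), trueSnps(g2))
  g3 <- generateDiploid(genomeLength = 2e4, seed = 10)
  expect_false(identical(as.character(hapA(g1)), as.character(hapA(g3))))
})

test_that("SNP count lands within 4 binomial SD of the target rate", {
  g <- generateDiploid(genomeLength = 1e6, hetRate = 0.0115, seed = 31)
  expected <- 1e6 * 0.0115
  sd <- sqrt(1e6 * 0.0115 * (1 - 0.0115))
  expect_lt(abs(nrow(trueSnps(g)) - expected), 4 * sd)
  # hapB really differs from hapA exactly at the recorded sites
  a <- strsplit(as.character(hapA(g))[[1]], "")[[1]]
  b <- strsplit(as.character(hapB(g))[[1]], "")[[1]]
  expect_identical(which(a != b), trueSnps(g)$pos)
})

test_that("repeat arrays exceeding the genome are rejected", {
  expect_error(
    generateDiploid(genomeLength = 1e4,
                    repeatSpec = list(nFamilies = 3, copies = 3,
                                      unitLength = 2000, divergence = 0.005),
                    seed = 1),
    "exceed|fit")
})

test_that("artifact construction obeys the length-conservation accounting", {
  sc <- demoScenario()
  tr <- artifactTruth(sc$assembly)
  gain_exp <- sum(tr$end[tr$kind == "expansion"] -
                  tr$start[tr$kind == "expansion"] + 1L)
  loss_col <- sum((tr$factor[tr$kind == "collapse"] - 1) *
                  tr$unit[tr$kind == "collapse"])
  bub <- tr[tr$kind == "bubble_fragmentation", ]
  gain_bub <- sum((bub$n_paths - 1L) * (bub$end - bub$start + 1L))
  expect_equal(sum(Biostrings::width(assemblySequences(sc$assembly))),
               sum(Biostrings::width(hapA(sc$genome))) +
                 gain_exp - loss_col + gain_bub)
})

test_that("expansion emits both haplotype copies; collapse keeps one unit", {
  sc <- demoScenario()
  cm <- contigMap(sc$assembly)
  exp_rows <- cm[cm$artifact_id %in% "exp1", ]
  expect_setequal(exp_rows$role, c("exp_hapA", "exp_hapB"))
  aA <- as.character(assemblySequences(sc$assembly)[["exp1_a"]])
  expect_identical(
    aA, substr(as.character(hapA(sc$genome))[[1]],
               exp_rows$src_start[1], exp_rows$src_end[1]))
  col <- cm[cm$role %in% "collapse", ]
  expect_equal(col$ctg_end - col$ctg_start + 1L,
               (col$src_end - col$src_start + 1L) %/% as.integer(col$factor))
})

test_that("bubble regions emit at most 2^n path contigs, capped at 1024", {
  sc <- demoScenario()
  tr <- artifactTruth(sc$assembly)
  bub <- tr[tr$kind == "bubble_fragmentation", ]
  expect_lte(bub$n_paths, 2^bub$n_snp_clusters)
  cm <- contigMap(sc$assembly)
  expect_equal(sum(cm$role == "bubble"), bub$n_paths)

  g <- demoGenome(seed = 301L, genomeLength = 3e4)
  w <- freeWindow(g, 5000L)
  a <- makeTestAssembly(g, artifactTable("bb", "bubble_fragmentation",
                                         "ref1", w[1], w[2],
                                         n_snp_clusters = 12L))
  expect_equal(sum(contigMap(a)$role == "bubble"), 1024L)
})

test_that("depth profile matches the signature model region by region", {
  sc <- demoScenario()
  d <- sc$profTest$depth
  cm <- contigMap(sc$assembly)
  md <- function(role) {
    r <- cm[cm$role == role, ][1, ]
    regionalDepth(d, gr(r$contig, r$ctg_start, r$ctg_end))
  }
  expect_lt(abs(md("exp_hapA") - 30) / 30, 0.10)
  expect_lt(abs(md("exp_hapB") - 30) / 30, 0.10)
  expect_lt(abs(md("collapse") - 180) / 180, 0.10)
  norm <- cm[cm$role == "normal", ]
  norm <- norm[which.max(norm$ctg_end - norm$ctg_start), ]
  expect_lt(abs(regionalDepth(d, gr(norm$contig, norm$ctg_start,
                                    norm$ctg_end)) - 60) / 60, 0.05)
})

test_that("an artifact-free zero-het genome gives an empty VCF and flat depth", {
  g <- generateDiploid(genomeLength = 2e4, hetRate = 0, repeatSpec = NULL,
                       seed = 77)
  prof <- simulateMappingProfile(referenceAssembly(g), g, baseDepth = 60,
                                 seed = 77)
  expect_equal(nrow(prof$snps), 0L)
  m <- mean(as.data.frame(prof$depth)$depth)
  se <- sqrt(60 / 2e4)
  expect_lt(abs(m - 60), 3 * se)
})

test_that("heterozygous calls are suppressed in expanded regions and enriched in collapsed ones", {
  sc <- demoScenario()
  snps <- sc$profTest$snps
  cm <- contigMap(sc$assembly)
  exp_ctgs <- cm$contig[cm$role %in% c("exp_hapA", "exp_hapB", "bubble")]
  expect_equal(sum(snps$contig %in% exp_ctgs), 0L)
  col <- cm[cm$role == "collapse", ][1, ]
  het_col <- sum(snps$contig == col$contig & snps$pos >= col$ctg_start &
                 snps$pos <= col$ctg_end) / (col$ctg_end - col$ctg_start + 1)
  expect_gt(het_col, 1.5 * 0.0115)
})

test_that("emitted alignment coordinates stay within sequence bounds", {
  sc <- demoScenario()
  wa <- stats::setNames(Biostrings::width(assemblySequences(sc$assembly)),
                        names(assemblySequences(sc$assembly)))
  wr <- stats::setNames(Biostrings::width(hapA(sc$genome)),
                        names(hapA(sc$genome)))
  tt <- sc$tabs$transcripts
  expect_true(all(tt$sstart >= 1 & tt$send <= wa[tt$sseqid]))
  rr <- sc$tabs$regions
  expect_true(all(rr$sstart >= 1 & rr$send <= wr[rr$sseqid]))
  ar <- sc$tabs$asmref
  expect_true(all(ar$qstart >= 1 & ar$qend <= wa[ar$qseqid]))
  expect_true(all(ar$sstart >= 1 & ar$send <= wr[ar$sseqid]))
})

test_that("expanded genes yield two overlapping hits near the expected identities", {
  sc <- demoScenario()
  rr <- sc$tabs$regions[sc$tabs$regions$qseqid %in%
                          c("gE1@exp1_a", "gE1@exp1_b"), ]
  expect_equal(nrow(rr), 2L)
  expect_equal(rr$sstart[1], rr$sstart[2])  # same reference span
  expect_setequal(round(rr$pident) >= 98, c(TRUE, TRUE))
  expect_equal(max(rr$pident), 100)          # hapA copy is exact
  expect_lt(min(rr$pident), 100)             # hapB copy carries the snps
  expect_gt(min(rr$pident), 100 * (1 - 3 * 0.0115))
})

test_that("the synthetic bundle is byte-identical across reruns of one seed", {
  sc <- demoScenario()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- writeSyntheticBundle(d1, sc$genome, sc$assembly, sc$genes, sc$sets,
                             baseDepth = 60, seed = 99)
  f2 <- writeSyntheticBundle(d2, sc$genome, sc$assembly, sc$genes, sc$sets,
                             baseDepth = 60, seed = 99)
  for (k in names(f1))
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])), label = k)
})
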