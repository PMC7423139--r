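test_that("gene regions span min..max of qualifying exon hits", {
  h <- alignmentHits(qseqid = c("g1", "g1", "g2"),
                     sseqid = c("c1", "c1", "c1"),
                     pident = c(95, 99, 91.9),
                     qstart = c(1, 101, 1), qend = c(100, 250, 100),
                     sstart = c(100, 500, 900), send = c(199, 649, 999))
  eg <- extractGeneRegions(h)
  expect_equal(length(eg$regions), 1L)  # g2's only hit is below 92
  r <- eg$regions["g1@c1"]
  expect_equal(BiocGenerics::start(r), 100)
  expect_equal(BiocGenerics::end(r), 649)
  expect_equal(r$n_exon_hits, 2L)
})

test_that("regions wider than the gene-span cap are excluded with a reason", {
  h <- alignmentHits(qseqid = c("g1", "g1"), sseqid = "c1",
                     pident = c(99, 99), qstart = c(1, 101),
                     qend = c(100, 200), sstart = c(1, 10401),
                     send = c(100, 10500))
  eg <- extractGeneRegions(h, maxGeneSpan = 10000)
  expect_equal(length(eg$regions), 0L)
  expect_equal(eg$excluded$reason, "span_over_max")
  expect_equal(eg$excluded$span, 10500L)
})

test_that("genes hitting several contigs yield one region per contig and are reported", {
  h <- alignmentHits(qseqid = c("g1", "g1"), sseqid = c("cA", "cB"),
                     pident = c(99, 99), qstart = c(1, 1),
                     qend = c(100, 100), sstart = c(1, 51),
                     send = c(100, 150))
  eg <- extractGeneRegions(h)
  expect_setequal(names(eg$regions), c("g1@cA", "g1@cB"))
  expect_equal(eg$multiContigGenes, "g1")
})

test_that("regional heterozygosity counts sites inside the region", {
  s <- snpTable(rep("c1", 3), c(110, 210, 290), rep("A", 3), rep("T", 3))
  expect_equal(regionalHeterozygosity(s, gr("c1", 101, 400)), 0.01)
  expect_equal(regionalHeterozygosity(s, gr("c1", 500, 600)), 0)
  expect_equal(regionalHeterozygosity(s, gr("c2", 101, 400)), 0)
})

test_that("whole-genome regional heterozygosity equals the total", {
  g <- demoGenome(seed = 101L)
  ref <- referenceAssembly(g)
  prof <- simulateMappingProfile(ref, g, seed = 101L)
  L <- sum(Biostrings::width(hapA(g)))
  expect_identical(
    regionalHeterozygosity(prof$snps, gr("ref1", 1, L)),
    totalHeterozygosity(prof$snps, assemblySequences(ref)))
})

test_that("regional depth zero-fills and matches per-base summation", {
  d <- depthTable(data.frame(contig = "c1", pos = 1:50, depth = 30L))
  expect_equal(regionalDepth(d, gr("c1", 1, 50)), 30)
  expect_equal(regionalDepth(d, gr("c1", 1, 100)), 15)  # half absent
  set.seed(13)
  tab <- data.frame(contig = "cX", pos = sample.int(400, 250),
                    depth = sample.int(80, 250, replace = TRUE))
  d2 <- depthTable(tab)
  for (i in 1:20) {
    s <- sample.int(350, 1); e <- s + sample.int(50, 1)
    expect_equal(regionalDepth(d2, gr("cX", s, e)),
                 sum(tab$depth[tab$pos >= s & tab$pos <= e]) / (e - s + 1))
  }
})

test_that("reference matching applies the strict identity threshold", {
  h <- alignmentHits(qseqid = c("r1", "r1", "r2"), sseqid = "ref",
                     pident = c(97.9, 99, 98), qstart = 1, qend = 100,
                     sstart = c(1, 201, 900), send = c(100, 300, 999))
  mm <- matchReferenceRegions(h, 98)
  expect_equal(length(mm$matches), 2L)
  expect_equal(mm$matches$region_id, c("r1", "r2"))
  expect_equal(BiocGenerics::start(mm$matches), c(201, 900))
  h2 <- alignmentHits("r3", "ref", 97, 1, 100, 1, 100)
  expect_equal(matchReferenceRegions(h2, 98)$unresolved, "r3")
})

test_that("reversed-orientation hits come back as forward reference intervals", {
  h <- alignmentHits("r1", "ref", 99, 1, 100, 500, 401)
  mm <- matchReferenceRegions(h, 98)
  expect_equal(BiocGenerics::start(mm$matches), 401)
  expect_equal(BiocGenerics::end(mm$matches), 500)
})

test_that("HSP collapsing merges overlaps and matches a bitmap union oracle", {
  iv <- gr(c("c1", "c1"), c(1, 50), c(100, 150))
  out <- collapseHsps(iv)
  expect_equal(length(out$intervals), 1L)
  expect_equal(out$uniqueBp, 150)
  dis <- gr(c("c1", "c1"), c(1, 200), c(100, 250))
  expect_equal(collapseHsps(dis)$uniqueBp, 151)
  set.seed(17)
  for (i in 1:200) {
    n <- sample.int(12, 1)
    ctg <- sample(c("u", "v"), n, replace = TRUE)
    s <- sample.int(1900, n, replace = TRUE)
    e <- pmin(s + sample.int(120, n, replace = TRUE), 2000L)
    expect_equal(collapseHsps(gr(ctg, s, e))$uniqueBp,
                 bitmapUnionBp(ctg, s, e))
  }
})

test_that("ratio arithmetic pools counts before dividing", {
  tm <- data.frame(n_snps = c(10, 10), length = c(1000, 1000),
                   mean_depth = c(30, 30))
  rm <- data.frame(n_snps = 20, length = 1000, mean_depth = 60)
  rr <- regionSetRatios(tm, rm, testUniqueBp = 2000, refUniqueBp = 1000)
  expect_equal(rr$len_ratio, 2)
  expect_equal(rr$het_ratio, 0.5)
  expect_equal(rr$cov_ratio, 0.5)
  same <- regionSetRatios(rm, rm)
  expect_equal(c(same$het_ratio, same$cov_ratio, same$len_ratio), c(1, 1, 1))
  expect_equal(same$classification, "normal")
})

test_that("zero reference denominators flag the set instead of erroring", {
  tm <- data.frame(n_snps = 5, length = 1000, mean_depth = 30)
  rm0 <- data.frame(n_snps = integer(), length = integer(),
                    mean_depth = numeric())
  rr <- regionSetRatios(tm, rm0, refUniqueBp = 0)
  expect_true(rr$flagged)
  expect_true(is.na(rr$len_ratio))
  expect_equal(rr$classification, "unresolved")
})

test_that("classification follows the three-ratio signature model", {
  expect_equal(classifyRegion(2.0, 0.5, 0.4), "expansion")
  expect_equal(classifyRegion(0.33, 3.0, 3.5), "collapse")
  expect_equal(classifyRegion(1.0, 1.0, 1.0), "normal")
  expect_equal(classifyRegion(2.0, 1.0, 2.0), "mixed")
  expect_equal(classifyRegion(3.0, 1.0, 0.5), "unresolved")
  expect_equal(classifyRegion(NA, 1, 1), "unresolved")
  expect_equal(classifyRegion(c(2, 1), c(0.5, 1), c(0, 1)),
               c("expansion", "normal"))
})

test_that("injected artifacts are recovered through the full regional analysis", {
  sc <- demoScenario()
  res <- regionSetAnalysis(sc$tabs$transcripts, sc$tabs$regions,
                           sc$profTest$snps, sc$profTest$depth,
                           sc$profRef$snps, sc$profRef$depth, sc$sets)
  r <- res$ratios
  rownames(r) <- r$region_set_id
  expect_equal(r["exp_set", "len_ratio"], 2, tolerance = 0.05)
  expect_equal(r["exp_set", "cov_ratio"], 0.5, tolerance = 0.10)
  expect_lt(r["exp_set", "het_ratio"], 0.2)
  expect_equal(r["exp_set", "classification"], "expansion")
  expect_equal(r["col_set", "len_ratio"], 1 / 3, tolerance = 0.05)
  expect_equal(r["col_set", "cov_ratio"], 3, tolerance = 0.10)
  expect_gt(r["col_set", "het_ratio"], 1.5)
  expect_equal(r["col_set", "classification"], "collapse")
  expect_equal(r["norm_set", "classification"], "normal")
  # direction law: length and coverage move in opposite directions
  pure <- r[c("exp_set", "col_set"), ]
  expect_true(all(sign(pure$len_ratio - 1) == -sign(pure$cov_ratio - 1)))
  expect_setequal(res$multiContigGenes, c("gE1", "gE2", "gE3"))
})
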