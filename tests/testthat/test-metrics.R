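test_that("length filtering is inclusive at the cutoff and order-preserving", {
  x <- assemblySeqs(c(s1 = paste(rep("A", 199), collapse = ""),
                      s2 = paste(rep("C", 200), collapse = ""),
                      s3 = paste(rep("G", 250), collapse = "")), "cut")
  expect_identical(names(filterByLength(x, 200)), c("s2", "s3"))
  expect_identical(names(filterByLength(x, 0)), names(x))
  set.seed(3)
  lens <- sample.int(400, 50)
  y <- assemblySeqs(setNames(vapply(lens, function(n)
    paste(rep("A", n), collapse = ""), character(1)),
    sprintf("r%02d", 1:50)), "rand")
  expect_identical(names(filterByLength(y, 150)),
                   sprintf("r%02d", 1:50)[lens >= 150])
})

test_that("N50 handles worked examples and matches the brute-force oracle", {
  expect_equal(computeN50(100), 100)
  expect_equal(computeN50(c(2, 3, 4, 5, 6)), 5)
  expect_error(computeN50(numeric(0)), "empty")
  set.seed(11)
  for (i in 1:1000) {
    l <- sample.int(500, sample.int(30, 1), replace = TRUE)
    expect_equal(computeN50(l), n50Oracle(l))
  }
})

test_that("N50 is invariant under permutation and bounded by the longest", {
  set.seed(12)
  for (i in 1:50) {
    l <- sample.int(100, 12, replace = TRUE)
    expect_equal(computeN50(l), computeN50(sample(l)))
    expect_lte(computeN50(l), max(l))
  }
})

test_that("total heterozygosity is snp sites over total length", {
  x <- assemblySeqs(c(c1 = paste(rep("A", 1000), collapse = "")), "h")
  expect_equal(totalHeterozygosity(emptySnpTable(), x), 0)
  s <- snpTable(rep("c1", 5), c(10, 20, 30, 40, 50), rep("A", 5),
                rep("T", 5))
  expect_equal(totalHeterozygosity(s, x), 0.005)
  s2 <- snpTable("c9", 1, "A", "T")
  expect_error(totalHeterozygosity(s2, x), "absent.*c9")
})

test_that("recovered heterozygosity matches the generator rate within 3 SE", {
  g <- demoGenome(seed = 101L)
  ref <- referenceAssembly(g)
  prof <- simulateMappingProfile(ref, g, seed = 101L)
  het <- totalHeterozygosity(prof$snps, assemblySequences(ref))
  L <- sum(Biostrings::width(hapA(g)))
  se <- sqrt(0.0115 * (1 - 0.0115) / L)
  expect_lt(abs(het - 0.0115), 3 * se)
})

test_that("assembly summaries compose filter and statistics", {
  x <- assemblySeqs(c(big = paste(rep("A", 10000), collapse = "")), "one")
  s <- snpTable(rep("big", 115), seq(10, by = 80, length.out = 115),
                rep("A", 115), rep("T", 115))
  sm <- summarizeAssembly(x, s, cutoff = 200)
  expect_equal(sm@n50, 10000)
  expect_equal(sm@totalHeterozygosity, 0.0115)
  expect_error(summarizeAssembly(x, s, cutoff = 20000), "removed every")
})

test_that("raising the cutoff never increases total length, and drops allelic copies so heterozygosity rises", {
  sc <- demoScenario()
  seqs <- assemblySequences(sc$assembly)
  snps <- sc$profTest$snps
  s200 <- summarizeAssembly(seqs, snps, 200)
  s1000 <- summarizeAssembly(seqs, snps, 1000)
  expect_lte(s1000@totalLength, s200@totalLength)
  # the 800 bp bubble-path contigs carry no heterozygous calls; removing
  # them at the 1 kb cutoff concentrates the same snps on less sequence
  expect_gte(s1000@totalHeterozygosity, s200@totalHeterozygosity)
  expect_gte(s200@n50, 200)
  expect_gte(s1000@n50, 1000)
})
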