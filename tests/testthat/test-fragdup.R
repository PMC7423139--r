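# helper: matches for one reference protein with given query-side spans
pmatch_hits <- function(qs, qe, protein = "P1") {
  alignmentHits(qseqid = protein,
                sseqid = sprintf("t%02d", seq_along(qs)),
                pident = 95, qstart = qs, qend = qe,
                sstart = 1, send = qe - qs + 1)
}

test_that("overlapping matches count N-1 duplications plus one correct match", {
  three <- classifyMatches(pmatch_hits(c(1, 10, 20), c(100, 110, 120)))
  expect_equal(three$duplication_events, 2L)
  expect_equal(three$n_clusters, 1L)
  expect_equal(three$fragmentation_case, 0L)
  expect_equal(three$one_to_one, 0L)
  two <- classifyMatches(pmatch_hits(c(1, 50), c(100, 150)))
  expect_equal(two$duplication_events, 1L)
  expect_equal(two$fragmentation_case, 0L)
})

test_that("non-overlapping matches are a fragmentation case with no duplications", {
  frag <- classifyMatches(pmatch_hits(c(1, 120), c(100, 220)))
  expect_equal(frag$fragmentation_case, 1L)
  expect_equal(frag$duplication_events, 0L)
  expect_equal(frag$n_clusters, 2L)
  single <- classifyMatches(pmatch_hits(1, 100))
  expect_equal(single$one_to_one, 1L)
  expect_equal(single$duplication_events, 0L)
  expect_error(classifyMatches(emptyAlignmentTable()), "at least one")
})

test_that("a single shared position suffices for overlap; abutting intervals do not merge", {
  touch <- classifyMatches(pmatch_hits(c(1, 100), c(100, 200)))
  expect_equal(touch$n_clusters, 1L)  # position 100 is shared
  abut <- classifyMatches(pmatch_hits(c(1, 101), c(100, 200)))
  expect_equal(abut$n_clusters, 2L)
})

test_that("mixed configurations obey the N = C + duplications identity", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample.int(8, 1)
    qs <- sample.int(500, n)
    qe <- qs + sample.int(120, n, replace = TRUE)
    cl <- classifyMatches(pmatch_hits(qs, qe))
    expect_equal(cl$n_matches, cl$n_clusters + cl$duplication_events)
    expect_true(cl$fragmentation_case %in% 0:1)
    expect_equal(cl$fragmentation_case, as.integer(cl$n_clusters > 1))
    # conservatism: never report as many duplications as matches
    expect_lt(cl$duplication_events, cl$n_matches)
  }
})

test_that("deduplication keeps one copy of identical rows and the best bitscore per coordinate key", {
  a <- alignmentHits("P1", "t1", 95, 1, 100, 1, 100, bitscore = 50)
  b <- alignmentHits("P1", "t1", 95, 1, 100, 1, 100, bitscore = 60)
  c2 <- alignmentHits("P1", "t2", 95, 1, 100, 1, 100, bitscore = 40)
  out <- dedupeHits(rbind(a, a, b, c2))
  expect_equal(nrow(out), 2L)
  expect_equal(out$bitscore[out$sseqid == "t1"], 60)
  expect_equal(nrow(dedupeHits(rbind(a, c2))), 2L)
})

test_that("paralog identification excludes both endpoints of non-self hits", {
  self_only <- alignmentHits(c("A", "B"), c("A", "B"), 100, 1, 100, 1, 100)
  expect_equal(identifyParalogs(self_only), character(0))
  withAB <- rbind(self_only, alignmentHits("A", "B", 80, 1, 90, 5, 94))
  expect_equal(identifyParalogs(withAB), c("A", "B"))
})

test_that("reference-query filtering preserves order and subsets", {
  h <- alignmentHits(c("P1", "x", "P2"), c("t1", "t2", "t3"), 90,
                     1, 100, 1, 100)
  out <- filterReferenceQueries(h, c("P1", "P2"))
  expect_equal(out$qseqid, c("P1", "P2"))
  expect_equal(nrow(filterReferenceQueries(h, "zz")), 0L)
})

test_that("per-assembly tallies screen paralogs and keep the accounting identity", {
  refs <- c("P1", "P2", "P3", "P4")
  hits <- rbind(
    pmatch_hits(1, 100, "P1"),                        # 1:1
    pmatch_hits(c(1, 20), c(100, 120), "P2"),         # duplication
    pmatch_hits(c(1, 150), c(100, 250), "P3"),        # fragmentation
    pmatch_hits(1, 80, "P4"))                         # paralog, dropped
  tl <- tallyAssembly(hits, refs, paralogs = "P4", label = "demo")
  expect_equal(tl$counts$one_to_one, 1L)
  expect_equal(tl$counts$duplication_events, 1L)
  expect_equal(tl$counts$fragmentation_cases, 1L)
  expect_equal(tl$counts$excluded_paralogs, 1L)
  expect_equal(tl$counts$n_proteins_matched, 3L)
  with(tl$perProtein,
       expect_equal(n_matches, n_clusters + duplication_events))
})

test_that("expansion-only synthetic data yields duplications for exactly the expanded genes", {
  sc <- demoScenario()
  tabs <- sc$tabs
  self_hits <- tabs$proteins[tabs$proteins$sseqid %in% tabs$refProteinIds, ]
  test_hits <- tabs$proteins[!tabs$proteins$sseqid %in% tabs$refProteinIds, ]
  tl <- tallyAssembly(dedupeHits(test_hits), tabs$refProteinIds,
                      identifyParalogs(self_hits), label = "demo")
  n_exp_genes <- sum(sc$sets$set_id == "exp_set")
  expect_equal(tl$counts$fragmentation_cases, 0L)
  expect_equal(tl$counts$duplication_events, n_exp_genes)
  expect_equal(tl$counts$one_to_one,
               nrow(sc$sets) - n_exp_genes - sum(sc$sets$set_id == "bub"))
})
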