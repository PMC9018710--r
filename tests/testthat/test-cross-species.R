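test_that("expressed-cluster calling applies inclusive thresholds", {
  st <- data.frame(
    cluster = c("hi", "low", "edge", "none"),
    uniqueReads = c(150, 50, 100, 0),
    strandFraction = c(0.85, 0.95, 0.80, 0),
    oneUFraction = c(0.45, 0.60, 0.40, 0))
  expect_setequal(callExpressedClusters(st), c("hi", "edge"))
})

test_that("library QC separates refined and global thresholds", {
  qc <- libraryQc(clusterReads = 12000, totalReads = 50000)
  expect_true(qc$refined)
  expect_false(qc$global)
})

test_that("robustness classes follow strict ranking rules", {
  mk <- function(stops, others) {
    cnt <- stats::setNames(numeric(64), piRcleave:::.TRINUCLEOTIDES)
    cnt[c("TAA", "TAG", "TGA")] <- stops
    free <- setdiff(piRcleave:::.TRINUCLEOTIDES, c("TAA", "TAG", "TGA"))
    cnt[free[seq_along(others)]] <- others
    cnt
  }
  expect_equal(classifyRobustness(mk(c(30, 25, 20), c(19, 10))), "robust")
  # stops at ranks 1, 2, 5
  expect_equal(classifyRobustness(mk(c(30, 25, 18), c(20, 19))), "near_robust")
  expect_equal(classifyRobustness(mk(c(30, 25, 10), c(20, 19, 18))), "none")
  # ties demote robust (equal top frequency elsewhere)
  expect_equal(classifyRobustness(mk(c(30, 25, 20), c(20, 5))), "near_robust")
  uniform <- stats::setNames(rep(1, 64), piRcleave:::.TRINUCLEOTIDES)
  expect_equal(classifyRobustness(uniform), "none")
  # scale invariance and robust => near-robust over random tables
  set.seed(111)
  for (i in 1:30) {
    cnt <- stats::setNames(rpois(64, 20), piRcleave:::.TRINUCLEOTIDES)
    lab <- classifyRobustness(cnt)
    expect_equal(classifyRobustness(cnt * 3), lab)
    if (lab == "robust") {
      rk <- rank(-cnt, ties.method = "min")
      expect_true(all(rk[c("TAA", "TAG", "TGA")] <= 5))
    }
  }
})

test_that("expected composition counts sliding 3-mers per record", {
  expect_equal(unname(expectedComposition(c(a = "AAAA"))["AAA"]), 1)
  e <- expectedComposition(c(a = "ATAA"))
  expect_equal(unname(e[c("ATA", "TAA")]), c(0.5, 0.5))
  # windows do not cross record boundaries
  split2 <- expectedComposition(c(a = "ATAA", b = "CCCC"))
  expect_equal(unname(split2[c("ATA", "TAA", "CCC")]), c(0.25, 0.25, 0.5))
  expect_equal(unname(split2["AAC"]), 0)  # would exist only across records
  expect_error(expectedComposition(c(a = "NNNN")), "3-mer")
})

test_that("composition normalization removes AT-rich artifacts", {
  cl <- fxCluster()
  expected <- expectedComposition(cl)
  # unbiased sampling proportional to cluster content
  set.seed(112)
  cnt <- as.vector(stats::rmultinom(1, 2e5, prob = expected))
  names(cnt) <- piRcleave:::.TRINUCLEOTIDES
  obs <- EndCountTable(cnt)
  raw <- stopCodonRatio(obs)$ratio
  norm <- normalizeComposition(obs, expected)
  expect_gt(raw, 1)  # AT-rich composition inflates the raw ratio
  expect_lt(abs(norm$normalizedStopRatio - 1), 0.1)
  # observed exactly equal to expected: all ratios 1
  exact <- EndCountTable(expected * 64000)
  nz <- normalizeComposition(exact, expected)
  expect_true(all(abs(nz$ratios - 1) < 1e-9, na.rm = TRUE))
  expect_equal(nz$normalizedStopRatio, 1, tolerance = 1e-9)
})

test_that("library summaries combine ratio, 1U and robustness", {
  tabs <- simulateLibraryTables(1, 1, effect = 4, depth = 1e5, seed = 113)
  s <- summarizeLibrary(tabs[[1]])
  expect_gt(s@stopRatio, 2)
  expect_true(s@robustness %in% c("robust", "near_robust"))
  expect_true(s@oneU > 0 && s@oneU < 1)
})

test_that("species grouping weights species equally, not libraries", {
  mkTab <- function(stop, other, species, n) {
    cnt <- stats::setNames(rep(10, 64), piRcleave:::.TRINUCLEOTIDES)
    cnt[c("TAA", "TAG", "TGA")] <- stop
    cnt[setdiff(piRcleave:::.UNN, c("TAA", "TAG", "TGA"))] <- other
    lapply(seq_len(n), function(i)
      EndCountTable(cnt, metadata = list(species = species,
                                         tissue = "testis",
                                         class = "mammals")))
  }
  # species A: ratio 1 (5 libraries); species B: ratio 3 (1 library)
  tabs <- c(mkTab(10, 10, "A", 5), mkTab(30, 10, "B", 1))
  sums <- lapply(tabs, summarizeLibrary)
  g <- speciesGroupSummary(sums)
  expect_equal(nrow(g$species), 2L)
  expect_equal(g$groups$nSpecies, 2L)
  expect_equal(g$groups$meanStopRatio, 2, tolerance = 1e-9)
  # one species, identical libraries: group equals either library
  solo <- speciesGroupSummary(lapply(mkTab(20, 10, "C", 2),
                                     summarizeLibrary))
  expect_equal(solo$groups$meanStopRatio, 2, tolerance = 1e-9)
})

test_that("the Fisher group test matches hypergeometric enumeration", {
  res <- groupEnrichmentFisher(3, 5, 0, 5)
  expect_equal(res$p, fisherEnumeration(3, 2, 0, 5), tolerance = 1e-12)
  expect_equal(groupEnrichmentFisher(0, 10, 0, 10)$p, 1)
  set.seed(114)
  for (i in 1:50) {
    tot <- sample(8:60, 1)
    aT <- sample(2:(tot - 2), 1); bT <- tot - aT
    a <- sample(0:aT, 1); b <- sample(0:bT, 1)
    expect_equal(groupEnrichmentFisher(a, aT, b, bT)$p,
                 fisherEnumeration(a, aT - a, b, bT - b),
                 tolerance = 1e-12)
  }
  expect_error(groupEnrichmentFisher(5, 3, 0, 5))
})

test_that("the uniform-ranking null matches permutation enumeration", {
  expect_equal(nullRobustFraction(16, 3), 1 / 560, tolerance = 1e-12)
  expect_equal(nullRobustFraction(3, 3), 1)
  expect_equal(nullRobustFraction(4, 2), 1 / 6, tolerance = 1e-12)
  # enumeration oracle: all orderings of n items, fraction whose top-k set
  # is exactly the designated k items
  for (case in list(c(4, 2), c(5, 3))) {
    n <- case[1]; k <- case[2]
    perms <- allPermutations(n)
    hits <- vapply(perms, function(p) all(p[seq_len(k)] %in% seq_len(k)),
                   logical(1))
    expect_equal(nullRobustFraction(n, k), mean(hits), tolerance = 1e-12)
  }
})
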