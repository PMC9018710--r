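test_that("5' tabulation respects the length window and the count column", {
  seqs <- Biostrings::DNAStringSet(
    c(cl = paste(rep("TAACGGA", 10), collapse = "")))
  rd <- makeReads("cl", 1, 27, "+")
  tab <- tabulateFivePrime(rd, seqs, window = c(26, 32))
  expect_equal(unname(endCounts(tab)["TAA"]), 1)
  expect_equal(totalCount(tab), 1)

  short <- makeReads("cl", 1, 22, "+")
  tabS <- tabulateFivePrime(short, seqs, window = c(26, 32))
  expect_equal(totalCount(tabS), 0)
  expect_true(isTRUE(tabS@metadata$empty))

  wide <- makeReads("cl", c(1, 1, 2), c(27, 27, 28), "+", count = c(2L, 3L, 4L))
  tabW <- tabulateFivePrime(wide, seqs, window = c(26, 32))
  expect_equal(unname(endCounts(tabW)["TAA"]), 5)  # two identical coords sum
  expect_equal(unname(endCounts(tabW)["AAC"]), 4)
  expect_equal(totalCount(tabW), 9)
})

test_that("the duplicate cap limits per-coordinate contributions", {
  seqs <- Biostrings::DNAStringSet(
    c(cl = paste(rep("TAACGGA", 10), collapse = "")))
  rd <- makeReads("cl", rep(1, 3), rep(27, 3), "+", count = c(150L, 60L, 40L))
  tab <- tabulateFivePrime(rd, seqs, window = c(26, 32), dedupCap = 100)
  expect_equal(unname(endCounts(tab)["TAA"]), 100)
})

test_that("table totals are conserved under any read partition", {
  cl <- fxCluster()
  rd <- fxStopSim()$reads
  whole <- tabulateFivePrime(rd, cl, window = c(15, 70))
  idx <- seq_along(rd) %% 3
  parts <- lapply(0:2, function(k)
    tabulateFivePrime(rd[idx == k], cl, window = c(15, 70)))
  summed <- Reduce(`+`, lapply(parts, endCounts))
  expect_equal(summed, endCounts(whole))
})

test_that("stop-codon ratio follows its definition and invariances", {
  counts <- stats::setNames(rep(2, 64), renderRNA(piRcleave:::.TRINUCLEOTIDES))
  counts[c("UAA", "UAG", "UGA")] <- 10
  counts[setdiff(names(counts)[startsWith(names(counts), "U")],
                 c("UAA", "UAG", "UGA"))] <- 5
  r <- stopCodonRatio(counts)
  expect_equal(r$ratio, 2.0)
  # scale invariance and non-U invariance
  expect_equal(stopCodonRatio(counts * 17)$ratio, 2.0)
  counts[c("AAA", "CGC")] <- c(1000, 0)
  expect_equal(stopCodonRatio(counts)$ratio, 2.0)
  # uniform table
  expect_equal(stopCodonRatio(rep(1, 64) |>
    stats::setNames(piRcleave:::.TRINUCLEOTIDES))$ratio, 1.0)
  # degenerate cases are flagged
  expect_equal(stopCodonRatio(numeric(0))$flag, "empty")
  only <- c(UAA = 5)
  expect_equal(stopCodonRatio(only)$flag, "undefined")
})

test_that("fold-enrichment test matches the closed-form t statistic", {
  ratios <- c(2.1, 2.2, 2.0, 2.2, 2.1)
  res <- foldEnrichmentTest(ratios)
  tHand <- (mean(ratios) - 1) / (sd(ratios) / sqrt(5))
  pHand <- 2 * pt(-abs(tHand), df = 4)
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$p, pHand, tolerance = 1e-12)
  expect_equal(res$df, 4)

  expect_equal(foldEnrichmentTest(rep(1, 4))$p, 1)
  z <- foldEnrichmentTest(rep(2, 5))
  expect_equal(z$flag, "zero_variance")
  expect_lt(z$p, 1e-300)
  lg <- foldEnrichmentTest(ratios, logScale = TRUE)
  expect_true(lg$ciLow > 1)
})

test_that("positional codon frequencies resolve a 5'-restricted signal", {
  seqs <- Biostrings::DNAStringSet(
    c(cl = paste(rep("TAACTGC", 12), collapse = "")))
  rd <- makeReads("cl", rep(1, 3), rep(27, 3), "+")
  m <- positionalCodonFrequency(rd, seqs, positions = 1:3)
  expect_equal(unname(m["UAA", "1"]), 1)
  expect_equal(unname(m["AAC", "2"]), 1)
  expect_equal(unname(colSums(m)), rep(1, 3))

  # stop-weighted simulator output: stop rows enriched at column 1 only
  pm <- positionalCodonFrequency(fxStopSim()$reads, fxCluster(),
                                 positions = 1:6)
  stopRows <- c("UAA", "UAG", "UGA")
  expect_gt(sum(pm[stopRows, "1"]), 2 * max(colSums(pm[stopRows, -1])))
})

test_that("the 10A ping-pong filter indexes position 10 strand-aware", {
  # position 10 (1-based) on the plus strand is start + 9
  seq <- paste0(strrep("C", 9), "A", strrep("G", 30))
  seqs <- Biostrings::DNAStringSet(c(cl = seq))
  plusA <- makeReads("cl", 1, 27, "+")
  expect_length(excludeTenA(plusA, seqs), 0L)
  plusOk <- makeReads("cl", 2, 28, "+")   # position 10 now G
  expect_length(excludeTenA(plusOk, seqs), 1L)
  # minus strand: position 10 is complement(base at end - 9)
  mseq <- paste0(strrep("C", 20), "T", strrep("C", 9))
  mseqs <- Biostrings::DNAStringSet(c(cl = mseq))
  minusA <- makeReads("cl", 4, 30, "-")   # end 30, base 21 = T -> A on read
  expect_length(excludeTenA(minusA, mseqs), 0L)
  minusOk <- makeReads("cl", 3, 29, "-")  # base 20 = C -> G on read
  expect_length(excludeTenA(minusOk, mseqs), 1L)
  # an all-A cluster loses everything
  allA <- Biostrings::DNAStringSet(c(cl = strrep("A", 60)))
  expect_length(excludeTenA(makeReads("cl", 1, 27, "+"), allA), 0L)
})

test_that("downstream composition of unbiased cleavage matches the cluster", {
  cl <- generateCluster(4000, seed = 61)
  uniform <- cleavageModel(weights = stats::setNames(
    rep(1, 64), piRcleave:::.TRINUCLEOTIDES), minus1G = 1, upstreamGC = 1)
  sim <- simulatePhasedReads(cl, uniform, nInitiations = 60,
                             trimming = "untrimmed", seed = 62)
  dp <- downstreamProfile(sim$reads, cl, byLength = FALSE)
  clusterStop <- sum(expectedComposition(cl)[c("TAA", "TAG", "TGA")])
  n <- dp$n[1]
  sd3 <- 3 * sqrt(clusterStop * (1 - clusterStop) / n)
  expect_lt(abs(dp$stopFraction[1] - clusterStop), sd3 + 0.01)

  # uniform random reads on random sequence: downstream 1U near 1/4
  clusterU <- sum(expectedComposition(cl)[startsWith(
    names(expectedComposition(cl)), "T")])
  sdU <- 3 * sqrt(clusterU * (1 - clusterU) / n)
  expect_lt(abs(dp$oneU[1] - clusterU), sdU + 0.01)
})

test_that("length histograms count reads and reflect trimming", {
  one <- makeReads("cl", 1, 27, "+")
  expect_equal(lengthDistribution(one), c("27" = 1))
  expect_length(lengthDistribution(one[0]), 0L)

  cl <- generateCluster(3000, seed = 71)
  simT <- simulatePhasedReads(cl, cleavageModel(), nInitiations = 50,
                              trimming = "trimmed", seed = 72)
  h <- lengthDistribution(simT$reads)
  expect_true(names(which.max(h)) %in% c("26", "27"))
  expect_equal(sum(h), sum(simT$reads$count))
})
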