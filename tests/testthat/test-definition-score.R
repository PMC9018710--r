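test_that("score engine matches the brute-force window-sum oracle", {
  set.seed(81)
  for (strand in c("+", "-")) {
    region <- GenomicRanges::GRanges("cl", IRanges::IRanges(11, 190),
                                     strand = strand, name = "r")
    n <- 40
    starts <- sample(15:160, n, replace = TRUE)
    rd <- makeReads("cl", starts, starts + 26L, strand,
                    count = sample(1:50, n, replace = TRUE))
    sp <- computeScores(rd, region, scoreConfigDefaults(minLocalReads = 1))
    oracle <- bruteForceScores(rd, region)
    gr <- granges(sp)
    expect_equal(gr$f, oracle$f, tolerance = 1e-12)
    expect_equal(gr$localTotal, oracle$localTotal, tolerance = 1e-12)
    expect_equal(gr$score, oracle$score, tolerance = 1e-12)
    # conservation: window totals derive from exactly the region's 5' ends
    five <- if (strand == "+") GenomicRanges::start(rd)
            else GenomicRanges::end(rd)
    inRegion <- five >= 11 & five <= 190
    expect_equal(sum(gr$f), sum(rd$count[inRegion]))
  }
})

test_that("score engine reproduces hand-evaluated window cases", {
  region <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 120),
                                   strand = "+", name = "r")
  # a single position carrying all local reads scores 1 and is covered
  rd1 <- makeReads("cl", 60, 86, "+", count = 120L)
  g1 <- granges(computeScores(rd1, region))
  expect_equal(g1$score[60], 1)
  expect_true(g1$covered[60])
  # zero f with a hot window is score 0 but covered
  rd2 <- makeReads("cl", 55, 81, "+", count = 150L)
  g2 <- granges(computeScores(rd2, region))
  expect_equal(g2$score[60], 0)
  expect_true(g2$covered[60])
  expect_false(g2$covered[5])
  # counts {x-1: 30, x: 60, x+5: 30} -> s(x) = 60/120
  rd3 <- makeReads("cl", c(59, 60, 65), c(85, 86, 91), "+",
                   count = c(30L, 60L, 30L))
  g3 <- granges(computeScores(rd3, region,
                              scoreConfigDefaults(minLocalReads = 100)))
  expect_equal(g3$score[60], 0.5)
  # edge windows are flagged truncated
  expect_true(all(g3$truncated[1:10]))
  expect_false(g3$truncated[11])
})

test_that("downstream-of-3'-end scoring counts positions past read ends", {
  region <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 120),
                                   strand = "+", name = "r")
  rd <- makeReads("cl", 20, 46, "+", count = 120L)
  g <- granges(computeScores(rd, region, end = "downstream_of_three_prime"))
  expect_equal(g$f[47], 120)  # one base past the 3' end
  expect_equal(sum(g$f), 120)
  # minus strand: downstream position is start - 1
  regionM <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 120),
                                    strand = "-", name = "r")
  rdM <- makeReads("cl", 20, 46, "-", count = 120L)
  gM <- granges(computeScores(rdM, regionM,
                              end = "downstream_of_three_prime"))
  expect_equal(gM$f[19], 120)
})

test_that("binning separates zero scores and splits evenly with stable ties", {
  region <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 160),
                                   strand = "+", name = "r")
  # all zero scores (no reads in window but force coverage via min 0 reads)
  rdNone <- makeReads("cl", 10, 36, "+", count = 200L)
  spA <- computeScores(rdNone, region, scoreConfigDefaults(minLocalReads = 1))
  bA <- granges(suppressWarnings(binPositions(spA)))
  zero <- bA$bin[bA$covered & bA$score == 0]
  expect_true(all(zero == 0L))

  # 40 distinct positive scores -> 20 bins of exactly 2
  starts <- seq(21, 138, by = 3)[1:40]
  rd <- makeReads("cl", starts, starts + 26L,
                  count = as.integer(seq(10, 400, by = 10)))
  sp <- computeScores(rd, region, scoreConfigDefaults(minLocalReads = 1))
  b <- granges(binPositions(sp))
  sizes <- table(b$bin[!is.na(b$bin) & b$bin > 0])
  expect_equal(length(sizes), 20L)
  expect_true(all(sizes == 2))
  # bin index nondecreasing in score
  pos <- !is.na(b$bin) & b$bin > 0
  expect_true(all(diff(b$bin[pos][order(b$score[pos])]) >= 0))

  # permutation invariance of input order
  perm <- sample(length(rd))
  b2 <- granges(binPositions(computeScores(rd[perm], region,
                                           scoreConfigDefaults(minLocalReads = 1))))
  expect_identical(b$bin, b2$bin)

  # fewer positive positions than bins degrades gracefully
  rdFew <- makeReads("cl", c(30, 70), c(56, 96), count = c(100L, 200L))
  spFew <- computeScores(rdFew, region, scoreConfigDefaults(minLocalReads = 1))
  expect_warning(bFew <- binPositions(spFew), "singleton")
})

test_that("bin sizes never differ by more than one", {
  for (m in c(7, 40, 101, 904)) {
    bin <- ceiling(seq_len(m) * 20 / m)
    sizes <- table(bin)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(length(sizes), min(m, 20L))
  }
})

test_that("context grouping recovers the injected Unn preference", {
  spb <- fxStopScored()
  byNt <- scoreByContext(spb, fxCluster(), "nucleotide")
  sm <- byNt$summary
  expect_gt(sm$median[sm$context == "U"],
            max(sm$median[sm$context != "U"]))
  byTri <- scoreByContext(spb, fxCluster(), "trinucleotide")
  smT <- byTri$summary
  unn <- smT[startsWith(smT$context, "U"), ]
  top4 <- unn$context[order(-unn$mean)][1:4]
  expect_setequal(top4, c("UAA", "UAG", "UGA", "UAC"))
})

test_that("bin composition sums to one and peaks stops in the top bin", {
  spb <- fxStopScored()
  comp <- binComposition(spb, fxCluster())
  cs <- colSums(comp$trinucleotide, na.rm = TRUE)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))
  stopRows <- c("UAA", "UAG", "UGA")
  topBin <- as.character(max(as.integer(colnames(comp$trinucleotide))))
  stopTop <- sum(comp$trinucleotide[stopRows, topBin])
  stopBin0 <- sum(comp$trinucleotide[stopRows, "0"])
  expect_gt(stopTop, 3 * stopBin0)
  # bin 0 is U-depleted relative to the upper bins
  expect_lt(comp$base["U", "0"], comp$base["U", topBin])
})

test_that("motif enrichment sees the -1G penalty and upstream GC bonus", {
  spb <- fxStopScored()
  topBin <- max(granges(spb)$bin, na.rm = TRUE)
  m <- motifAround(spb, fxCluster(), binIndex = topBin, flank = 15)
  expect_equal(dim(m$freq), c(4L, 31L))
  # G is depleted immediately upstream of the preferred cut sites
  expect_lt(m$enrichment["G", "-1"], 1)
  # GC-rich region further upstream (offsets -20..-10 clipped to flank 15)
  gcUp <- mean(m$enrichment[c("G", "C"), as.character(-15:-10)])
  expect_gt(gcUp, 1)
  # background equal to the selected set gives enrichment exactly 1
  sel <- granges(spb)[!is.na(granges(spb)$bin) & granges(spb)$bin == topBin]
  m2 <- motifAround(spb, fxCluster(), binIndex = topBin, flank = 5,
                    background = sel)
  expect_true(all(abs(m2$enrichment - 1) < 1e-12, na.rm = TRUE))
})

test_that("5' and downstream-of-3' scores agree for untrimmed phased reads", {
  region <- wholeClusterRegion(fxCluster())
  cfg <- scoreConfigDefaults(minLocalReads = 50)
  sp5 <- computeScores(fxStopSim()$reads, region, cfg)
  sp3 <- computeScores(fxStopSim()$reads, region, cfg,
                       end = "downstream_of_three_prime")
  res <- correlateFiveThree(sp5, sp3)
  expect_equal(res$flag, "ok")
  expect_gt(res$r, 0.8)
  # identical inputs correlate exactly
  self <- correlateFiveThree(sp5, sp5)
  expect_equal(self$r, 1, tolerance = 1e-12)
  # too few shared positions is flagged, not an error
  few <- computeScores(makeReads("cl", 30, 56, "+", count = 200L),
                       GenomicRanges::GRanges("cl", IRanges::IRanges(1, 100),
                                              strand = "+", name = "x"))
  fewCov <- correlateFiveThree(few, sp3)
  expect_true(fewCov$flag %in% c("ok", "undefined"))
})
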