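# A small binned fixture: deterministic scores on one region, with bins.
.consFixture <- function() .fxGet("consFixture", function() {
  region <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 200),
                                   strand = "+", name = "r")
  starts <- seq(21, 170, by = 5)
  rd <- makeReads("cl", starts, starts + 26L,
                  count = as.integer(seq_along(starts) * 8))
  sp <- computeScores(rd, region, scoreConfigDefaults(minLocalReads = 1,
                                                      nBins = 5))
  binPositions(sp)
})

test_that("track joins are inner joins with dropped-position reporting", {
  spb <- .consFixture()
  pos <- coveredPositions(spb)
  full <- simulateTrack(200, "flat", value = 0.7, contig = "cl")
  j <- joinTrack(pos, full)
  expect_equal(nrow(j), length(pos))
  expect_true(all(j$value == 0.7))

  half <- full[1:100]
  expect_message(jh <- joinTrack(pos, half), "dropped")
  expect_equal(nrow(jh), sum(GenomicRanges::start(pos) <= 100))

  other <- simulateTrack(200, "flat", contig = "elsewhere")
  expect_message(j0 <- joinTrack(pos, other), "dropped")
  expect_equal(nrow(j0), 0L)
})

test_that("per-bin means are exact on a flat track and detect an offset", {
  spb <- .consFixture()
  pos <- coveredPositions(spb)
  flat <- simulateTrack(200, "flat", value = 0.5, contig = "cl")
  s <- binMeanCI(joinTrack(pos, flat))
  expect_true(all(s$mean == 0.5))
  expect_true(all(s$ciHigh - s$ciLow == 0))

  # add +0.8 noise offset to every position of one bin
  targetBin <- 3L
  offPos <- GenomicRanges::start(pos)[pos$bin == targetBin]
  tr <- simulateTrack(200, "bin-correlated", offset = 0.8,
                      offsetPositions = offPos, seed = 101, contig = "cl")
  s2 <- binMeanCI(joinTrack(pos, tr))
  row <- s2[s2$bin == targetBin, ]
  others <- s2[s2$bin != targetBin, ]
  expect_gt(row$mean, max(others$mean))
  expect_true(row$ciLow <= row$mean && row$mean <= row$ciHigh)
})

test_that("acceleration fractions use a strict threshold and flag outliers", {
  spb <- .consFixture()
  pos <- coveredPositions(spb)
  zero <- simulateTrack(200, "flat", value = 0, contig = "cl")
  a0 <- acceleratedFraction(joinTrack(pos, zero))
  expect_true(all(a0$fraction == 0))

  # a value exactly at the threshold is not an acceleration call
  at <- simulateTrack(200, "flat", value = -1.30103, contig = "cl")
  aAt <- acceleratedFraction(joinTrack(pos, at))
  expect_true(all(aAt$fraction == 0))

  # one bin driven below threshold stands out in the Z test
  j <- joinTrack(pos, zero)
  target <- 2L
  inBin <- j$bin == target
  j$value[inBin] <- -2                       # all accelerated
  j$value[!inBin][seq_len(ceiling(sum(!inBin) * 0.02))] <- -2
  az <- acceleratedFraction(j)
  row <- az[az$bin == target, ]
  expect_equal(row$fraction, 1)
  expect_lt(row$p, 0.05)
})

test_that("SNP frequencies are membership fractions per bin", {
  spb <- .consFixture()
  pos <- coveredPositions(spb)
  none <- GenomicRanges::GRanges(character(0), IRanges::IRanges())
  s0 <- snpFrequency(pos, none)
  expect_true(all(s0$frequency == 0))

  bin1 <- pos[pos$bin == 1L]
  snpAll <- GenomicRanges::GRanges("cl",
    IRanges::IRanges(GenomicRanges::start(bin1), width = 1))
  s1 <- snpFrequency(pos, snpAll)
  expect_equal(s1$frequency[s1$bin == 1L], 1)
  expect_true(all(s1$frequency[!s1$bin %in% c(1L)] %in% c(0)))

  set.seed(103)
  hit <- sample(200, 60)
  snpR <- GenomicRanges::GRanges("cl", IRanges::IRanges(hit, width = 1))
  sR <- snpFrequency(pos, snpR)
  expect_true(all(abs(sR$frequency - 0.3) < 0.25))
})

test_that("context subsetting restricts to U and stop-codon positions", {
  spb <- fxStopScored()
  cl <- fxCluster()
  allPos <- subsetByContext(spb, cl, "all")
  uPos <- subsetByContext(spb, cl, "U")
  stopPos <- subsetByContext(spb, cl, "stopU")
  expect_lte(length(uPos), length(allPos))
  expect_lte(length(stopPos), length(uPos))
  chars <- as.character(cl)[[1]]
  expect_true(all(substr(chars, GenomicRanges::start(uPos),
                         GenomicRanges::start(uPos)) == "T"))
  tri <- substr(rep(chars, length(stopPos)),
                GenomicRanges::start(stopPos),
                GenomicRanges::start(stopPos) + 2)
  expect_true(all(tri %in% c("TAA", "TAG", "TGA")))
})

test_that("summaries are invariant to input ordering", {
  spb <- .consFixture()
  pos <- coveredPositions(spb)
  tr <- simulateTrack(200, "noisy", seed = 104, contig = "cl")
  j <- joinTrack(pos, tr)
  perm <- sample(nrow(j))
  a <- binMeanCI(j)
  b <- binMeanCI(j[perm, ])
  expect_equal(a, b)
})
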