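# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

.fxGet <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# GRanges read builder from 1-based closed coordinates.
makeReads <- function(contig, start, end, strand = "+", count = 1L,
                      name = NULL) {
  n <- max(length(start), length(end))
  if (is.null(name)) name <- paste0("r", seq_len(n))
  GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                         strand = strand, name = name,
                         count = as.integer(count))
}

wholeClusterRegion <- function(cluster) {
  GenomicRanges::GRanges(names(cluster)[1],
                         IRanges::IRanges(1L, Biostrings::width(cluster)[1]),
                         strand = "+", name = names(cluster)[1], count = 1L)
}

# Medium cluster + stop-biased untrimmed simulation used by several files.
fxCluster <- function() .fxGet("cluster", function() {
  generateCluster(6000, seed = 101)
})

fxStopSim <- function() .fxGet("stopSim", function() {
  simulatePhasedReads(fxCluster(), cleavageModel(), nInitiations = 120,
                      trimming = "untrimmed", seed = 202)
})

fxStopScored <- function() .fxGet("stopScored", function() {
  sp <- computeScores(fxStopSim()$reads, wholeClusterRegion(fxCluster()),
                      scoreConfigDefaults(minLocalReads = 50))
  binPositions(sp)
})

# Brute-force definition-score oracle: literal window sums over f.
bruteForceScores <- function(reads, region, up = 10L, down = 20L) {
  rStart <- GenomicRanges::start(region)
  rEnd <- GenomicRanges::end(region)
  rStrand <- as.character(GenomicRanges::strand(region))
  n <- rEnd - rStart + 1L
  strandv <- as.character(GenomicRanges::strand(reads))
  five <- ifelse(strandv == "+", GenomicRanges::start(reads),
                 GenomicRanges::end(reads))
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  sel <- as.character(GenomicRanges::seqnames(reads)) ==
    as.character(GenomicRanges::seqnames(region)) &
    strandv == rStrand & five >= rStart & five <= rEnd
  f <- numeric(n)
  for (i in which(sel)) {
    # transcript coordinate: index 1 at the transcript 5' end
    tpos <- if (rStrand == "+") five[i] - rStart + 1L else rEnd - five[i] + 1L
    f[tpos] <- f[tpos] + cnt[i]
  }
  s <- numeric(n); lt <- numeric(n)
  for (x in seq_len(n)) {
    tot <- 0
    for (j in (x - up):(x + down)) if (j >= 1 && j <= n) tot <- tot + f[j]
    lt[x] <- tot
    s[x] <- if (tot > 0) f[x] / tot else 0
  }
  # back to genomic orientation
  if (rStrand == "-") { f <- rev(f); lt <- rev(lt); s <- rev(s) }
  list(f = f, localTotal = lt, score = s)
}

# Exact two-sided Fisher p by hypergeometric enumeration with choose().
fisherEnumeration <- function(a, b, c, d) {
  K <- a + b          # row 1 margin
  m <- a + c          # col 1 margin
  n <- b + d
  kRange <- max(0, K - n):min(K, m)
  pk <- vapply(kRange, function(k)
    choose(m, k) * choose(n, K - k) / choose(m + n, K), numeric(1))
  pObs <- choose(m, a) * choose(n, K - a) / choose(m + n, K)
  sum(pk[pk <= pObs * (1 + 1e-7)])
}

# All permutations of seq_len(n) (small n) for ranking-null enumeration.
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}
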