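# The windowed 5' end definition score: for a transcript position x,
# s(x) = f(x) / sum_{i = x-10}^{x+20} f(i), where f counts read 5' ends at
# each position (transcript oriented; upstream = toward the transcript 5'
# end). s is the fraction of local cleavage events landing exactly at x and
# is therefore independent of the underlying abundance of each sequence.
# Positions with fewer than minLocalReads in the window are flagged
# uncovered and excluded from downstream statistics.

#' Scoring configuration
#'
#' @param upstream window extent toward the transcript 5' end (default 10 nt).
#' @param downstream window extent toward the 3' end (default 20 nt); the
#'   denominator spans upstream + downstream + 1 positions including x.
#' @param minLocalReads coverage gate on the window total (default 100).
#' @param nBins number of equal-size bins for positive scores (default 20;
#'   bin 0 separately holds positions never observed as a 5' end).
#' @return list of class-checked parameters.
#' @export
scoreConfigDefaults <- function(upstream = 10L, downstream = 20L,
                                minLocalReads = 100L, nBins = 20L) {
  stopifnot(upstream >= 0, downstream >= 0, minLocalReads >= 1, nBins >= 1)
  list(upstream = as.integer(upstream), downstream = as.integer(downstream),
       minLocalReads = as.integer(minLocalReads), nBins = as.integer(nBins))
}

# f(x) per region position, transcript oriented. For end = "five_prime"
# f counts read 5' ends; for "downstream_of_three_prime" it counts the
# position immediately past each read's 3' end (the expected next 5' end
# under phased processing).
.endPositions <- function(reads, end) {
  strandv <- as.character(GenomicRanges::strand(reads))
  .checkStrand(strandv)
  if (end == "five_prime") {
    ifelse(strandv == "+", GenomicRanges::start(reads),
           GenomicRanges::end(reads))
  } else {
    ifelse(strandv == "+", GenomicRanges::end(reads) + 1L,
           GenomicRanges::start(reads) - 1L)
  }
}

#' Compute 5' end definition scores
#'
#' For every position of every region, counts read 5' ends (`f`), the
#' window total (`localTotal`, summed over `upstream` nt toward the
#' transcript 5' end through `downstream` nt toward the 3' end, inclusive
#' of the position itself), and the score `f / localTotal` (0 where the
#' window is empty). Windows are truncated, and flagged, at region edges.
#' With `end = "downstream_of_three_prime"` the score is computed on
#' positions immediately past read 3' ends instead, the expected next 5'
#' end under phased tail-to-head processing.
#'
#' @param reads GRanges of reads with an optional `count` column; only
#'   reads on a region's strand contribute to that region.
#' @param regions GRanges of transcript regions (strand defines
#'   orientation); names (or a `name` column) identify regions.
#' @param config list from [scoreConfigDefaults()].
#' @param end `"five_prime"` (default) or `"downstream_of_three_prime"`.
#' @return A [ScoredPositions-class] object.
#' @examples
#' rg <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 60), strand = "+")
#' rd <- GenomicRanges::GRanges("cl", IRanges::IRanges(30, 56), strand = "+",
#'                              count = 120L)
#' sp <- computeScores(rd, rg)
#' granges(sp)$score[30]  # 1: the only local 5' end
#' @export
computeScores <- function(reads, regions, config = scoreConfigDefaults(),
                          end = c("five_prime", "downstream_of_three_prime")) {
  end <- match.arg(end)
  up <- config$upstream; down <- config$downstream
  regionNames <- names(regions)
  if (is.null(regionNames)) regionNames <- regions$name
  if (is.null(regionNames)) regionNames <- paste0("region", seq_along(regions))
  endPos <- .endPositions(reads, end)
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  readContig <- as.character(GenomicRanges::seqnames(reads))
  readStrand <- as.character(GenomicRanges::strand(reads))
  out <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    rStart <- GenomicRanges::start(regions)[r]
    rEnd <- GenomicRanges::end(regions)[r]
    rStrand <- as.character(GenomicRanges::strand(regions))[r]
    rContig <- as.character(GenomicRanges::seqnames(regions))[r]
    n <- rEnd - rStart + 1L
    sel <- readContig == rContig & readStrand == rStrand &
      endPos >= rStart & endPos <= rEnd
    f <- numeric(n)
    if (any(sel)) {
      idx <- endPos[sel] - rStart + 1L
      agg <- vapply(split(cnt[sel], idx), sum, numeric(1))
      f[as.integer(names(agg))] <- agg
    }
    # transcript orientation: index 1 = transcript 5' end
    if (rStrand == "-") f <- rev(f)
    cs <- c(0, cumsum(f))
    i <- seq_len(n)
    lo <- pmax(1L, i - up)
    hi <- pmin(n, i + down)
    localTotal <- cs[hi + 1L] - cs[lo]
    score <- ifelse(localTotal > 0, f / localTotal, 0)
    truncated <- (i - up) < 1L | (i + down) > n
    if (rStrand == "-") {
      f <- rev(f); localTotal <- rev(localTotal); score <- rev(score)
      truncated <- rev(truncated)
    }
    out[[r]] <- GenomicRanges::GRanges(
      rContig, IRanges::IRanges(rStart:rEnd, width = 1L), strand = rStrand,
      region = regionNames[r], f = f, localTotal = localTotal,
      score = score, covered = localTotal >= config$minLocalReads,
      truncated = truncated)
  }
  gr <- do.call(c, out)
  new("ScoredPositions", positions = gr, config = config, end = end)
}

#' Assign covered positions to score bins
#'
#' Bin 0 holds covered positions with score exactly 0 (never observed as a
#' 5' end); the remaining covered positions are ordered by (score, contig,
#' position) -- a stable, deterministic tie-break -- and split into `nBins`
#' contiguous groups whose sizes differ by at most one, ordered lowest to
#' highest score. Uncovered positions get bin NA. Fewer positive positions
#' than bins yields that many singleton bins, with a warning.
#'
#' @param scored a [ScoredPositions-class] object.
#' @param nBins number of positive-score bins (default from the scoring
#'   config, 20).
#' @return `scored` with a `bin` metadata column added.
#' @export
binPositions <- function(scored, nBins = scoreConfig(scored)$nBins) {
  gr <- scored@positions
  bin <- rep(NA_integer_, length(gr))
  covered <- gr$covered
  bin[covered & gr$score == 0] <- 0L
  posIdx <- which(covered & gr$score > 0)
  m <- length(posIdx)
  if (m > 0L) {
    if (m < nBins) {
      warning("only ", m, " positive-score positions for ", nBins,
              " bins; producing ", m, " singleton bins")
      nBins <- m
    }
    ord <- order(gr$score[posIdx],
                 as.character(GenomicRanges::seqnames(gr))[posIdx],
                 GenomicRanges::start(gr)[posIdx], method = "radix")
    bin[posIdx[ord]] <- as.integer(ceiling(seq_len(m) * nBins / m))
  }
  gr$bin <- bin
  methods::initialize(scored, positions = gr)
}

#' Score distributions by sequence context
#'
#' Groups covered-position scores by the base, or the trinucleotide
#' starting, at each position (strand aware along the transcript) and
#' summarises each group.
#'
#' @param scored a [ScoredPositions-class] object.
#' @param seqs named DNAStringSet of the region sequences.
#' @param context `"nucleotide"` or `"trinucleotide"`.
#' @return list with `perPosition` (data.frame of `context`, `score`,
#'   `bin` if present) and `summary` (data.frame of `context`, `n`,
#'   `median`, `q1`, `q3`, `mean`), contexts rendered in RNA alphabet.
#' @export
scoreByContext <- function(scored, seqs,
                           context = c("nucleotide", "trinucleotide")) {
  context <- match.arg(context)
  k <- if (context == "nucleotide") 1L else 3L
  gr <- coveredPositions(scored)
  ctx <- .kmerAtGRanges(GenomicRanges::start(gr),
                        as.character(GenomicRanges::strand(gr)),
                        as.character(GenomicRanges::seqnames(gr)), seqs, k)
  ok <- !is.na(ctx)
  per <- data.frame(context = renderRNA(ctx[ok]), score = gr$score[ok])
  if (!is.null(gr$bin)) per$bin <- gr$bin[ok]
  sm <- do.call(rbind, lapply(split(per$score, per$context), function(s) {
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(s), median = q[2], q1 = q[1], q3 = q[3],
               mean = mean(s))
  }))
  sm <- cbind(context = rownames(sm), sm)
  rownames(sm) <- NULL
  list(perPosition = per, summary = sm)
}

#' Per-bin sequence composition
#'
#' For each score bin, the frequency of each trinucleotide starting at the
#' member positions, and of each single base, over positions with an
#' extractable context. Needs [binPositions()] to have been run.
#'
#' @inheritParams scoreByContext
#' @return list of two matrices, `trinucleotide` (64 x bins) and `base`
#'   (4 x bins); columns are bin indices, each column sums to 1 (or is all
#'   NA for an empty bin). Row names are RNA-alphabet.
#' @export
binComposition <- function(scored, seqs) {
  gr <- coveredPositions(scored)
  if (is.null(gr$bin)) stop("run binPositions() first")
  tri <- .kmerAtGRanges(GenomicRanges::start(gr),
                        as.character(GenomicRanges::strand(gr)),
                        as.character(GenomicRanges::seqnames(gr)), seqs, 3L)
  bins <- sort(unique(stats::na.omit(gr$bin)))
  triM <- matrix(NA_real_, 64L, length(bins),
                 dimnames = list(renderRNA(.TRINUCLEOTIDES), bins))
  baseM <- matrix(NA_real_, 4L, length(bins),
                  dimnames = list(renderRNA(.BASES), bins))
  for (j in seq_along(bins)) {
    sel <- which(gr$bin == bins[j] & !is.na(tri))
    if (!length(sel)) next
    tf <- table(factor(tri[sel], levels = .TRINUCLEOTIDES))
    triM[, j] <- as.numeric(tf) / sum(tf)
    bf <- table(factor(substr(tri[sel], 1, 1), levels = .BASES))
    baseM[, j] <- as.numeric(bf) / sum(bf)
  }
  list(trinucleotide = triM, base = baseM)
}

#' Base frequencies and enrichment around bin positions
#'
#' For transcript-oriented offsets -flank..+flank around every position of
#' a chosen bin, the base frequency at each offset, the same for a
#' background set (all covered positions by default), and their ratio. A
#' -1G cleavage penalty appears as G enrichment below 1 at offset -1; an
#' upstream GC preference as G/C enrichment above 1 at upstream offsets.
#'
#' @inheritParams scoreByContext
#' @param binIndex bin to profile (e.g. the top bin).
#' @param flank offsets to cover on each side (default 10).
#' @param background `"all_scored"` (all covered positions) or a GRanges of
#'   positions to use instead.
#' @return list of three 4 x (2 flank + 1) matrices: `freq`,
#'   `backgroundFreq`, `enrichment`; columns named by offset.
#' @export
motifAround <- function(scored, seqs, binIndex, flank = 10L,
                        background = "all_scored") {
  gr <- coveredPositions(scored)
  if (is.null(gr$bin)) stop("run binPositions() first")
  sel <- gr[!is.na(gr$bin) & gr$bin == binIndex]
  bg <- if (methods::is(background, "GRanges")) background else gr
  offsets <- (-flank):flank
  freqAt <- function(g) {
    strandv <- as.character(GenomicRanges::strand(g))
    contig <- as.character(GenomicRanges::seqnames(g))
    anchor <- GenomicRanges::start(g)
    m <- matrix(NA_real_, 4L, length(offsets),
                dimnames = list(renderRNA(.BASES), offsets))
    for (j in seq_along(offsets)) {
      # transcript orientation: positive offsets run toward the 3' end
      pos <- ifelse(strandv == "+", anchor + offsets[j], anchor - offsets[j])
      b <- .kmerAtGRanges(pos, strandv, contig, seqs, 1L)
      tb <- table(factor(b[!is.na(b)], levels = .BASES))
      if (sum(tb) > 0) m[, j] <- as.numeric(tb) / sum(tb)
    }
    m
  }
  fg <- freqAt(sel)
  bgF <- freqAt(bg)
  list(freq = fg, backgroundFreq = bgF, enrichment = fg / bgF)
}

#' Correlate 5' end and 3'-downstream scores
#'
#' Pearson correlation of definition scores over positions covered in both
#' a 5'-end scoring and a downstream-of-3'-end scoring. Under phased
#' tail-to-head processing the two agree strongly.
#'
#' @param scored5,scored3 [ScoredPositions-class] objects (typically
#'   `end = "five_prime"` and `end = "downstream_of_three_prime"`).
#' @return list with `r`, `p`, `n`, and `flag` (`"ok"` or `"undefined"`
#'   when fewer than 3 shared covered positions exist).
#' @export
correlateFiveThree <- function(scored5, scored3) {
  g5 <- coveredPositions(scored5)
  g3 <- coveredPositions(scored3)
  k5 <- paste(as.character(GenomicRanges::seqnames(g5)),
              GenomicRanges::start(g5), as.character(GenomicRanges::strand(g5)))
  k3 <- paste(as.character(GenomicRanges::seqnames(g3)),
              GenomicRanges::start(g3), as.character(GenomicRanges::strand(g3)))
  common <- intersect(k5, k3)
  if (length(common) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = length(common),
                flag = "undefined"))
  s5 <- g5$score[match(common, k5)]
  s3 <- g3$score[match(common, k3)]
  ct <- stats::cor.test(s5, s3, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       flag = "ok")
}
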