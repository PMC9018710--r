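# Joining per-base conservation scores and variant positions to the
# definition-score bins: per-bin means with confidence intervals,
# acceleration-call fractions with two-proportion Z tests, and SNP
# frequencies, with optional restriction to U or U-in-stop-codon contexts.

# phyloP's -log10(0.05): scores strictly below this are significant
# acceleration (positive selection) calls.
.ACCEL_THRESHOLD <- -1.30103

#' Subset binned positions by sequence context
#'
#' Restricts the covered, binned positions of a [ScoredPositions-class]
#' object to positions whose transcript base is U (`"U"`), or whose
#' trinucleotide starting there is a stop codon (`"stopU"`). Base
#' composition differs in conservation (A/U positions are more conserved
#' genome wide than C/G), so context-matched subsets separate that effect
#' from the cleavage-preference signal.
#'
#' @param scored a binned [ScoredPositions-class] object.
#' @param seqs named DNAStringSet of the region sequences.
#' @param subset `"all"`, `"U"` or `"stopU"`.
#' @return GRanges of the selected covered positions (with `bin`).
#' @export
subsetByContext <- function(scored, seqs, subset = c("all", "U", "stopU")) {
  subset <- match.arg(subset)
  gr <- coveredPositions(scored)
  if (subset == "all") return(gr)
  tri <- .kmerAtGRanges(GenomicRanges::start(gr),
                        as.character(GenomicRanges::strand(gr)),
                        as.character(GenomicRanges::seqnames(gr)), seqs, 3L)
  keep <- if (subset == "U") !is.na(tri) & startsWith(tri, "T")
          else !is.na(tri) & tri %in% .STOP_CODONS
  gr[keep]
}

#' Join a per-base track to binned positions
#'
#' Inner join of a per-base score track onto binned positions by (contig,
#' position); positions absent from the track are dropped and their count
#' reported via a message.
#'
#' @param positions GRanges of binned positions (e.g. from
#'   [subsetByContext()] or [coveredPositions()] after [binPositions()]).
#' @param track GRanges of width-1 positions with a `value` column (see
#'   [readTrack()] or [simulateTrack()]).
#' @return data.frame with `contig`, `pos`, `strand`, `bin`, `score`,
#'   `value`.
#' @export
joinTrack <- function(positions, track) {
  kp <- paste(as.character(GenomicRanges::seqnames(positions)),
              GenomicRanges::start(positions))
  kt <- paste(as.character(GenomicRanges::seqnames(track)),
              GenomicRanges::start(track))
  hit <- match(kp, kt)
  dropped <- sum(is.na(hit))
  if (dropped > 0)
    message(dropped, " position(s) missing from the track were dropped")
  ok <- !is.na(hit)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(positions))[ok],
    pos = GenomicRanges::start(positions)[ok],
    strand = as.character(GenomicRanges::strand(positions))[ok],
    bin = positions$bin[ok],
    score = positions$score[ok],
    value = track$value[hit[ok]])
}

#' Per-bin mean conservation with confidence intervals
#'
#' Mean track value per bin with a t-based confidence interval of the
#' mean (absent for bins with fewer than 2 positions or zero variance,
#' where the interval degenerates to the mean).
#'
#' @param pairs data.frame from [joinTrack()] (needs `bin` and `value`).
#' @param conf confidence level (default 0.95).
#' @return data.frame with `bin`, `n`, `mean`, `ciLow`, `ciHigh`.
#' @export
binMeanCI <- function(pairs, conf = 0.95) {
  out <- lapply(split(pairs$value, pairs$bin), function(v) {
    n <- length(v); m <- mean(v)
    if (n < 2L || stats::sd(v) == 0)
      return(data.frame(n = n, mean = m, ciLow = m, ciHigh = m))
    half <- stats::qt(1 - (1 - conf) / 2, n - 1L) * stats::sd(v) / sqrt(n)
    data.frame(n = n, mean = m, ciLow = m - half, ciHigh = m + half)
  })
  df <- do.call(rbind, out)
  df <- cbind(bin = as.integer(names(out)), df)
  rownames(df) <- NULL
  df[order(df$bin), , drop = FALSE]
}

#' Per-bin acceleration-call fraction with Z tests
#'
#' Fraction of positions per bin whose track value lies strictly below the
#' acceleration threshold (default -1.30103, phyloP's significance bound
#' for positive selection), and a two-sided two-proportion Z test of each
#' bin against all remaining bins pooled.
#'
#' @param pairs data.frame from [joinTrack()].
#' @param threshold acceleration threshold (strict `<`).
#' @return data.frame with `bin`, `n`, `accelerated`, `fraction`, `z`,
#'   `p` (NA with a flag when the pooled rate is 0 or a bin is empty).
#' @export
acceleratedFraction <- function(pairs, threshold = .ACCEL_THRESHOLD) {
  acc <- pairs$value < threshold
  bins <- sort(unique(pairs$bin))
  out <- lapply(bins, function(b) {
    inBin <- pairs$bin == b
    n1 <- sum(inBin); x1 <- sum(acc[inBin])
    n2 <- sum(!inBin); x2 <- sum(acc[!inBin])
    z <- p <- NA_real_
    if (n1 > 0 && n2 > 0 && (x1 + x2) > 0 && (x1 + x2) < (n1 + n2)) {
      pPool <- (x1 + x2) / (n1 + n2)
      z <- (x1 / n1 - x2 / n2) /
        sqrt(pPool * (1 - pPool) * (1 / n1 + 1 / n2))
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(bin = b, n = n1, accelerated = x1,
               fraction = if (n1 > 0) x1 / n1 else NA_real_, z = z, p = p)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Per-bin SNP frequency
#'
#' Fraction of positions in each bin that appear in a set of variant
#' positions (membership by contig and position).
#'
#' @param positions GRanges of binned positions.
#' @param snps GRanges of width-1 SNP positions (e.g. read with
#'   [readIntervalBed()] from a BED of single-base intervals).
#' @return data.frame with `bin`, `n`, `snps`, `frequency`.
#' @export
snpFrequency <- function(positions, snps) {
  kp <- paste(as.character(GenomicRanges::seqnames(positions)),
              GenomicRanges::start(positions))
  ks <- unique(paste(as.character(GenomicRanges::seqnames(snps)),
                     GenomicRanges::start(snps)))
  isSnp <- kp %in% ks
  out <- lapply(split(isSnp, positions$bin), function(v) {
    data.frame(n = length(v), snps = sum(v), frequency = mean(v))
  })
  df <- do.call(rbind, out)
  df <- cbind(bin = as.integer(names(out)), df)
  rownames(df) <- NULL
  df[order(df$bin), , drop = FALSE]
}
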