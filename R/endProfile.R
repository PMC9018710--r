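# 5' end and 3'-downstream composition statistics: trinucleotide count
# tables, positional codon frequencies, read filters, the stop-codon ratio
# and its one-sample enrichment test, and length profiles.

#' Tabulate trinucleotides at read 5' ends
#'
#' Builds the 64-cell [EndCountTable-class] of trinucleotides starting at
#' read 5' ends. Reads outside the length window are dropped. When
#' `dedupCap` is set, records sharing the exact coordinate tuple (contig,
#' start, end, strand) contribute at most `dedupCap` counts in total, which
#' damps extremely abundant contaminating sequences. Reads whose 5'
#' trinucleotide is unavailable (sequence boundary or N) are excluded from
#' this table only.
#'
#' @param reads GRanges of reads with an optional `count` column.
#' @param seqs named DNAStringSet the reads map to.
#' @param window length-2 numeric, inclusive read-length window in nt
#'   (default c(26, 32), the adult mouse piRNA window; use c(24, 31) for
#'   cross-species work or c(23, 32) for prenatal samples).
#' @param dedupCap optional per-coordinate count cap (e.g. 100).
#' @param seed unused when capping by coordinate aggregation (which is
#'   deterministic) but accepted for interface stability.
#' @param metadata list merged into the table's metadata.
#' @return An [EndCountTable-class]; empty input (or everything filtered)
#'   gives a table with total 0 and metadata flag `empty = TRUE`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(cl = paste(rep("TAAC", 20), collapse = "")))
#' rd <- GenomicRanges::GRanges("cl", IRanges::IRanges(1, 27), strand = "+",
#'                              count = 1L)
#' endCounts(tabulateFivePrime(rd, seqs))["TAA"]
#' @export
tabulateFivePrime <- function(reads, seqs, window = c(26, 32),
                              dedupCap = NULL, seed = NULL,
                              metadata = list()) {
  len <- GenomicRanges::width(reads)
  reads <- reads[len >= window[1] & len <= window[2]]
  if (length(reads) && !is.null(dedupCap)) {
    reads <- .capDuplicates(reads, dedupCap)
  }
  md <- c(metadata, list(lengthWindow = window,
                         dedupCap = if (is.null(dedupCap)) NA else dedupCap))
  if (length(reads) == 0L)
    return(EndCountTable(metadata = c(md, list(empty = TRUE))))
  tri <- fivePrimeTrinucleotide(reads, seqs)
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  ok <- !is.na(tri)
  counts <- vapply(split(cnt[ok], factor(tri[ok], levels = .TRINUCLEOTIDES)),
                   sum, numeric(1))
  EndCountTable(counts, metadata = md)
}

# Aggregate identical (contig, start, end, strand) records and cap the
# summed multiplicity. Aggregation-then-cap is deterministic: which copies
# are removed is immaterial because capped copies are interchangeable.
.capDuplicates <- function(reads, cap) {
  key <- paste(as.character(GenomicRanges::seqnames(reads)),
               GenomicRanges::start(reads), GenomicRanges::end(reads),
               as.character(GenomicRanges::strand(reads)))
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  tot <- tapply(cnt, key, sum)
  first <- !duplicated(key)
  out <- reads[first]
  out$count <- as.integer(pmin(tot[key[first]], cap))
  out
}

#' Positional codon frequency along reads
#'
#' For each read position p = 1..P, the frequency of each trinucleotide
#' beginning at that position (strand aware). A 5'-restricted cleavage bias
#' shows up as stop-codon enrichment in column 1 only.
#'
#' @inheritParams tabulateFivePrime
#' @param positions integer vector of 1-based read positions (default 1:10).
#' @return 64 x length(positions) matrix of frequencies; every column sums
#'   to 1 over represented trinucleotides. Row names are RNA-alphabet.
#' @export
positionalCodonFrequency <- function(reads, seqs, positions = 1:10) {
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  strandv <- as.character(GenomicRanges::strand(reads))
  .checkStrand(strandv)
  contig <- as.character(GenomicRanges::seqnames(reads))
  out <- matrix(0, nrow = 64L, ncol = length(positions),
                dimnames = list(renderRNA(.TRINUCLEOTIDES),
                                as.character(positions)))
  for (j in seq_along(positions)) {
    off <- positions[j] - 1L
    pos <- ifelse(strandv == "+", GenomicRanges::start(reads) + off,
                  GenomicRanges::end(reads) - off)
    tri <- .kmerAtGRanges(pos, strandv, contig, seqs, 3L)
    ok <- !is.na(tri)
    if (!any(ok)) next
    cs <- vapply(split(cnt[ok], factor(tri[ok], levels = .TRINUCLEOTIDES)),
                 sum, numeric(1))
    out[, j] <- cs / sum(cs)
  }
  out
}

#' Exclude reads with an A at position 10
#'
#' Removes reads carrying an A at 5'-relative position 10 (1-based), the
#' ping-pong signature position: PIWI slicers cut their targets between
#' guide positions 10 and 11, leaving responder piRNAs with 10A. Filtering
#' them enriches for phased-biogenesis products. Strand aware; reads
#' shorter than 10 nt, or with N at position 10, are kept.
#'
#' @inheritParams tabulateFivePrime
#' @return the filtered GRanges.
#' @export
excludeTenA <- function(reads, seqs) {
  if (length(reads) == 0L) return(reads)
  strandv <- as.character(GenomicRanges::strand(reads))
  .checkStrand(strandv)
  pos <- ifelse(strandv == "+", GenomicRanges::start(reads) + 9L,
                GenomicRanges::end(reads) - 9L)
  base <- .kmerAtGRanges(pos, strandv,
                         as.character(GenomicRanges::seqnames(reads)),
                         seqs, 1L)
  tooShort <- GenomicRanges::width(reads) < 10L
  reads[tooShort | is.na(base) | base != "A"]
}

#' Stop-codon ratio of an end-count table
#'
#' The mean 5' end frequency of the three stop codons (UAA, UAG, UGA)
#' divided by the mean frequency of the 13 other Unn trinucleotides. The
#' ratio is invariant to rescaling all counts and to any change confined to
#' non-U cells.
#'
#' @param x an [EndCountTable-class] or a named numeric vector of counts.
#' @param ... unused.
#' @return list with `meanStop`, `meanOtherUnn`, `ratio`, and `flag`
#'   (`"ok"`, `"empty"` when the table total is 0, or
#'   `"undefined"` when the other-Unn mean is 0).
#' @examples
#' stopCodonRatio(EndCountTable(c(TAA = 10, TAG = 10, TGA = 10, TTT = 5,
#'                                TCC = 5)))$ratio
#' @rdname stopCodonRatio
#' @export
setMethod("stopCodonRatio", "EndCountTable", function(x, ...) {
  stopCodonRatio(x@counts)
})

#' @rdname stopCodonRatio
#' @export
setMethod("stopCodonRatio", "numeric", function(x, ...) {
  cnt <- stats::setNames(numeric(64), .TRINUCLEOTIDES)
  nm <- chartr("U", "T", names(x))
  cnt[nm[nm %in% .TRINUCLEOTIDES]] <- x[nm %in% .TRINUCLEOTIDES]
  tot <- sum(cnt)
  if (tot == 0)
    return(list(meanStop = NA_real_, meanOtherUnn = NA_real_,
                ratio = NA_real_, flag = "empty"))
  f <- cnt / tot
  meanStop <- mean(f[.STOP_CODONS])
  meanOther <- mean(f[.OTHER_UNN])
  if (meanOther == 0)
    return(list(meanStop = meanStop, meanOtherUnn = 0,
                ratio = NA_real_, flag = "undefined"))
  list(meanStop = meanStop, meanOtherUnn = meanOther,
       ratio = meanStop / meanOther, flag = "ok")
})

#' One-sample enrichment test of per-replicate stop-codon ratios
#'
#' Two-sided one-sample t test of per-replicate ratios against the null
#' value 1, with a t-based confidence interval. Testing on the log scale
#' (against log-ratio 0) is available via `logScale`.
#'
#' @param ratios numeric vector of per-replicate stop-codon ratios (at
#'   least 2).
#' @param logScale test log(ratios) against 0 instead (default FALSE).
#' @param conf confidence level (default 0.95).
#' @return list with `mean` (of the ratios, always on the natural scale),
#'   `ciLow`, `ciHigh`, `t`, `df`, `p`, and `flag` (`"ok"` or
#'   `"zero_variance"`, in which case p is reported as below machine
#'   precision when the mean differs from 1, or exactly 1 otherwise).
#' @examples
#' foldEnrichmentTest(c(2.1, 2.2, 2.0, 2.2, 2.1))
#' @export
foldEnrichmentTest <- function(ratios, logScale = FALSE, conf = 0.95) {
  stopifnot(length(ratios) >= 2L)
  y <- if (logScale) log(ratios) else ratios
  mu <- if (logScale) 0 else 1
  if (stats::sd(y) == 0) {
    p <- if (isTRUE(all.equal(mean(y), mu))) 1 else .Machine$double.xmin
    return(list(mean = mean(ratios), ciLow = mean(ratios),
                ciHigh = mean(ratios), t = NA_real_,
                df = length(ratios) - 1L, p = p, flag = "zero_variance"))
  }
  tt <- stats::t.test(y, mu = mu, conf.level = conf)
  ci <- as.numeric(tt$conf.int)
  if (logScale) ci <- exp(ci)
  list(mean = mean(ratios), ciLow = ci[1], ciHigh = ci[2],
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flag = "ok")
}

#' Composition immediately downstream of 3' ends
#'
#' Per read length, the fraction of reads with a U immediately after the 3'
#' end and the fraction whose downstream trinucleotide is a stop codon.
#' Under phased biogenesis the downstream window is the next pre-piRNA's 5'
#' end, so untrimmed (pre-piRNA) populations show 1U and stop-codon
#' enrichment there, while 3'-trimmed mature piRNAs show background levels.
#' Baselines assuming equal trinucleotide abundance are 1/4 (1U) and 3/64
#' (stop codons).
#'
#' @inheritParams tabulateFivePrime
#' @param byLength also return per-length rows (default TRUE).
#' @return data.frame with columns `length` (NA row = all reads pooled),
#'   `n` (total weighted reads with an extractable downstream 3-mer),
#'   `oneU`, `stopFraction`, `expectedOneU` (0.25) and `expectedStop`
#'   (3/64).
#' @export
downstreamProfile <- function(reads, seqs, byLength = TRUE) {
  tri <- downstreamKmer(reads, seqs, 3L)
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  ok <- !is.na(tri)
  len <- GenomicRanges::width(reads)
  one <- function(idx) {
    w <- cnt[idx]
    n <- sum(w)
    if (n == 0) return(c(n = 0, oneU = NA_real_, stopFraction = NA_real_))
    c(n = n,
      oneU = sum(w[startsWith(tri[idx], "T")]) / n,
      stopFraction = sum(w[tri[idx] %in% .STOP_CODONS]) / n)
  }
  rows <- list(cbind(length = NA_integer_, t(one(which(ok)))))
  if (byLength) {
    for (L in sort(unique(len[ok]))) {
      rows[[length(rows) + 1L]] <-
        cbind(length = L, t(one(which(ok & len == L))))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$expectedOneU <- 0.25
  out$expectedStop <- 3 / 64
  out
}

#' Read length histogram
#'
#' Counts per read length, weighted by multiplicity; the counts sum to the
#' total (weighted) read count.
#'
#' @param reads GRanges of reads with an optional `count` column.
#' @return named numeric vector, names = lengths in nt.
#' @export
lengthDistribution <- function(reads) {
  if (length(reads) == 0L) return(stats::setNames(numeric(0), character(0)))
  cnt <- if (is.null(reads$count)) rep(1L, length(reads)) else reads$count
  len <- GenomicRanges::width(reads)
  vapply(split(cnt, len), sum, numeric(1))
}
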