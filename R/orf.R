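# Stop codons and upstream ORFs in precursor transcripts, and the score
# comparisons between ORF classes: Wilcoxon rank-sum between groups and a
# size-matched empirical resampling test for experimentally confirmed ORFs.

#' Find stop codons in transcripts
#'
#' Every occurrence of TAA, TAG or TGA on the sense strand of each
#' transcript, in any frame, overlaps allowed.
#'
#' @param seqs named DNAStringSet (or character vector) of transcripts.
#' @return data.frame with `transcript`, `pos` (1-based position of the
#'   stop trinucleotide's first base), `codon` (DNA alphabet), sorted by
#'   transcript then position.
#' @examples
#' findStopCodons(c(tx = "TAATAA"))$pos  # 1 and 4
#' @export
findStopCodons <- function(seqs) {
  chars <- .seqsAsChar(seqs)
  out <- lapply(names(chars), function(id) {
    s <- Biostrings::DNAString(chars[[id]])
    hits <- lapply(.STOP_CODONS, function(codon) {
      m <- Biostrings::matchPattern(codon, s)
      if (length(m) == 0L) return(NULL)
      data.frame(transcript = id, pos = BiocGenerics::start(m), codon = codon)
    })
    do.call(rbind, hits)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    return(data.frame(transcript = character(0), pos = integer(0),
                      codon = character(0)))
  df[order(df$transcript, df$pos), , drop = FALSE]
}

#' Classify stop codons by upstream ORF membership
#'
#' Walks upstream in frame from each stop codon: if an ATG is met before
#' any in-frame stop codon (and before the transcript start), the site
#' closes an ORF whose length in amino acids counts the codons from that
#' ATG up to, but excluding, the stop. The site is classed in-ORF when the
#' length lies in `[minAa, maxAa]`.
#'
#' @param sites data.frame from [findStopCodons()].
#' @param seqs the same transcript sequences.
#' @param minAa,maxAa admissible ORF length bounds in amino acids
#'   (defaults 3 and 100).
#' @return `sites` with logical `inOrf` and integer `orfLengthAa` (NA when
#'   not in an admissible ORF) columns added.
#' @examples
#' s <- findStopCodons(c(tx = "ATGAAACCCTAA"))
#' classifyInOrf(s, c(tx = "ATGAAACCCTAA"))  # 3-aa ORF
#' @export
classifyInOrf <- function(sites, seqs, minAa = 3L, maxAa = 100L) {
  chars <- .seqsAsChar(seqs)
  nSites <- nrow(sites)
  inOrf <- logical(nSites)
  lenAa <- rep(NA_integer_, nSites)
  for (i in seq_len(nSites)) {
    s <- chars[[sites$transcript[i]]]
    p <- sites$pos[i] - 3L
    while (p >= 1L) {
      codon <- substr(s, p, p + 2L)
      if (codon == "ATG") {
        aa <- (sites$pos[i] - p) %/% 3L
        if (aa >= minAa && aa <= maxAa) {
          inOrf[i] <- TRUE
          lenAa[i] <- aa
        }
        break
      }
      if (codon %in% .STOP_CODONS) break
      p <- p - 3L
    }
  }
  sites$inOrf <- inOrf
  sites$orfLengthAa <- lenAa
  sites
}

#' ORF size strata
#'
#' The three similar-size strata used for grouping and size matching:
#' 3-8, 9-19 and 20-100 amino acids.
#'
#' @param aa integer vector of ORF lengths in amino acids.
#' @return factor with levels `"3-8"`, `"9-19"`, `"20-100"`; NA outside
#'   3-100.
#' @export
orfSizeStratum <- function(aa) {
  cut(aa, breaks = c(2.5, 8.5, 19.5, 100.5),
      labels = c("3-8", "9-19", "20-100"))
}

#' Compare definition scores between ORF groups
#'
#' Two-sided Wilcoxon rank-sum test of definition scores between two
#' groups of stop-codon sites (in-ORF vs not, or between size strata).
#'
#' @param scoresA,scoresB numeric score vectors for the two groups; both
#'   must be non-empty.
#' @return list with `W`, `p`, `nA`, `nB`.
#' @export
compareOrfScores <- function(scoresA, scoresB) {
  if (length(scoresA) == 0L || length(scoresB) == 0L)
    stop("both groups must be non-empty")
  wt <- stats::wilcox.test(scoresA, scoresB, alternative = "two.sided",
                           exact = FALSE)
  list(W = unname(wt$statistic), p = wt$p.value,
       nA = length(scoresA), nB = length(scoresB))
}

#' Size-matched empirical test of mean definition score
#'
#' Compares the observed mean score of confirmed sites against a
#' resampling distribution of control means: each resample draws, for
#' every confirmed site, one control site from the same ORF size stratum
#' (with replacement), and records the mean of the drawn scores. The
#' empirical p is the fraction of resampled control means at or below the
#' observed mean (a one-sided test of whether the observed mean is low).
#'
#' @param confirmedScores,confirmedStrata scores and size strata of the
#'   confirmed sites.
#' @param controlScores,controlStrata scores and size strata of the
#'   control pool; every stratum present among the confirmed sites must be
#'   populated.
#' @param nResamples number of resamples (default 10000).
#' @param seed integer seed; the full test is bit-reproducible given one.
#' @param conf confidence level for the control-mean interval
#'   (default 0.95).
#' @return list with `observedMean`, `controlMeans` (length `nResamples`),
#'   `ciLow`, `ciHigh` (quantiles of the control means), and `p`.
#' @export
empiricalSizeMatchedTest <- function(confirmedScores, confirmedStrata,
                                     controlScores, controlStrata,
                                     nResamples = 10000L, seed = NULL,
                                     conf = 0.95) {
  stopifnot(length(confirmedScores) == length(confirmedStrata),
            length(controlScores) == length(controlStrata),
            nResamples >= 1L)
  confirmedStrata <- as.character(confirmedStrata)
  controlStrata <- as.character(controlStrata)
  strata <- unique(confirmedStrata)
  pools <- lapply(strata, function(st) controlScores[controlStrata == st])
  names(pools) <- strata
  empty <- strata[lengths(pools) == 0L]
  if (length(empty))
    stop("no control sites in stratum: ", paste(empty, collapse = ", "))
  nPer <- table(factor(confirmedStrata, levels = strata))
  nConf <- length(confirmedScores)
  controlMeans <- .withSeed(seed, {
    sums <- numeric(nResamples)
    for (st in strata) {
      pool <- pools[[st]]
      k <- as.integer(nPer[[st]])
      draws <- matrix(pool[sample.int(length(pool), nResamples * k,
                                      replace = TRUE)],
                      nrow = nResamples)
      sums <- sums + rowSums(draws)
    }
    sums / nConf
  })
  observed <- mean(confirmedScores)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(controlMeans, c(alpha, 1 - alpha), names = FALSE)
  list(observedMean = observed, controlMeans = controlMeans,
       ciLow = ci[1], ciHigh = ci[2],
       p = mean(controlMeans <= observed))
}
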