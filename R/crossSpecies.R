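# Cross-species stop-codon enrichment: expressed-cluster calling, library
# QC, robustness classification, trinucleotide composition normalization,
# equal-weight species grouping, the Fisher group test and the analytic
# null for robust enrichment under a uniform ranking.

#' Expressed-cluster filter configuration
#'
#' @param minUniqueReads minimum uniquely mapped reads (default 100).
#' @param minStrandFraction minimum fraction of reads from the preferred
#'   strand (default 0.80).
#' @param minOneUFraction minimum 1U fraction (default 0.40).
#' @return parameter list.
#' @export
clusterFilterConfig <- function(minUniqueReads = 100L,
                                minStrandFraction = 0.80,
                                minOneUFraction = 0.40) {
  stopifnot(minStrandFraction > 0, minStrandFraction <= 1,
            minOneUFraction > 0, minOneUFraction <= 1)
  list(minUniqueReads = minUniqueReads,
       minStrandFraction = minStrandFraction,
       minOneUFraction = minOneUFraction)
}

#' Library QC configuration
#'
#' @param minClusterReads minimum reads on expressed clusters for the
#'   refined analysis (default 10000).
#' @param minTotalReads minimum total reads for the global analysis
#'   (default 100000).
#' @param lengthWindow read-length window in nt (default c(24, 31)).
#' @param positionCap per-position read cap (default 100).
#' @return parameter list.
#' @export
libraryQcConfig <- function(minClusterReads = 10000L,
                            minTotalReads = 100000L,
                            lengthWindow = c(24L, 31L),
                            positionCap = 100L) {
  list(minClusterReads = minClusterReads, minTotalReads = minTotalReads,
       lengthWindow = lengthWindow, positionCap = positionCap)
}

#' Call expressed piRNA clusters
#'
#' Applies the three inclusive thresholds: uniquely mapped reads, fraction
#' from the preferred strand, and 1U fraction.
#'
#' @param stats data.frame with columns `cluster`, `uniqueReads`,
#'   `strandFraction`, `oneUFraction`.
#' @param config list from [clusterFilterConfig()].
#' @return character vector of expressed cluster names.
#' @examples
#' st <- data.frame(cluster = c("a", "b"),
#'                  uniqueReads = c(150, 50),
#'                  strandFraction = c(0.85, 0.9),
#'                  oneUFraction = c(0.45, 0.5))
#' callExpressedClusters(st)  # "a"
#' @export
callExpressedClusters <- function(stats, config = clusterFilterConfig()) {
  keep <- stats$uniqueReads >= config$minUniqueReads &
    stats$strandFraction >= config$minStrandFraction &
    stats$oneUFraction >= config$minOneUFraction
  stats$cluster[keep]
}

#' Library QC flags
#'
#' @param clusterReads reads mapping to expressed clusters.
#' @param totalReads total reads in the library.
#' @param config list from [libraryQcConfig()].
#' @return list with logical `refined` and `global` pass flags.
#' @export
libraryQc <- function(clusterReads, totalReads, config = libraryQcConfig()) {
  list(refined = clusterReads >= config$minClusterReads,
       global = totalReads >= config$minTotalReads)
}

#' Classify stop-codon enrichment robustness
#'
#' `robust`: every stop codon's frequency strictly exceeds every non-stop
#' trinucleotide's (ties demote). `near_robust`: all three stop codons
#' rank within the five most abundant trinucleotides. `none`: otherwise.
#' Robust always implies near-robust; the classification is invariant to
#' count rescaling.
#'
#' @param x an [EndCountTable-class] or a named numeric vector of counts
#'   or frequencies over the 64 trinucleotides.
#' @return `"robust"`, `"near_robust"` or `"none"`.
#' @examples
#' classifyRobustness(c(UAA = 30, UAG = 25, UGA = 20, UUU = 19))
#' @rdname classifyRobustness
#' @export
setMethod("classifyRobustness", "EndCountTable", function(x) {
  classifyRobustness(x@counts)
})

#' @rdname classifyRobustness
#' @export
setMethod("classifyRobustness", "numeric", function(x) {
  cnt <- stats::setNames(numeric(64), .TRINUCLEOTIDES)
  nm <- chartr("U", "T", names(x))
  cnt[nm[nm %in% .TRINUCLEOTIDES]] <- x[nm %in% .TRINUCLEOTIDES]
  stopF <- cnt[.STOP_CODONS]
  otherF <- cnt[setdiff(.TRINUCLEOTIDES, .STOP_CODONS)]
  if (min(stopF) > max(otherF)) return("robust")
  # top-5 rule with conservative tie handling: a cell tied with others
  # takes the worst rank of its tie group, so ties never promote
  rk <- rank(-cnt, ties.method = "max")
  if (all(rk[.STOP_CODONS] <= 5L)) return("near_robust")
  "none"
})

#' Expected trinucleotide composition of cluster sequences
#'
#' Sliding-window (step 1) 3-mer frequencies over the sense strands of the
#' expressed cluster sequences; windows containing N are skipped, and
#' windows never cross record boundaries.
#'
#' @param seqs named DNAStringSet (or character vector) of expressed
#'   cluster sequences.
#' @return named numeric(64) of frequencies summing to 1.
#' @examples
#' expectedComposition(c(cl = "ATAA"))[c("ATA", "TAA")]  # 0.5, 0.5
#' @export
expectedComposition <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = 3L,
                                                         step = 1L))
  counts <- counts[.TRINUCLEOTIDES]
  tot <- sum(counts)
  if (tot == 0) stop("no countable 3-mer windows (all-N or too-short input)")
  counts / tot
}

#' Normalize observed 5' end composition by cluster composition
#'
#' Divides the observed 5' end trinucleotide distribution by the expected
#' distribution from the underlying cluster sequence, removing composition
#' artifacts (an AT-rich cluster inflates raw stop-codon frequencies even
#' under unbiased cleavage). The normalized stop-codon ratio is the mean
#' observed/expected ratio of the stop codons over the mean ratio of the
#' other Unn trinucleotides.
#'
#' @param observed an [EndCountTable-class] of 5' end counts.
#' @param expected named numeric(64) from [expectedComposition()].
#' @return list with `ratios` (named numeric(64) observed/expected, NA
#'   where the expected cell is 0 - flagged cells with observed counts are
#'   reported in `flaggedCells`), `normalizedStopRatio`, and
#'   `flaggedCells`.
#' @export
normalizeComposition <- function(observed, expected) {
  obs <- endFrequencies(observed)
  expected <- expected[.TRINUCLEOTIDES] / sum(expected, na.rm = TRUE)
  ratios <- rep(NA_real_, 64L)
  names(ratios) <- .TRINUCLEOTIDES
  ok <- expected > 0
  ratios[ok] <- obs[ok] / expected[ok]
  flagged <- .TRINUCLEOTIDES[!ok & obs > 0]
  stopR <- ratios[.STOP_CODONS]
  otherR <- ratios[.OTHER_UNN]
  nsr <- mean(stopR, na.rm = TRUE) / mean(otherR, na.rm = TRUE)
  list(ratios = ratios, normalizedStopRatio = nsr, flaggedCells = flagged)
}

#' Summarize one library
#'
#' Computes the 1U fraction, stop-codon ratio, robustness class and
#' (when cluster sequences are supplied) the composition-normalized stop
#' ratio for one library's end-count table.
#'
#' @param table an [EndCountTable-class] with `species`, `tissue`, `class`
#'   metadata (missing entries default to "unknown").
#' @param expected optional named numeric(64) from [expectedComposition()].
#' @param qc optional list of QC flags (see [libraryQc()]).
#' @return A [LibrarySummary-class].
#' @export
summarizeLibrary <- function(table, expected = NULL, qc = list()) {
  md <- table@metadata
  f <- endFrequencies(table)
  nsr <- NA_real_
  if (!is.null(expected))
    nsr <- normalizeComposition(table, expected)$normalizedStopRatio
  new("LibrarySummary",
      species = md$species %||% "unknown",
      tissue = md$tissue %||% "unknown",
      taxonGroup = md$class %||% "unknown",
      table = table,
      oneU = sum(f[.UNN]),
      stopRatio = stopCodonRatio(table)$ratio,
      normalizedStopRatio = nsr,
      robustness = classifyRobustness(table),
      qc = qc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equal-weight species group summary
#'
#' Averages trinucleotide frequency tables over libraries of the same
#' (species, tissue) pair, then treats each species as one equal-weight
#' point within its (class, tissue) group, so species with many libraries
#' do not dominate.
#'
#' @param summaries list of [LibrarySummary-class] objects.
#' @param normalized use normalized stop ratios where available
#'   (default FALSE).
#' @return list with `species` (data.frame: one row per species-tissue,
#'   with class, mean frequency-derived stop ratio, robustness of the
#'   averaged table) and `groups` (data.frame: one row per class-tissue,
#'   with `nSpecies`, `meanStopRatio`, `robustness` of the group-mean
#'   frequency vector).
#' @export
speciesGroupSummary <- function(summaries, normalized = FALSE) {
  spKey <- vapply(summaries, function(s) paste(s@species, s@tissue, sep = "|"),
                  character(1))
  spRows <- lapply(split(summaries, spKey), function(grp) {
    freqs <- vapply(grp, function(s) endFrequencies(s@table), numeric(64))
    meanF <- rowMeans(freqs)
    s1 <- grp[[1]]
    ratio <- if (normalized) {
      r <- vapply(grp, function(s) s@normalizedStopRatio, numeric(1))
      mean(r, na.rm = TRUE)
    } else stopCodonRatio(meanF)$ratio
    data.frame(species = s1@species, tissue = s1@tissue, class = s1@taxonGroup,
               nLibraries = length(grp), stopRatio = ratio,
               robustness = classifyRobustness(meanF),
               t(meanF), check.names = FALSE)
  })
  spDf <- do.call(rbind, spRows)
  rownames(spDf) <- NULL
  grpKey <- paste(spDf$class, spDf$tissue, sep = "|")
  grpRows <- lapply(split(seq_len(nrow(spDf)), grpKey), function(idx) {
    sub <- spDf[idx, , drop = FALSE]
    meanF <- colMeans(as.matrix(sub[, .TRINUCLEOTIDES, drop = FALSE]))
    data.frame(class = sub$class[1], tissue = sub$tissue[1],
               nSpecies = nrow(sub),
               meanStopRatio = mean(sub$stopRatio, na.rm = TRUE),
               robustness = classifyRobustness(meanF))
  })
  grpDf <- do.call(rbind, grpRows)
  rownames(grpDf) <- NULL
  list(species = spDf, groups = grpDf)
}

#' Fisher exact test of robust-enrichment counts between groups
#'
#' Two-sided Fisher exact test on the 2x2 table of robust libraries vs
#' totals in two groups (e.g. mammalian vs all other libraries).
#'
#' @param aSuccess,aTotal robust count and total in group A.
#' @param bSuccess,bTotal robust count and total in group B.
#' @return list with `p`, `oddsRatio`, and the 2x2 `table`.
#' @examples
#' groupEnrichmentFisher(22, 80, 1, 132)$p  # about 1e-9
#' @export
groupEnrichmentFisher <- function(aSuccess, aTotal, bSuccess, bTotal) {
  stopifnot(aSuccess <= aTotal, bSuccess <= bTotal, aTotal > 0, bTotal > 0)
  tab <- matrix(c(aSuccess, aTotal - aSuccess, bSuccess, bTotal - bSuccess),
                nrow = 2,
                dimnames = list(c("robust", "other"), c("A", "B")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p = ft$p.value, oddsRatio = unname(ft$estimate), table = tab)
}

#' Null probability of robust enrichment under a uniform ranking
#'
#' If all `nUnn` Unn trinucleotides were equally likely to occupy any rank,
#' the probability that the `nStop` stop codons all land in the top `nStop`
#' ranks is `1 / choose(nUnn, nStop)`: with 16 Unn trinucleotides and 3
#' stop codons, 1/560, i.e. about 0.18%.
#'
#' @param nUnn number of candidate trinucleotides (default 16).
#' @param nStop number of stop codons (default 3).
#' @return the probability (not a percentage).
#' @examples
#' nullRobustFraction()  # 0.0017857...
#' @export
nullRobustFraction <- function(nUnn = 16L, nStop = 3L) {
  stopifnot(nStop <= nUnn)
  1 / choose(nUnn, nStop)
}
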