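#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

# ---------------------------------------------------------------------------
# CompositionModel
# ---------------------------------------------------------------------------

#' Cluster sequence composition model
#'
#' Describes the base composition used to generate synthetic piRNA cluster
#' sequences: independent base probabilities with the C->G (CpG) transition
#' down-weighted by a depletion factor, mirroring the genome-wide CpG
#' depletion of non-coding regions. piRNA clusters are typically AT rich,
#' which the default probabilities reflect.
#'
#' @slot baseProbs named numeric(4), probabilities for A, C, G, T; sums to 1.
#' @slot cpgDepletion numeric in (0, 1]; multiplier applied to the C->G
#'   transition before renormalisation. 1 disables depletion.
#'
#' @seealso [generateCluster()]
#' @export
setClass("CompositionModel", representation(
  baseProbs = "numeric",
  cpgDepletion = "numeric"
))

setValidity("CompositionModel", function(object) {
  p <- object@baseProbs
  msg <- NULL
  if (length(p) != 4L || !setequal(names(p), .BASES))
    msg <- c(msg, "baseProbs must be named A, C, G, T")
  if (any(p < 0) || sum(p) <= 0)
    msg <- c(msg, "baseProbs must be non-negative with positive sum")
  if (abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "baseProbs must sum to 1")
  d <- object@cpgDepletion
  if (length(d) != 1L || d <= 0 || d > 1)
    msg <- c(msg, "cpgDepletion must be a single value in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CompositionModel
#'
#' @param baseProbs named numeric(4) of A/C/G/T probabilities. The default
#'   is AT rich (30/20/20/30), typical of pachytene piRNA clusters.
#' @param cpgDepletion CpG transition multiplier in (0, 1]; default 0.25
#'   gives the strong CpG depletion seen in non-coding mammalian sequence.
#' @return A [CompositionModel-class] object.
#' @examples
#' compositionModel()
#' compositionModel(baseProbs = c(A = .25, C = .25, G = .25, T = .25),
#'                  cpgDepletion = 1)
#' @export
compositionModel <- function(baseProbs = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
                             cpgDepletion = 0.25) {
  if (sum(baseProbs) > 0 && abs(sum(baseProbs) - 1) > 1e-8)
    baseProbs <- baseProbs / sum(baseProbs)
  new("CompositionModel", baseProbs = baseProbs[.BASES],
      cpgDepletion = cpgDepletion)
}

setMethod("show", "CompositionModel", function(object) {
  cat("CompositionModel\n")
  cat("  baseProbs:", paste(sprintf("%s=%.3f", .BASES, object@baseProbs),
                            collapse = " "), "\n")
  cat("  cpgDepletion:", object@cpgDepletion, "\n")
})

# ---------------------------------------------------------------------------
# CleavageModel
# ---------------------------------------------------------------------------

#' Phased-cleavage preference model
#'
#' Encodes the sequence preference of the Zucchini/PLD6 endonuclease used
#' by the phased-read simulator. Each candidate cut site is weighted by the
#' trinucleotide beginning at the cut's downstream side (the next 5' end),
#' multiplied by a penalty when the base immediately upstream (-1) is G and
#' by an upstream-GC bonus scaled by the GC fraction 10-20 nt upstream of
#' the cut.
#'
#' @slot weights named numeric(64), non-negative weight per trinucleotide.
#' @slot minus1G numeric > 0; multiplier applied when the -1 base is G.
#' @slot upstreamGC numeric > 0; per-unit-GC multiplier for the upstream
#'   window (weight is multiplied by `upstreamGC^gcFraction`).
#' @slot initiationRate numeric > 0; expected chain initiations per kb used
#'   when `nInitiations` is not given explicitly.
#'
#' @seealso [simulatePhasedReads()]
#' @export
setClass("CleavageModel", representation(
  weights = "numeric",
  minus1G = "numeric",
  upstreamGC = "numeric",
  initiationRate = "numeric"
))

setValidity("CleavageModel", function(object) {
  msg <- NULL
  w <- object@weights
  if (length(w) != 64L || !identical(names(w), .TRINUCLEOTIDES))
    msg <- c(msg, "weights must be named by the 64 trinucleotides in A<C<G<T order")
  if (any(w < 0) || !any(w > 0))
    msg <- c(msg, "weights must be non-negative with at least one positive entry")
  for (s in c("minus1G", "upstreamGC", "initiationRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste(s, "must be a single positive value"))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CleavageModel
#'
#' The default reproduces the qualitative in vivo preference: 1U-biased
#' cleavage with a further 4-fold preference for the three stop codons and
#' UAC, a strong -1G penalty, and a mild upstream-GC bonus.
#'
#' @param unnWeight weight for Unn trinucleotides other than the preferred
#'   four (default 1).
#' @param preferredWeight weight for UAA/UAG/UGA/UAC (default 4).
#' @param nonUWeight weight for trinucleotides not starting with U
#'   (default 0.05; a small leak keeps the 1U fraction below 1 as in real
#'   libraries).
#' @param minus1G penalty multiplier when the -1 base is G (default 0.25).
#' @param upstreamGC upstream-GC bonus base (default 1.5).
#' @param initiationRate chain initiations per kb (default 1).
#' @param weights optional explicit named numeric(64) overriding the
#'   construction above.
#' @return A [CleavageModel-class] object.
#' @examples
#' cleavageModel()
#' uniformUnnModel <- cleavageModel(preferredWeight = 1)
#' @export
cleavageModel <- function(unnWeight = 1, preferredWeight = 4,
                          nonUWeight = 0.05, minus1G = 0.25,
                          upstreamGC = 1.5, initiationRate = 1,
                          weights = NULL) {
  if (is.null(weights)) {
    weights <- rep(nonUWeight, 64L)
    names(weights) <- .TRINUCLEOTIDES
    weights[.UNN] <- unnWeight
    weights[c(.STOP_CODONS, "TAC")] <- preferredWeight
  } else {
    weights <- weights[.TRINUCLEOTIDES]
    names(weights) <- .TRINUCLEOTIDES
    weights[is.na(weights)] <- 0
  }
  new("CleavageModel", weights = weights, minus1G = minus1G,
      upstreamGC = upstreamGC, initiationRate = initiationRate)
}

setMethod("show", "CleavageModel", function(object) {
  w <- object@weights
  cat("CleavageModel\n")
  cat("  positive weights:", sum(w > 0), "of 64 trinucleotides\n")
  top <- sort(w[w > 0], decreasing = TRUE)
  top <- top[seq_len(min(6, length(top)))]
  cat("  top weights:", paste(sprintf("%s=%g", renderRNA(names(top)), top),
                              collapse = " "), "\n")
  cat("  minus1G:", object@minus1G, " upstreamGC:", object@upstreamGC,
      " initiationRate:", object@initiationRate, "/kb\n")
})

# ---------------------------------------------------------------------------
# EndCountTable
# ---------------------------------------------------------------------------

#' Trinucleotide counts at read ends
#'
#' Counts of the 64 trinucleotides observed at read 5' ends (or immediately
#' downstream of 3' ends). The backbone of the stop-codon enrichment
#' statistics: frequencies, the stop-codon ratio, robustness classes and
#' composition normalization all derive from this table.
#'
#' @slot counts named numeric(64) of non-negative counts, trinucleotides in
#'   A<C<G<T lexicographic order (DNA alphabet).
#' @slot metadata list of free-form annotation (library id, species,
#'   tissue, taxonomic class, length window, filter flags).
#'
#' @seealso [tabulateFivePrime()], [stopCodonRatio()], [classifyRobustness()]
#' @export
setClass("EndCountTable", representation(
  counts = "numeric",
  metadata = "list"
))

setValidity("EndCountTable", function(object) {
  msg <- NULL
  if (length(object@counts) != 64L ||
      !identical(names(object@counts), .TRINUCLEOTIDES))
    msg <- c(msg, "counts must be named by the 64 trinucleotides in A<C<G<T order")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    msg <- c(msg, "counts must be finite and non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EndCountTable
#'
#' @param counts numeric counts named by DNA trinucleotides; missing cells
#'   are filled with 0. RNA-alphabet names (U) are accepted.
#' @param metadata list of annotation.
#' @return An [EndCountTable-class].
#' @examples
#' tab <- EndCountTable(c(TAA = 10, TAG = 8, TGA = 6, TTT = 4))
#' totalCount(tab)
#' @export
EndCountTable <- function(counts = numeric(0), metadata = list()) {
  if (!is.null(names(counts))) names(counts) <- chartr("U", "T", names(counts))
  full <- stats::setNames(numeric(64L), .TRINUCLEOTIDES)
  if (length(counts)) {
    bad <- setdiff(names(counts), .TRINUCLEOTIDES)
    if (length(bad))
      stop("unknown trinucleotide name(s): ", paste(bad, collapse = ", "))
    full[names(counts)] <- unname(counts)
  }
  new("EndCountTable", counts = full, metadata = metadata)
}

setMethod("show", "EndCountTable", function(object) {
  tot <- sum(object@counts)
  cat("EndCountTable with", tot, "reads\n")
  if (tot > 0) {
    f <- sort(object@counts / tot, decreasing = TRUE)[1:5]
    cat("  top 5' trinucleotides:",
        paste(sprintf("%s=%.3f", renderRNA(names(f)), f), collapse = " "), "\n")
  }
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# ScoredPositions
# ---------------------------------------------------------------------------

#' Positions scored for 5' end definition
#'
#' Per-position results of the windowed 5' end definition score: for each
#' transcript-strand position x, `f` (the number of read 5' ends exactly at
#' x), `localTotal` (the sum of f over the window 10 nt upstream to 20 nt
#' downstream, transcript oriented), the score `score = f / localTotal`,
#' and the coverage gate `covered = localTotal >= minLocalReads`. After
#' [binPositions()] a `bin` column holds the 0..nBins bin index (bin 0 is
#' score exactly 0; NA for uncovered positions).
#'
#' @slot positions [GenomicRanges::GRanges] of width-1 positions carrying
#'   metadata columns `region`, `f`, `localTotal`, `score`, `covered`,
#'   `truncated`, and optionally `bin`.
#' @slot config list of scoring parameters (upstream, downstream,
#'   minLocalReads, nBins).
#' @slot end character; `"five_prime"` or `"downstream_of_three_prime"`.
#'
#' @seealso [computeScores()], [binPositions()]
#' @export
setClass("ScoredPositions", representation(
  positions = "GRanges",
  config = "list",
  end = "character"
))

setValidity("ScoredPositions", function(object) {
  mc <- names(S4Vectors::mcols(object@positions))
  need <- c("region", "f", "localTotal", "score", "covered", "truncated")
  if (!all(need %in% mc))
    return(paste("positions must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (!object@end %in% c("five_prime", "downstream_of_three_prime"))
    return("end must be 'five_prime' or 'downstream_of_three_prime'")
  TRUE
})

setMethod("show", "ScoredPositions", function(object) {
  gr <- object@positions
  n <- length(gr)
  cov <- sum(gr$covered)
  cat("ScoredPositions (", object@end, ") with ", n, " positions\n", sep = "")
  cat("  covered (localTotal >= ", object@config$minLocalReads, "): ",
      cov, "\n", sep = "")
  if (cov > 0)
    cat("  mean score over covered positions:",
        signif(mean(gr$score[gr$covered]), 4), "\n")
  if (!is.null(gr$bin))
    cat("  binned into", length(unique(stats::na.omit(gr$bin))), "bins\n")
})

#' @describeIn ScoredPositions-class the underlying GRanges of scored
#'   positions.
#' @param x a `ScoredPositions` object.
#' @param use.names,use.mcols ignored (present for generic compatibility).
#' @param ... ignored.
#' @export
setMethod("granges", "ScoredPositions",
          function(x, use.names = TRUE, use.mcols = FALSE, ...) x@positions)

setMethod("length", "ScoredPositions", function(x) length(x@positions))

# ---------------------------------------------------------------------------
# LibrarySummary
# ---------------------------------------------------------------------------

#' Per-library stop-codon enrichment summary
#'
#' One small-RNA library's 5' end composition statistics: the 64-cell
#' trinucleotide table, the 1U fraction, the raw (and optionally
#' composition-normalized) stop-codon ratio, and the robustness class
#' (`robust` when every stop codon is more frequent than any non-stop
#' trinucleotide, `near_robust` when all three rank in the top five,
#' `none` otherwise).
#'
#' @slot species character species label.
#' @slot tissue character, e.g. "testis" or "ovary".
#' @slot taxonGroup character taxonomic group label.
#' @slot table [EndCountTable-class] of 5' trinucleotide counts.
#' @slot oneU numeric 1U fraction.
#' @slot stopRatio numeric raw stop-codon ratio.
#' @slot normalizedStopRatio numeric or NA; ratio after composition
#'   normalization.
#' @slot robustness character, one of "robust", "near_robust", "none".
#' @slot qc list of QC flags.
#'
#' @seealso [summarizeLibrary()], [classifyRobustness()]
#' @export
setClass("LibrarySummary", representation(
  species = "character",
  tissue = "character",
  taxonGroup = "character",
  table = "EndCountTable",
  oneU = "numeric",
  stopRatio = "numeric",
  normalizedStopRatio = "numeric",
  robustness = "character",
  qc = "list"
))

setValidity("LibrarySummary", function(object) {
  if (!object@robustness %in% c("robust", "near_robust", "none"))
    return("robustness must be 'robust', 'near_robust' or 'none'")
  TRUE
})

setMethod("show", "LibrarySummary", function(object) {
  cat("LibrarySummary:", object@species, "/", object@tissue,
      "(", object@taxonGroup, ")\n")
  cat("  1U fraction:", signif(object@oneU, 3),
      " stop ratio:", signif(object@stopRatio, 3))
  if (!is.na(object@normalizedStopRatio))
    cat(" (normalized:", signif(object@normalizedStopRatio, 3), ")")
  cat("\n  robustness:", object@robustness, "\n")
})
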