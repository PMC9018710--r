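# Seeded generator of Zuc-style phased piRNA biogenesis: cluster sequences
# with tunable composition, tail-to-head pre-piRNA chains driven by a known
# trinucleotide cleavage-weight vector, per-base tracks, and multi-library
# trinucleotide count tables. Because the injected preferences are known,
# every downstream statistic can be checked for parameter recovery.

# Fragment length window: successive cuts land 20-50 nt apart. Pre-piRNAs
# run up to ~50 nt; the lower bound prevents degenerate fragments.
.FRAG_MIN <- 20L
.FRAG_MAX <- 50L
# Mature lengths after 3'->5' trimming; the 5' end is never touched.
.TRIM_LEN <- c(26L, 27L)
# Upstream window used for the GC bonus: 10-20 nt upstream of the cut.
.GC_FROM <- 20L
.GC_TO <- 10L

#' Generate a synthetic piRNA cluster sequence
#'
#' Samples a sequence base by base from a first-order chain: each base is
#' drawn from the model's base probabilities, except that following a C the
#' probability of G is multiplied by the CpG depletion factor and the four
#' probabilities renormalised. The stationary CpG frequency implied by this
#' construction is available from [expectedCpGFrequency()].
#'
#' @param length sequence length in nt (at least 100).
#' @param model a [CompositionModel-class]; default [compositionModel()].
#' @param seed integer seed; identical seed and parameters give an
#'   identical sequence.
#' @param name sequence identifier (default "cluster1").
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @examples
#' cl <- generateCluster(500, seed = 1)
#' Biostrings::width(cl)
#' @export
generateCluster <- function(length, model = compositionModel(), seed = NULL,
                            name = "cluster1") {
  stopifnot(length >= 100)
  p <- model@baseProbs
  if (all(p == 0)) stop("degenerate composition model: all-zero probabilities")
  pc <- p  # transition probabilities out of C
  pc["G"] <- pc["G"] * model@cpgDepletion
  pc <- pc / sum(pc)
  cdfP <- cumsum(p / sum(p))
  cdfC <- cumsum(pc)
  bases <- .withSeed(seed, {
    u <- stats::runif(length)
    out <- integer(length)
    # 1 = A, 2 = C, 3 = G, 4 = T; inverse-CDF draw, transition depends only
    # on whether the previous base is C
    out[1] <- sum(u[1] > cdfP) + 1L
    for (i in 2:length) {
      cdf <- if (out[i - 1L] == 2L) cdfC else cdfP
      out[i] <- sum(u[i] > cdf) + 1L
    }
    out
  })
  seq <- paste(.BASES[bases], collapse = "")
  out <- Biostrings::DNAStringSet(stats::setNames(seq, name))
  out
}

#' Expected CpG frequency under a composition model
#'
#' Closed form for the stationary CpG dinucleotide frequency of the chain
#' used by [generateCluster()]: the stationary probability of C times the
#' depleted, renormalised C->G transition probability.
#'
#' @param model a [CompositionModel-class].
#' @return expected frequency of the CG dinucleotide.
#' @export
expectedCpGFrequency <- function(model = compositionModel()) {
  p <- model@baseProbs
  pc <- p
  pc["G"] <- pc["G"] * model@cpgDepletion
  pc <- pc / sum(pc)
  # stationary P(C): c = P(C | prev != C) (1 - c) + P(C | prev C) c
  cNonC <- p[["C"]]
  cC <- pc[["C"]]
  statC <- cNonC / (1 - cC + cNonC)
  unname(statC * pc[["G"]])
}

# Per-position cut weights for a cluster sequence under a cleavage model.
# Position x (1-based) is a candidate next 5' end; its weight is
# w(3-mer at x) * minus1G penalty if base x-1 is G
#              * upstreamGC ^ (GC fraction of x-20 .. x-10).
# Positions too close to either boundary get weight 0.
.positionWeights <- function(chrseq, model) {
  n <- nchar(chrseq)
  w <- numeric(n)
  if (n < .GC_FROM + 3L) return(w)
  pos <- (.GC_FROM + 1L):(n - 2L)
  tri <- substring(chrseq, pos, pos + 2L)
  w3 <- model@weights[tri]
  w3[is.na(w3)] <- 0  # windows containing N
  prev <- substring(chrseq, pos - 1L, pos - 1L)
  pen <- ifelse(prev == "G", model@minus1G, 1)
  isGC <- as.integer(strsplit(chrseq, "")[[1]] %in% c("G", "C"))
  cs <- c(0L, cumsum(isGC))
  gcFrac <- (cs[pos - .GC_TO + 1L] - cs[pos - .GC_FROM]) / (.GC_FROM - .GC_TO + 1L)
  w[pos] <- w3 * pen * model@upstreamGC^gcFrac
  w
}

#' Simulate phased (tail-to-head) pre-piRNA reads
#'
#' From each initiation site a chain of successive cuts is generated:
#' candidate cut positions 20-50 nt downstream of the current 5' end are
#' sampled with probability proportional to the cleavage model's weight at
#' the candidate (trinucleotide weight x -1G penalty x upstream-GC bonus),
#' and the fragment between the current 5' end and the cut is emitted. The
#' cut becomes the next fragment's 5' end, so consecutive fragments of a
#' chain are exactly tail-to-head. In `"trimmed"` mode each fragment is
#' shortened from its 3' end to 26-27 nt (the 5' end is never modified),
#' which destroys the tail-to-head adjacency as 3'->5' trimming does in
#' vivo; `"untrimmed"` leaves the raw 20-50 nt fragments.
#'
#' @param cluster named DNAStringSet of length 1 (see [generateCluster()]).
#' @param model a [CleavageModel-class].
#' @param nInitiations number of chains; default derives from the model's
#'   initiation rate and the cluster length.
#' @param trimming `"trimmed"` or `"untrimmed"`.
#' @param seed integer seed.
#' @return A list with components
#'   \describe{
#'     \item{reads}{GRanges of fragments (plus strand, `count` aggregated
#'       over identical coordinates).}
#'     \item{fragments}{data.frame of raw per-chain fragments (`chain`,
#'       `start`, `end`, 1-based closed) before aggregation, in emission
#'       order; consecutive rows of one chain satisfy
#'       `start[i + 1] == end[i] + 1` in untrimmed mode.}
#'     \item{truth}{list recording the model, seed, trimming mode, and the
#'       per-position relative cut weight (`cutWeights`) used, for
#'       parameter-recovery tests.}
#'   }
#' @examples
#' cl <- generateCluster(2000, seed = 1)
#' sim <- simulatePhasedReads(cl, cleavageModel(), nInitiations = 20,
#'                            trimming = "untrimmed", seed = 2)
#' length(sim$reads)
#' @export
simulatePhasedReads <- function(cluster, model = cleavageModel(),
                                nInitiations = NULL,
                                trimming = c("trimmed", "untrimmed"),
                                seed = NULL) {
  trimming <- match.arg(trimming)
  stopifnot(length(cluster) == 1L)
  chrseq <- .seqsAsChar(cluster)[[1]]
  contig <- names(cluster)
  n <- nchar(chrseq)
  if (n <= .FRAG_MAX + .GC_FROM + 3L)
    stop("cluster shorter than the maximum fragment length plus margins")
  if (is.null(nInitiations))
    nInitiations <- max(1L, round(model@initiationRate * n / 1000))
  w <- .positionWeights(chrseq, model)
  terminated <- 0L
  frags <- .withSeed(seed, {
    # initiation 5' ends are themselves upstream cleavage products, so they
    # follow the same positional weights as every later cut
    startRange <- (.GC_FROM + 1L):(n - .FRAG_MAX - 3L)
    startW <- w[startRange]
    if (!any(startW > 0)) stop("no positive-weight initiation site")
    starts <- startRange[sample.int(length(startRange), nInitiations,
                                    replace = TRUE, prob = startW)]
    res <- vector("list", nInitiations)
    for (ch in seq_len(nInitiations)) {
      p <- starts[ch]
      fs <- integer(0); fe <- integer(0)
      repeat {
        lo <- p + .FRAG_MIN
        hi <- min(p + .FRAG_MAX, n - 2L)
        if (lo > hi) break
        cand <- lo:hi
        cw <- w[cand]
        if (!any(cw > 0)) { terminated <<- terminated + 1L; break }
        cut <- cand[sample.int(length(cand), 1L, prob = cw)]
        fs <- c(fs, p); fe <- c(fe, cut - 1L)
        p <- cut
      }
      res[[ch]] <- if (length(fs))
        data.frame(chain = ch, start = fs, end = fe) else NULL
    }
    frags <- do.call(rbind, res)
    if (trimming == "trimmed" && !is.null(frags)) {
      tl <- sample(.TRIM_LEN, nrow(frags), replace = TRUE)
      frags$end <- pmin(frags$end, frags$start + tl - 1L)
    }
    frags
  })
  if (terminated > 0L)
    message(terminated, " chain(s) terminated with no positive-weight candidate")
  if (is.null(frags))
    frags <- data.frame(chain = integer(0), start = integer(0), end = integer(0))
  reads <- if (nrow(frags)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(frags))),
                            by = list(start = frags$start, end = frags$end),
                            FUN = sum)
    GenomicRanges::GRanges(contig, IRanges::IRanges(agg$start, agg$end),
                           strand = "+",
                           name = paste0("sim", seq_len(nrow(agg))),
                           count = agg$count)
  } else {
    GenomicRanges::GRanges(seqnames = character(0),
                           ranges = IRanges::IRanges(),
                           strand = character(0),
                           name = character(0), count = integer(0))
  }
  truth <- list(model = model, seed = seed, trimming = trimming,
                cutWeights = w / sum(w), nInitiations = nInitiations)
  list(reads = reads, fragments = frags, truth = truth)
}

#' Simulate a per-base score track
#'
#' Fixture generator for the conservation module: a constant track
#' (`"flat"`), i.i.d. normal noise (`"noisy"`), or noise with a stated
#' offset added at chosen positions (`"bin-correlated"`).
#'
#' @param cluster named DNAStringSet of length 1, or an integer length with
#'   `contig` naming the chromosome.
#' @param mode `"flat"`, `"noisy"`, or `"bin-correlated"`.
#' @param value constant value for flat mode (default 0.5) and mean for
#'   the noise modes (default 0).
#' @param sd standard deviation of the noise (default 1).
#' @param offset value added at `offsetPositions` in bin-correlated mode
#'   (default 0.5).
#' @param offsetPositions 1-based positions receiving the offset.
#' @param seed integer seed.
#' @param contig contig name when `cluster` is a bare length.
#' @return GRanges of width-1 positions with a `value` column, one per base.
#' @export
simulateTrack <- function(cluster, mode = c("flat", "noisy", "bin-correlated"),
                          value = if (match.arg(mode) == "flat") 0.5 else 0,
                          sd = 1, offset = 0.5, offsetPositions = integer(0),
                          seed = NULL, contig = "cluster1") {
  mode <- match.arg(mode)
  if (methods::is(cluster, "DNAStringSet")) {
    n <- Biostrings::width(cluster)[1]
    contig <- names(cluster)[1]
  } else n <- as.integer(cluster)
  vals <- switch(mode,
    flat = rep(value, n),
    noisy = .withSeed(seed, stats::rnorm(n, value, sd)),
    `bin-correlated` = {
      v <- .withSeed(seed, stats::rnorm(n, value, sd))
      v[offsetPositions] <- v[offsetPositions] + offset
      v
    })
  GenomicRanges::GRanges(contig, IRanges::IRanges(seq_len(n), width = 1L),
                         value = vals)
}

#' Simulate multi-species library count tables
#'
#' Each library is a multinomial draw of `depth` reads over the 64
#' trinucleotides from a base distribution whose three stop-codon cells are
#' multiplied by `effect` and renormalised; a fixture for the cross-species
#' enrichment analysis. The default base distribution is uniform over the
#' 64 trinucleotides, so the expected stop-codon ratio equals `effect`
#' exactly; pass a composition-derived `baseFreq` (e.g. from
#' [expectedComposition()]) to emulate composition-confounded libraries.
#'
#' @param nSpecies number of species.
#' @param librariesPerSpecies libraries per species.
#' @param effect stop-codon odds multiplier (1 = null).
#' @param depth reads per library (at least 1000).
#' @param seed integer seed.
#' @param baseFreq optional named numeric(64) base distribution.
#' @param tissue tissue label recycled over species (default "testis").
#' @param class taxonomic class label recycled over species.
#' @return list of [EndCountTable-class] objects with `species`, `tissue`,
#'   `class` and `effect` metadata.
#' @export
simulateLibraryTables <- function(nSpecies, librariesPerSpecies, effect = 1,
                                  depth = 1e5, seed = NULL, baseFreq = NULL,
                                  tissue = "testis", class = "groupA") {
  stopifnot(depth >= 1000)
  if (is.null(baseFreq))
    baseFreq <- stats::setNames(rep(1 / 64, 64L), .TRINUCLEOTIDES)
  baseFreq <- baseFreq[.TRINUCLEOTIDES] / sum(baseFreq)
  prob <- baseFreq
  prob[.STOP_CODONS] <- prob[.STOP_CODONS] * effect
  prob <- prob / sum(prob)
  tissue <- rep_len(tissue, nSpecies)
  class <- rep_len(class, nSpecies)
  .withSeed(seed, {
    out <- list()
    for (s in seq_len(nSpecies)) {
      for (l in seq_len(librariesPerSpecies)) {
        cnt <- as.vector(stats::rmultinom(1L, size = depth, prob = prob))
        names(cnt) <- .TRINUCLEOTIDES
        out[[length(out) + 1L]] <- EndCountTable(cnt, metadata = list(
          library = sprintf("sp%02d_lib%02d", s, l),
          species = sprintf("sp%02d", s), tissue = tissue[s],
          class = class[s], effect = effect))
      }
    }
    out
  })
}
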