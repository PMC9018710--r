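#' @rdname endCounts
#' @export
setGeneric("endCounts", function(x) standardGeneric("endCounts"))

#' @rdname endCounts
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname endCounts
#' @export
setGeneric("endFrequencies", function(x, normalize = c("all", "Unn"))
  standardGeneric("endFrequencies"))

#' @rdname stopCodonRatio
#' @export
setGeneric("stopCodonRatio", function(x, ...) standardGeneric("stopCodonRatio"))

#' @rdname classifyRobustness
#' @export
setGeneric("classifyRobustness", function(x) standardGeneric("classifyRobustness"))

#' @rdname coveredPositions
#' @export
setGeneric("coveredPositions", function(x) standardGeneric("coveredPositions"))

#' @rdname coveredPositions
#' @export
setGeneric("scoreConfig", function(x) standardGeneric("scoreConfig"))

# --- accessors -------------------------------------------------------------

#' Access an EndCountTable
#'
#' `endCounts` returns the named 64-cell count vector (DNA alphabet),
#' `totalCount` its sum, and `endFrequencies` the cell frequencies,
#' normalized either over all 64 trinucleotides or within the 16 Unn
#' trinucleotides only (both conventions appear in 5' end composition
#' reports; the stop-codon ratio is identical under either).
#'
#' @param x an [EndCountTable-class].
#' @param normalize `"all"` (default) or `"Unn"`.
#' @return `endCounts`/`endFrequencies`: named numeric(64) (frequencies are
#'   NA-free; an empty table gives all-zero frequencies). `totalCount`: a
#'   single number.
#' @examples
#' tab <- EndCountTable(c(TAA = 6, TTT = 2))
#' endCounts(tab)[c("TAA", "TTT")]
#' endFrequencies(tab, "Unn")[c("TAA", "TTT")]
#' @rdname endCounts
#' @export
setMethod("endCounts", "EndCountTable", function(x) x@counts)

#' @rdname endCounts
#' @export
setMethod("totalCount", "EndCountTable", function(x) sum(x@counts))

#' @rdname endCounts
#' @export
setMethod("endFrequencies", "EndCountTable", function(x, normalize = c("all", "Unn")) {
  normalize <- match.arg(normalize)
  cnt <- x@counts
  denom <- if (normalize == "all") sum(cnt) else sum(cnt[.UNN])
  if (denom == 0) return(cnt * 0)
  cnt / denom
})

#' Covered positions and scoring configuration
#'
#' `coveredPositions` returns the subset of scored positions passing the
#' local-coverage gate (localTotal at or above `minLocalReads`) as a
#' GRanges; `scoreConfig` returns the scoring parameter list.
#'
#' @param x a [ScoredPositions-class] object.
#' @return A GRanges, or a list of parameters.
#' @rdname coveredPositions
#' @export
setMethod("coveredPositions", "ScoredPositions", function(x) {
  x@positions[x@positions$covered]
})

#' @rdname coveredPositions
#' @export
setMethod("scoreConfig", "ScoredPositions", function(x) x@config)
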