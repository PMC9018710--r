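# Internal constants and helpers shared across modules.

# Lexicographic (A<C<G<T) 3-mer order; matches Biostrings::oligonucleotideFrequency.
.BASES <- c("A", "C", "G", "T")

.TRINUCLEOTIDES <- as.vector(t(outer(
  as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0)))

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.UNN <- .TRINUCLEOTIDES[startsWith(.TRINUCLEOTIDES, "T")]

.OTHER_UNN <- setdiff(.UNN, .STOP_CODONS)

#' Render a DNA label in RNA alphabet
#'
#' The package works internally in the DNA alphabet; user-facing tables
#' render T as U (stop codons appear as UAA/UAG/UGA). This is the single
#' conversion point.
#'
#' @param x character vector of DNA labels.
#' @return `x` with every T replaced by U.
#' @examples
#' renderRNA(c("TAA", "TTG"))
#' @export
renderRNA <- function(x) chartr("T", "U", x)

# Evaluate expr under a fixed RNG state without touching the caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stage-specific seed from a global one (keeps values < 2^31).
.deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Reverse complement of a character vector of DNA strings (vectorised).
.revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Complement single bases.
.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.checkStrand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand value(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  strand
}

# Open a path with gzip transparency.
.openInput <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}
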