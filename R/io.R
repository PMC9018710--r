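# Reading and writing the plain-text formats the pipeline touches, and the
# shared coordinate conventions. Files are BED-style 0-based half-open on
# disk; in memory everything is a GRanges (1-based, closed), so the 5'-most
# base of a minus-strand read is end(gr) and of a plus-strand read start(gr).
# FASTA goes through Biostrings. All readers are gzip transparent.

#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   reverseComplement oligonucleotideFrequency
#' @importFrom utils read.delim write.table
NULL

.parseBedLines <- function(path, minCols) {
  lines <- readLines(.openInput(path))
  keep <- !grepl("^\\s*$", lines) & !grepl("^(#|track|browser)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  list(fields = fields, lineNumbers = idx)
}

.badLine <- function(path, lineno, why) {
  stop(sprintf("%s: malformed line %d (%s)", basename(path), lineno, why),
       call. = FALSE)
}

.readBed <- function(path, format = c("auto", "bed6", "bed6count"),
                     lengthRange = NULL) {
  format <- match.arg(format)
  p <- .parseBedLines(path)
  n <- length(p$fields)
  if (n == 0L) {
    return(GenomicRanges::GRanges(
      seqnames = character(0), ranges = IRanges::IRanges(),
      strand = character(0), name = character(0), count = integer(0)))
  }
  ncols <- lengths(p$fields)
  expected <- switch(format, bed6 = 6L, bed6count = 7L, auto = NA_integer_)
  for (i in seq_len(n)) {
    nc <- ncols[i]
    ok <- if (is.na(expected)) nc %in% c(6L, 7L) else nc == expected
    if (!ok)
      .badLine(path, p$lineNumbers[i],
               sprintf("expected %s columns, found %d",
                       if (is.na(expected)) "6 or 7" else expected, nc))
  }
  mat <- t(vapply(p$fields, function(f) f[1:6], character(6)))
  start0 <- suppressWarnings(as.integer(mat[, 2]))
  end0 <- suppressWarnings(as.integer(mat[, 3]))
  strand <- mat[, 6]
  for (i in seq_len(n)) {
    if (is.na(start0[i]) || is.na(end0[i]))
      .badLine(path, p$lineNumbers[i], "non-integer coordinates")
    if (start0[i] >= end0[i])
      .badLine(path, p$lineNumbers[i], "start must be < end")
    if (!strand[i] %in% c("+", "-"))
      .badLine(path, p$lineNumbers[i],
               sprintf("unknown strand '%s'", strand[i]))
  }
  count <- rep(1L, n)
  has7 <- ncols == 7L
  if (any(has7)) {
    cnt <- suppressWarnings(as.integer(vapply(
      p$fields[has7], `[`, character(1), 7L)))
    bad <- which(is.na(cnt) | cnt < 1L)
    if (length(bad))
      .badLine(path, p$lineNumbers[has7][bad[1]],
               "count column must be a positive integer")
    count[has7] <- cnt
  }
  if (!is.null(lengthRange)) {
    len <- end0 - start0
    bad <- which(len < lengthRange[1] | len > lengthRange[2])
    if (length(bad))
      .badLine(path, p$lineNumbers[bad[1]],
               sprintf("read length %d outside %d-%d nt",
                       len[bad[1]], lengthRange[1], lengthRange[2]))
  }
  GenomicRanges::GRanges(
    seqnames = mat[, 1],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand, name = mat[, 4], count = count)
}

#' Read aligned small-RNA reads from BED
#'
#' Parses BED6 or the BED6+count dialect (a seventh column holding a
#' positive integer read multiplicity; absent means 1). Coordinates on disk
#' are 0-based half-open; the returned GRanges is 1-based closed with
#' metadata columns `name` and `count`. Malformed lines raise an error
#' naming the offending line number; `.gz` inputs are decompressed
#' transparently.
#'
#' @param path BED file (optionally gzipped).
#' @param format `"auto"` (default; 6 or 7 columns per line), `"bed6"` or
#'   `"bed6count"`.
#' @param lengthRange length-2 integer vector of admissible read lengths in
#'   nt (default 15-70, the plausible small-RNA range); reads outside it
#'   are treated as malformed. Use `NULL` to disable.
#' @return GRanges of reads with `name` and `count` metadata columns.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t128\tr1\t0\t+", bed)
#' readReadBed(bed)
#' @seealso [writeReadBed()], [readIntervalBed()]
#' @export
readReadBed <- function(path, format = c("auto", "bed6", "bed6count"),
                        lengthRange = c(15L, 70L)) {
  .readBed(path, format, lengthRange = lengthRange)
}

#' Read genomic intervals from BED6
#'
#' Same parser as [readReadBed()] but without the read-length constraint;
#' used for cluster/transcript regions of arbitrary size.
#'
#' @inheritParams readReadBed
#' @return GRanges with `name` and `count` metadata columns.
#' @export
readIntervalBed <- function(path, format = c("auto", "bed6", "bed6count")) {
  .readBed(path, format, lengthRange = NULL)
}

#' Write reads to BED6+count
#'
#' Inverse of [readReadBed()]: writes 0-based half-open coordinates with
#' the count multiplicity in column 7. Reading the file back yields
#' identical records.
#'
#' @param reads GRanges with optional `name` and `count` metadata columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReadBed <- function(reads, path) {
  n <- length(reads)
  name <- reads$name
  if (is.null(name)) name <- paste0("r", seq_len(n))
  count <- reads$count
  if (is.null(count)) count <- rep(1L, n)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(reads)),
    start = GenomicRanges::start(reads) - 1L,
    end = GenomicRanges::end(reads),
    name = name, score = 0L,
    strand = as.character(GenomicRanges::strand(reads)),
    count = count)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write sequence sets
#'
#' Thin wrappers over Biostrings FASTA I/O that enforce the package's
#' conventions: unique identifiers (first whitespace token of the header)
#' and non-empty DNA sequences.
#'
#' @param path FASTA file (optionally gzipped).
#' @return `readSequences`: a named [Biostrings::DNAStringSet].
#' @export
readSequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers in ", basename(path))
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence(s) in ", basename(path))
  seqs
}

#' @rdname readSequences
#' @param seqs a named DNAStringSet (or named character vector).
#' @export
writeSequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a per-base score track
#'
#' Accepts either the package's 3-column per-base dialect (contig, 0-based
#' position, value) or 4-column bedGraph (contig, start, end, value; the
#' interval is expanded to one value per base). One value per (contig,
#' position) is enforced.
#'
#' @param path track file (optionally gzipped).
#' @return GRanges of width-1 positions with a `value` metadata column.
#' @seealso [writeTrack()], [joinTrack()]
#' @export
readTrack <- function(path) {
  p <- .parseBedLines(path)
  n <- length(p$fields)
  if (n == 0L)
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  value = numeric(0)))
  ncols <- lengths(p$fields)
  if (!all(ncols %in% c(3L, 4L)))
    .badLine(path, p$lineNumbers[which(!ncols %in% c(3L, 4L))[1]],
             "expected 3 (per-base) or 4 (bedGraph) columns")
  contig <- pos <- character(0); val <- numeric(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- p$fields[[i]]
    if (ncols[i] == 3L) {
      s <- suppressWarnings(as.integer(f[2]))
      if (is.na(s)) .badLine(path, p$lineNumbers[i], "non-integer position")
      out[[i]] <- data.frame(contig = f[1], pos = s + 1L,
                             value = as.numeric(f[3]))
    } else {
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e) || s >= e)
        .badLine(path, p$lineNumbers[i], "bad bedGraph interval")
      out[[i]] <- data.frame(contig = f[1], pos = (s + 1L):e,
                             value = as.numeric(f[4]))
    }
  }
  df <- do.call(rbind, out)
  if (anyDuplicated(df[c("contig", "pos")]))
    stop(basename(path), ": more than one value for some (contig, position)")
  GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$pos, width = 1L),
                         value = df$value)
}

#' Write a per-base score track
#'
#' Writes the 3-column per-base dialect (contig, 0-based position, value)
#' that [readTrack()] reads back identically.
#'
#' @param track GRanges of width-1 positions with a `value` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path) {
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(track)),
    pos = GenomicRanges::start(track) - 1L,
    value = track$value)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write trinucleotide count tables
#'
#' Tab-separated 64-row tables with a `trinucleotide` / `count` header and
#' optional `#key value` metadata comment lines; the on-disk exchange
#' format for [EndCountTable-class] objects (trinucleotides rendered in the
#' RNA alphabet).
#'
#' @param path TSV file (optionally gzipped).
#' @return `readCountTable`: an [EndCountTable-class].
#' @export
readCountTable <- function(path) {
  lines <- readLines(.openInput(path))
  metaLines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in metaLines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\t")[[1]]
    if (length(kv) == 2L) metadata[[kv[1]]] <- kv[2]
  }
  df <- read.delim(text = lines[!grepl("^#", lines)],
                   header = TRUE, sep = "\t")
  counts <- stats::setNames(df$count, df$trinucleotide)
  EndCountTable(counts, metadata = metadata)
}

#' @rdname readCountTable
#' @param table an [EndCountTable-class].
#' @export
writeCountTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- table@metadata
  for (k in names(md))
    writeLines(sprintf("#%s\t%s", k, as.character(md[[k]])), con)
  df <- data.frame(trinucleotide = renderRNA(names(endCounts(table))),
                   count = unname(endCounts(table)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- strand-aware sequence context -----------------------------------------

# Character cache so repeated extraction does not re-decode the XStringSet.
.seqsAsChar <- function(seqs) {
  if (is.character(seqs)) return(seqs)
  stats::setNames(as.character(seqs), names(seqs))
}

# k-mer read 5'->3' along the transcript whose first base sits at genomic
# position pos (1-based) on the given strand. NA outside bounds or over N.
.kmerAt <- function(chrseq, pos, strand, k) {
  n <- nchar(chrseq)
  out <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  okP <- plus & pos >= 1L & (pos + k - 1L) <= n
  if (any(okP)) out[okP] <- substring(chrseq, pos[okP], pos[okP] + k - 1L)
  okM <- !plus & (pos - k + 1L) >= 1L & pos <= n
  if (any(okM))
    out[okM] <- .revcomp(substring(chrseq, pos[okM] - k + 1L, pos[okM]))
  out[!is.na(out) & grepl("N", out)] <- NA_character_
  out
}

# Apply .kmerAt across contigs for a GRanges of width-1 anchor positions.
.kmerAtGRanges <- function(pos, strandv, contig, seqs, k) {
  chars <- .seqsAsChar(seqs)
  missing <- setdiff(unique(contig), names(chars))
  if (length(missing))
    stop("contig(s) missing from sequence set: ",
         paste(missing, collapse = ", "))
  out <- rep(NA_character_, length(pos))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    out[i] <- .kmerAt(chars[[ct]], pos[i], strandv[i], k)
  }
  out
}

#' Trinucleotide at read 5' ends
#'
#' Returns the trinucleotide whose first base is the read's 5'-most base,
#' read 5'->3' along the read: on the plus strand the 3 bases starting at
#' the read start, on the minus strand the reverse complement of the 3
#' bases ending at the read end. NA where the window leaves the sequence or
#' contains N (such reads are excluded from the statistic at hand only).
#'
#' @param reads GRanges of reads.
#' @param seqs named DNAStringSet (or character vector) of the sequences
#'   the reads map to; a missing contig is an error.
#' @return character vector (DNA alphabet; use [renderRNA()] to display),
#'   NA where unavailable.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chr = "CCTAAGG"))
#' rd <- GenomicRanges::GRanges("chr", IRanges::IRanges(3, 7), strand = "+")
#' fivePrimeTrinucleotide(rd, seqs)  # "TAA"
#' @export
fivePrimeTrinucleotide <- function(reads, seqs) {
  strandv <- as.character(GenomicRanges::strand(reads))
  .checkStrand(strandv)
  pos <- ifelse(strandv == "+", GenomicRanges::start(reads),
                GenomicRanges::end(reads))
  .kmerAtGRanges(pos, strandv, as.character(GenomicRanges::seqnames(reads)),
                 seqs, 3L)
}

#' k-mer immediately downstream of read 3' ends
#'
#' The k bases just past the read's 3' end, read 5'->3' along the read
#' orientation: on the plus strand the k bases after the read end, on the
#' minus strand the reverse complement of the k bases before the read
#' start. Under phased (tail-to-head) biogenesis this window is the next
#' fragment's 5' end. NA at sequence boundaries or over N.
#'
#' @inheritParams fivePrimeTrinucleotide
#' @param k k-mer length (default 3).
#' @return character vector, NA where unavailable.
#' @export
downstreamKmer <- function(reads, seqs, k = 3L) {
  strandv <- as.character(GenomicRanges::strand(reads))
  .checkStrand(strandv)
  pos <- ifelse(strandv == "+", GenomicRanges::end(reads) + 1L,
                GenomicRanges::start(reads) - 1L)
  .kmerAtGRanges(pos, strandv, as.character(GenomicRanges::seqnames(reads)),
                 seqs, k)
}
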