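# Sequence input/output, chunking of long sequences and coordinate lift-back.
#
# Sequence collections are represented throughout the package as named
# character vectors: names are the sequence IDs (FASTA header up to the
# first whitespace), values the DNA strings with case preserved.

#' Read a FASTA file
#'
#' Reads one or more DNA records from a (possibly multi-line) FASTA file.
#' IDs are taken from the header up to the first whitespace; the remaining
#' description is dropped. Sequence case is preserved (soft-masked
#' lowercase is retained and still searched by the miner).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) stopf("FASTA file is empty: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stopf("not a FASTA file (no '>' header line): %s", path)
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence IDs in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Convert a FASTQ file to FASTA records
#'
#' Reads a plain 4-line-per-record FASTQ file, discards the quality lines
#' and returns the reads as a FASTA-style sequence collection. IDs come
#' from the \code{@} lines (up to the first whitespace).
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of sequences.
#' @export
fastq_to_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) stopf("FASTQ file is empty: %s", path)
  if (length(lines) %% 4L != 0L) {
    stopf("truncated FASTQ record %d in %s", length(lines) %/% 4L + 1L, path)
  }
  idx <- seq(1L, length(lines), by = 4L)
  for (k in seq_along(idx)) {
    if (!startsWith(lines[idx[k]], "@")) {
      stopf("malformed FASTQ record %d in %s (no '@' header)", k, path)
    }
    if (!startsWith(lines[idx[k] + 2L], "+")) {
      stopf("malformed FASTQ record %d in %s (no '+' separator)", k, path)
    }
    if (nchar(lines[idx[k] + 1L]) != nchar(lines[idx[k] + 3L])) {
      stopf("malformed FASTQ record %d in %s (sequence/quality length mismatch)",
            k, path)
    }
  }
  ids <- sub("^@", "", lines[idx])
  ids <- sub("\\s.*$", "", ids)
  seqs <- lines[idx + 1L]
  if (anyDuplicated(ids)) {
    stopf("duplicate read IDs in %s", path)
  }
  names(seqs) <- ids
  seqs
}

#' Split a sequence into overlapping chunks
#'
#' Long sequences are mined chunk by chunk; consecutive chunks share
#' \code{overlap} bases so that short repeats crossing a chunk border are
#' still seen complete in one of the two chunks, and longer border-spanning
#' runs are reassembled afterwards (see \code{\link{merge_chunk_loci}}).
#' Chunk \code{k} (0-based) covers parent positions
#' \code{[k*(chunk_size-overlap), k*(chunk_size-overlap)+chunk_size)},
#' clipped at the parent end.
#'
#' @param sequence A single DNA string.
#' @param chunk_size Chunk length in bp (default 2e6).
#' @param overlap Overlap between consecutive chunks in bp (default 20).
#' @param parent_id Optional sequence ID recorded on each chunk.
#' @return data.frame with columns parent_id, index (0-based), offset
#'   (0-based start of chunk within parent), overlap, sequence.
#' @export
chunk_sequence <- function(sequence, chunk_size = 2000000L, overlap = 20L,
                           parent_id = "seq") {
  chunk_size <- as.integer(chunk_size)
  overlap <- as.integer(overlap)
  if (is.na(chunk_size) || chunk_size <= 0L) stopf("chunk_size must be positive")
  if (overlap < 0L) stopf("overlap must be non-negative")
  if (chunk_size <= 2L * overlap) {
    stopf("chunk_size (%d) must exceed twice the overlap (%d)",
          chunk_size, overlap)
  }
  n <- nchar(sequence)
  step <- chunk_size - overlap
  if (n <= chunk_size) {
    offsets <- 0L
  } else {
    k_last <- ceiling((n - chunk_size) / step)
    offsets <- as.integer(seq(0L, by = step, length.out = k_last + 1L))
  }
  data.frame(
    parent_id = parent_id,
    index = seq_along(offsets) - 1L,
    offset = offsets,
    overlap = overlap,
    sequence = substring(sequence, offsets + 1L,
                         pmin(offsets + chunk_size, n)),
    stringsAsFactors = FALSE
  )
}

#' Lift a chunk-local position back to its parent sequence
#'
#' @param chunk One row of the data.frame from \code{\link{chunk_sequence}}
#'   (or any list with `offset` and `sequence`).
#' @param local_pos 1-based position within the chunk.
#' @return 1-based position on the parent sequence.
#' @export
lift_to_parent <- function(chunk, local_pos) {
  len <- nchar(chunk$sequence)
  if (any(local_pos < 1L | local_pos > len)) {
    stopf("local position out of chunk range [1, %d]", len)
  }
  chunk$offset + local_pos
}

#' Extract a flanking window around a locus
#'
#' Returns the subsequence \code{[max(1, start-flank), min(L, end+flank)]},
#' silently clipped at the sequence ends, together with the 1-based parent
#' coordinate of the window start (needed to lift primer positions found
#' within the window back onto the parent).
#'
#' @param sequence A single DNA string.
#' @param start,end 1-based inclusive locus coordinates.
#' @param flank Flank length in bp on each side (default 400).
#' @return List with elements `sequence` and `start` (parent coordinate of
#'   the first window base).
#' @export
extract_flank <- function(sequence, start, end, flank = 400L) {
  n <- nchar(sequence)
  if (start < 1L || end < start || end > n) {
    stopf("invalid locus interval [%d, %d] on sequence of length %d",
          start, end, n)
  }
  if (flank < 0L) stopf("flank must be non-negative")
  ws <- max(1L, start - flank)
  we <- min(n, end + flank)
  list(sequence = substr(sequence, ws, we), start = as.integer(ws))
}
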