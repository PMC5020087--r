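# The five statistical classifications of a locus collection and the
# sectioned `.sat2` report: motif type by unit length, motif composition,
# complementary motif groups, per-sequence SSR frequency, and SSR length
# distribution. Class tables carry count and percentage in descending rank.

count_table <- function(keys, key_name) {
  if (length(keys) == 0L) {
    out <- data.frame(k = character(), count = integer(),
                      percentage = numeric(), stringsAsFactors = FALSE)
    names(out)[1] <- key_name
    return(out)
  }
  tab <- table(keys)
  out <- data.frame(k = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- round(100 * out$count / sum(out$count), 2)
  out <- out[order(-out$count, out$k), , drop = FALSE]
  names(out)[1] <- key_name
  rownames(out) <- NULL
  out
}

#' Classify loci by motif unit length
#'
#' @param loci Locus data.frame (see \code{\link{mine_genome}}).
#' @return data.frame unit_length, count, percentage, descending by count.
#' @export
classify_unit_length <- function(loci) {
  out <- count_table(as.character(nchar(loci$motif)), "unit_length")
  out$unit_length <- as.integer(out$unit_length)
  out
}

#' Classify loci by motif composition
#'
#' Motifs are counted exactly as reported by the miner (phase preserved,
#' no canonical rotation).
#'
#' @param loci Locus data.frame.
#' @return data.frame motif, count, percentage, descending by count.
#' @export
classify_motif <- function(loci) {
  count_table(loci$motif, "motif")
}

#' Group loci by complementary motif pairs
#'
#' When strand orientation is unknown a motif and its reverse complement
#' describe the same repeat, so the two are pooled into one group labelled
#' "X/Y" with X the lexicographically smaller of the pair (GA and TC form
#' "GA/TC"; a self-complementary motif such as AT forms "AT/AT").
#'
#' @param loci Locus data.frame.
#' @return data.frame group, count, percentage, descending by count.
#' @export
group_complementary <- function(loci) {
  if (nrow(loci) == 0L) return(count_table(character(0), "group"))
  rc <- revcomp(loci$motif)
  a <- pmin(loci$motif, rc)
  b <- pmax(loci$motif, rc)
  count_table(paste0(a, "/", b), "group")
}

#' Per-sequence SSR frequency
#'
#' One row per input sequence (zero-count sequences included) with the SSR
#' count, the sequence length, and frequency = scale * count / length.
#' The default scale of 1e6 reports SSRs per megabase; \code{scale =
#' 100000} reproduces the alternative per-100-kb convention.
#'
#' @param loci Locus data.frame.
#' @param seqs Named character vector of sequences, or a named numeric
#'   vector of sequence lengths.
#' @param scale Frequency scale constant (default 1e6).
#' @return data.frame seq_id, count, length, frequency, descending by
#'   frequency.
#' @export
per_sequence_frequency <- function(loci, seqs, scale = 1e6) {
  lens <- if (is.character(seqs)) nchar(seqs) else seqs
  if (is.null(names(lens))) stopf("seqs must be named")
  orphan <- setdiff(unique(loci$seq_id), names(lens))
  if (length(orphan)) {
    stopf("loci reference unknown sequence(s): %s",
          paste(orphan, collapse = ", "))
  }
  cnt <- table(factor(loci$seq_id, levels = names(lens)))
  out <- data.frame(seq_id = names(lens),
                    count = as.integer(cnt),
                    length = as.integer(unname(lens)),
                    stringsAsFactors = FALSE)
  out$frequency <- scale * out$count / out$length
  out <- out[order(-out$frequency, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SSR length distribution
#'
#' Counts loci by total tract length (end - start + 1).
#'
#' @param loci Locus data.frame.
#' @return data.frame ssr_length, count, percentage, descending by count.
#' @export
length_distribution <- function(loci) {
  out <- count_table(as.character(loci$end - loci$start + 1L), "ssr_length")
  out$ssr_length <- as.integer(out$ssr_length)
  out
}

#' Compute all five statistical classifications
#'
#' @param loci Locus data.frame.
#' @param seqs Named character vector of sequences (or named lengths).
#' @param scale Frequency scale constant (default 1e6).
#' @return List of class \code{ssr_stats} with elements unit_length,
#'   motif, complement_group, frequency, ssr_length.
#' @export
ssr_stats <- function(loci, seqs, scale = 1e6) {
  structure(list(unit_length = classify_unit_length(loci),
                 motif = classify_motif(loci),
                 complement_group = group_complementary(loci),
                 frequency = per_sequence_frequency(loci, seqs, scale),
                 ssr_length = length_distribution(loci)),
            class = "ssr_stats")
}

.sat2_sections <- c(unit_length = "Motif unit length",
                    motif = "Motif composition",
                    complement_group = "Complementary motif groups",
                    frequency = "SSR frequency per sequence",
                    ssr_length = "SSR length distribution")

#' Write / read the `.sat2` statistics report
#'
#' Sectioned tab-separated text: each of the five classifications is
#' emitted under a \code{## section} header with its own column header
#' line, rows in descending rank. \code{read_sat2} reproduces the tables.
#'
#' @param stats An \code{\link{ssr_stats}} object.
#' @param path Output path.
#' @return Invisibly, `path` (\code{write_sat2}); an \code{ssr_stats} list
#'   (\code{read_sat2}).
#' @export
write_sat2 <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(.sat2_sections)) {
    writeLines(paste0("## ", .sat2_sections[[key]]), con)
    tab <- stats[[key]]
    writeLines(paste(names(tab), collapse = "\t"), con)
    if (nrow(tab)) {
      body <- do.call(paste, c(lapply(tab, format_col), list(sep = "\t")))
      writeLines(body, con)
    }
    writeLines("", con)
  }
  invisible(path)
}

format_col <- function(x) {
  if (is.double(x)) formatC(x, format = "g", digits = 15) else as.character(x)
}

#' @rdname write_sat2
#' @export
read_sat2 <- function(path) {
  lines <- readLines(path)
  heads <- grep("^## ", lines)
  out <- list()
  for (h in seq_along(heads)) {
    title <- sub("^## ", "", lines[heads[h]])
    key <- names(.sat2_sections)[match(title, .sat2_sections)]
    from <- heads[h] + 1L
    to <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(block)]
    cols <- strsplit(block[1], "\t", fixed = TRUE)[[1]]
    if (length(block) > 1L) {
      cells <- do.call(rbind, strsplit(block[-1], "\t", fixed = TRUE))
      tab <- as.data.frame(cells, stringsAsFactors = FALSE)
      names(tab) <- cols
      int_cols <- c("unit_length", "count", "length", "ssr_length")
      num_cols <- c("percentage", "frequency")
      for (cc in cols) {
        if (cc %in% int_cols) tab[[cc]] <- as.integer(tab[[cc]])
        if (cc %in% num_cols) tab[[cc]] <- as.numeric(tab[[cc]])
      }
    } else {
      tab <- data.frame(matrix(nrow = 0, ncol = length(cols)))
      names(tab) <- cols
    }
    out[[key]] <- tab
  }
  structure(out, class = "ssr_stats")
}
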