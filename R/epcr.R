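# Electronic PCR: locate primer binding sites on target sequences, pair
# convergent sites into predicted amplicons, score per-marker allele sizes
# and polymorphism across targets, and summarise the mapping.

#' e-PCR parameters
#'
#' @param max_mismatch Mismatches allowed per primer (default 0, strict;
#'   relax for cross-species transferability screening).
#' @param three_prime_exact Number of 3'-terminal primer bases that must
#'   match exactly (default 3; polymerase extension requires an annealed
#'   3' end).
#' @param size_min,size_max Absolute amplicon size bounds in bp (default
#'   50-5000; prevents pathological sequence-spanning pairings).
#' @param size_margin Optional margin around a marker's declared product
#'   size; \code{Inf} (default) disables the declared-size filter, which
#'   is what allele-length polymorphism scoring needs.
#' @return List of class \code{epcr_params}.
#' @export
epcr_params <- function(max_mismatch = 0L, three_prime_exact = 3L,
                        size_min = 50L, size_max = 5000L,
                        size_margin = Inf) {
  if (max_mismatch < 0L || three_prime_exact < 0L || size_min < 0L) {
    stopf("e-PCR parameters must be non-negative")
  }
  structure(list(max_mismatch = as.integer(max_mismatch),
                 three_prime_exact = as.integer(three_prime_exact),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 size_margin = size_margin),
            class = "epcr_params")
}

#' Find primer binding sites on a sequence
#'
#' Reports every match of the primer on the forward strand and every match
#' of its reverse complement (a reverse-strand binding site), honoring the
#' mismatch budget with the primer's 3'-terminal bases required to match
#' exactly.
#'
#' @param sequence A single DNA string.
#' @param primer Primer sequence, 5'->3'.
#' @param params An \code{\link{epcr_params}}.
#' @return data.frame position (1-based start of the match on the forward
#'   strand), strand ("+" or "-"), mismatches.
#' @export
find_primer_sites <- function(sequence, primer, params = epcr_params()) {
  primer <- toupper(primer)
  plen <- nchar(primer)
  if (plen < params$three_prime_exact) {
    stopf("primer shorter than the exact 3'-end requirement")
  }
  subject <- Biostrings::DNAString(toupper(sequence))
  hit_df <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = params$max_mismatch)
    if (length(m) == 0L) {
      return(data.frame(position = integer(), strand = character(),
                        mismatches = integer(), stringsAsFactors = FALSE))
    }
    st <- BiocGenerics::start(m)
    mm <- vapply(seq_along(m), function(i) {
      sum(strsplit(as.character(m[[i]]), "")[[1]] !=
            strsplit(pattern, "")[[1]])
    }, integer(1))
    # 3' end exactness: last bases of the primer for "+", first bases of
    # the reverse-complement image for "-"
    k <- params$three_prime_exact
    keep <- vapply(seq_along(m), function(i) {
      hit <- as.character(m[[i]])
      if (k == 0L) return(TRUE)
      if (strand == "+") {
        substr(hit, plen - k + 1L, plen) ==
          substr(pattern, plen - k + 1L, plen)
      } else {
        substr(hit, 1L, k) == substr(pattern, 1L, k)
      }
    }, logical(1))
    data.frame(position = st[keep], strand = rep(strand, sum(keep)),
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  fwd <- hit_df(primer, "+")
  rev <- hit_df(revcomp(primer), "-")
  out <- rbind(fwd, rev)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Map markers onto target sequences by e-PCR
#'
#' For every marker and target, pairs each forward-strand site of one
#' primer with each downstream reverse-strand site of the other primer (in
#' both template orientations), keeping size-valid, convergent pairings as
#' predicted amplicons. Duplicate coordinate pairs collapse to one record.
#'
#' @param markers A \code{marker_set} or a markers data.frame
#'   (\code{\link{read_sts}} output).
#' @param seqs Named character vector of target sequences.
#' @param params An \code{\link{epcr_params}}.
#' @return data.frame marker_id, seq_id, start, end, size, strand (of the
#'   left primer), mm_left, mm_right.
#' @export
epcr <- function(markers, seqs, params = epcr_params()) {
  m <- if (inherits(markers, "marker_set")) markers$markers else markers
  out <- list()
  for (i in seq_len(nrow(m))) {
    declared <- m$product_size[i]
    for (sid in names(seqs)) {
      sl <- find_primer_sites(seqs[[sid]], m$left_primer[i], params)
      if (nrow(sl) == 0L) next
      sr <- find_primer_sites(seqs[[sid]], m$right_primer[i], params)
      if (nrow(sr) == 0L) next
      llen <- nchar(m$left_primer[i])
      rlen <- nchar(m$right_primer[i])
      amps <- rbind(
        pair_sites(sl, llen, sr, rlen, "+"),   # left fwd, right rev
        pair_sites(sr, rlen, sl, llen, "-"))   # right fwd, left rev
      if (nrow(amps) == 0L) next
      ok <- amps$size >= params$size_min & amps$size <= params$size_max
      if (is.finite(params$size_margin)) {
        ok <- ok & abs(amps$size - declared) <= params$size_margin
      }
      amps <- amps[ok, , drop = FALSE]
      if (nrow(amps) == 0L) next
      amps$marker_id <- m$marker_id[i]
      amps$seq_id <- sid
      out[[length(out) + 1L]] <- amps
    }
  }
  if (!length(out)) {
    return(data.frame(marker_id = character(), seq_id = character(),
                      start = integer(), end = integer(), size = integer(),
                      strand = character(), mm_left = integer(),
                      mm_right = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("marker_id", "seq_id", "start", "end")]),
             c("marker_id", "seq_id", "start", "end", "size", "strand",
               "mm_left", "mm_right"), drop = FALSE]
  res <- res[order(res$marker_id, res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# pair forward sites of primer A with downstream reverse sites of primer B
pair_sites <- function(sa, alen, sb, blen, left_strand) {
  af <- sa[sa$strand == "+", , drop = FALSE]
  br <- sb[sb$strand == "-", , drop = FALSE]
  if (nrow(af) == 0L || nrow(br) == 0L) {
    return(data.frame(start = integer(), end = integer(), size = integer(),
                      strand = character(), mm_left = integer(),
                      mm_right = integer(), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(a = seq_len(nrow(af)), b = seq_len(nrow(br)))
  start <- af$position[grid$a]
  end <- br$position[grid$b] + blen - 1L
  keep <- br$position[grid$b] >= af$position[grid$a] + alen
  mm_a <- af$mismatches[grid$a]
  mm_b <- br$mismatches[grid$b]
  data.frame(start = start[keep], end = end[keep],
             size = (end - start + 1L)[keep],
             strand = left_strand,
             mm_left = if (left_strand == "+") mm_a[keep] else mm_b[keep],
             mm_right = if (left_strand == "+") mm_b[keep] else mm_a[keep],
             stringsAsFactors = FALSE)
}

#' Score marker polymorphism across targets
#'
#' Builds the marker-by-sequence allele matrix: each cell holds the sorted
#' amplicon sizes of that marker on that target joined with "+"
#' (multi-band amplification), or "NA" when the marker does not amplify.
#' A marker is polymorphic when at least two distinct non-NA cell values
#' occur across the targets.
#'
#' @param amplicons Amplicon data.frame from \code{\link{epcr}}.
#' @param markers A \code{marker_set} or markers data.frame.
#' @param seqs Named character vector (or named lengths) of the targets.
#' @return List with \code{matrix} (data.frame, one row per marker, one
#'   column per target) and \code{polymorphic} (named logical per marker).
#' @export
score_polymorphism <- function(amplicons, markers, seqs) {
  m <- if (inherits(markers, "marker_set")) markers$markers else markers
  ids <- m$marker_id
  targets <- names(seqs)
  cell <- matrix("NA", nrow = length(ids), ncol = length(targets),
                 dimnames = list(ids, targets))
  amp <- amplicons[amplicons$marker_id %in% ids &
                     amplicons$seq_id %in% targets, , drop = FALSE]
  if (nrow(amp)) {
    agg <- stats::aggregate(size ~ marker_id + seq_id, data = amp,
                            FUN = function(x) {
                              paste(sort(unique(x)), collapse = "+")
                            })
    for (r in seq_len(nrow(agg))) {
      cell[agg$marker_id[r], agg$seq_id[r]] <- agg$size[r]
    }
  }
  poly <- apply(cell, 1, function(row) {
    vals <- unique(row[row != "NA"])
    length(vals) >= 2L
  })
  mat <- data.frame(marker_id = ids, cell, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(mat) <- NULL
  list(matrix = mat, polymorphic = poly)
}

#' Summarise an e-mapping run
#'
#' The `.sat4` quantities: the distribution of allele counts over markers,
#' the number of target sequences with at least one mapped marker, the
#' number of mapped markers, the total amplicon count, and the mean number
#' of amplicons per mapped marker.
#'
#' @param amplicons Amplicon data.frame from \code{\link{epcr}}.
#' @param markers A \code{marker_set} or markers data.frame.
#' @param seqs Named character vector (or named lengths) of the targets.
#' @return List n_markers, n_markers_mapped, n_sequences_with_marker,
#'   total_amplicons, mean_amplicons_per_mapped_marker,
#'   allele_count_distribution (table: distinct allele sizes per marker,
#'   mapped markers only).
#' @export
summarize_mapping <- function(amplicons, markers, seqs) {
  m <- if (inherits(markers, "marker_set")) markers$markers else markers
  n_mapped <- length(unique(amplicons$marker_id))
  total <- nrow(amplicons)
  if (n_mapped == 0L) {
    message("no markers mapped; mean amplicons per mapped marker reported as 0")
    mean_amp <- 0
    dist <- table(integer(0))
  } else {
    mean_amp <- total / n_mapped
    alleles <- tapply(amplicons$size, amplicons$marker_id,
                      function(x) length(unique(x)))
    dist <- table(alleles)
  }
  list(n_markers = nrow(m),
       n_markers_mapped = n_mapped,
       n_sequences_with_marker = length(unique(amplicons$seq_id)),
       total_amplicons = total,
       mean_amplicons_per_mapped_marker = mean_amp,
       allele_count_distribution = dist)
}

#' Write e-mapping result files
#'
#' \code{write_amp}: the amplicon table (TSV). \code{write_frg}: the
#' allele matrix with NA cells. \code{write_emap}: per-target list of
#' mapped markers. \code{write_sat4}: the mapping summary.
#'
#' @param amplicons,score,summary Outputs of \code{\link{epcr}},
#'   \code{\link{score_polymorphism}} and \code{\link{summarize_mapping}}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_amp <- function(amplicons, path) {
  utils::write.table(amplicons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_amp
#' @export
read_amp <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "character",
                                   "integer", "integer"))
}

#' @rdname write_amp
#' @export
write_frg <- function(score, path) {
  tab <- score$matrix
  tab$polymorphic <- ifelse(score$polymorphic[tab$marker_id], "yes", "no")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_amp
#' @export
write_emap <- function(amplicons, seqs, path) {
  ids <- names(seqs)
  lines <- vapply(ids, function(sid) {
    mk <- unique(amplicons$marker_id[amplicons$seq_id == sid])
    paste0(sid, "\t", paste(mk, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_amp
#' @export
write_sat4 <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("Total_markers\t%d", summary$n_markers),
    sprintf("Mapped_markers\t%d", summary$n_markers_mapped),
    sprintf("Sequences_with_marker\t%d", summary$n_sequences_with_marker),
    sprintf("Total_amplicons\t%d", summary$total_amplicons),
    sprintf("Mean_amplicons_per_mapped_marker\t%s",
            formatC(summary$mean_amplicons_per_mapped_marker,
                    format = "g", digits = 15)),
    "## Allele count distribution (alleles\tmarkers)"), con)
  d <- summary$allele_count_distribution
  if (length(d)) {
    writeLines(paste0(names(d), "\t", as.integer(d)), con)
  }
  invisible(path)
}
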