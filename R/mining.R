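# SSR mining: motif library, maximal tandem-run detection, chunk merging.
#
# A reported locus is a maximal whole-copy tandem run of a primitive motif:
# it cannot be extended by one unit on either side, the motif is not itself
# a repetition of a shorter word, and runs of the same minimal period never
# overlap (the scan is greedy left-to-right, matching a regex engine
# consuming the sequence). Loci whose interval is contained in another
# reported locus are dropped by default.

#' Mining configuration
#'
#' @param min_unit,max_unit Motif unit length range in bp. Default 2-6;
#'   monomer mining is off by default and is enabled by setting
#'   \code{min_unit = 1} (a minimum of 12 copies for monomers is the
#'   conventional choice, e.g. \code{min_repeats = c("1" = 12)} merged
#'   with the dimer-and-up default).
#' @param min_repeats Minimum copy number per unit length: either a single
#'   number applied to every unit length, or a named vector keyed by unit
#'   length (\code{c("1" = 12, "2" = 5, ...)}). Unnamed default: 5 copies
#'   for every unit length. All values must be >= 2.
#' @param chunk_size Sequences longer than this are mined in overlapping
#'   chunks (default 2,000,000 bp).
#' @param overlap Chunk overlap in bp (default 20).
#' @param containment_filter Drop loci whose interval lies within another
#'   reported locus (default TRUE). On ties (equal interval) the shorter
#'   period is kept.
#' @return A list of class \code{mining_config}.
#' @export
mining_config <- function(min_unit = 2L, max_unit = 6L, min_repeats = 5L,
                          chunk_size = 2000000L, overlap = 20L,
                          containment_filter = TRUE) {
  min_unit <- as.integer(min_unit)
  max_unit <- as.integer(max_unit)
  if (is.na(min_unit) || min_unit < 1L) stopf("min_unit must be >= 1")
  if (max_unit < min_unit) stopf("max_unit must be >= min_unit")
  units <- min_unit:max_unit
  if (is.null(names(min_repeats))) {
    if (length(min_repeats) == 1L) {
      mr <- stats::setNames(rep(as.integer(min_repeats), length(units)),
                            as.character(units))
    } else if (length(min_repeats) == length(units)) {
      mr <- stats::setNames(as.integer(min_repeats), as.character(units))
    } else {
      stopf("min_repeats must be length 1, one per unit length, or named")
    }
  } else {
    mr <- stats::setNames(rep(5L, length(units)), as.character(units))
    given <- stats::setNames(as.integer(min_repeats), names(min_repeats))
    keep <- intersect(names(given), names(mr))
    mr[keep] <- given[keep]
  }
  if (any(mr < 2L)) stopf("every min_repeats value must be >= 2")
  structure(list(min_unit = min_unit, max_unit = max_unit,
                 min_repeats = mr,
                 chunk_size = as.integer(chunk_size),
                 overlap = as.integer(overlap),
                 containment_filter = isTRUE(containment_filter)),
            class = "mining_config")
}

#' Build the primitive motif library
#'
#' All words over {A,C,G,T} of each length in \code{[min_unit, max_unit]},
#' excluding non-primitive words (words that are repetitions of a shorter
#' word, e.g. AA or ATAT). Ordered by length ascending then
#' lexicographically.
#'
#' @param min_unit,max_unit Unit length bounds.
#' @return Character vector of motifs.
#' @export
build_motif_library <- function(min_unit, max_unit) {
  min_unit <- as.integer(min_unit)
  max_unit <- as.integer(max_unit)
  if (is.na(min_unit) || min_unit < 1L) stopf("min_unit must be >= 1")
  if (max_unit < min_unit) stopf("max_unit must be >= min_unit")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in min_unit:max_unit) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), p),
                      list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
    # expand.grid varies the first column fastest; reverse for lexicographic
    words <- do.call(paste0, rev(grid))
    words <- sort(words)
    out <- c(out, words[is_primitive(words)])
  }
  out
}

# Collect phase-0 candidate runs of period p.
# x: integer codepoints of the uppercased sequence; valid: A/C/G/T mask.
# Returns data.frame(start, end, region_end, copies, period) for runs with
# copies >= minrep, plus (if relax_edges) runs of >= 2 copies whose
# periodic region touches a sequence end -- those are potentially truncated
# pieces of a border-spanning run and are resolved by merge_chunk_loci().
collect_runs <- function(su, x, valid, p, minrep, relax_edges = FALSE) {
  n <- length(x)
  none <- data.frame(start = integer(), end = integer(),
                     region_end = integer(), copies = integer(),
                     period = integer(), motif = character(),
                     stringsAsFactors = FALSE)
  if (n < 2L * p) return(none)
  eq <- valid[1:(n - p)] & valid[(p + 1L):n] & (x[1:(n - p)] == x[(p + 1L):n])
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keepv <- r$values & r$lengths >= p  # region >= 2 whole copies
  if (!any(keepv)) return(none)
  bs <- starts[keepv]
  be <- ends[keepv]
  region_len <- be - bs + 1L + p
  copies <- region_len %/% p
  edge <- bs <= p | (be + p) >= (n - p + 1L)
  keep <- copies >= minrep | (relax_edges & edge & copies >= 2L)
  if (!any(keep)) return(none)
  bs <- bs[keep]; be <- be[keep]; copies <- copies[keep]
  motif <- substring(su, bs, bs + p - 1L)
  prim <- is_primitive(motif)
  if (!any(prim)) return(none)
  data.frame(start = bs[prim],
             end = bs[prim] + copies[prim] * p - 1L,
             region_end = be[prim] + p,
             copies = copies[prim],
             period = p,
             motif = motif[prim],
             stringsAsFactors = FALSE)
}

# Greedy left-to-right selection within one period: runs are taken in start
# order; a run overlapping the previously accepted one is shifted right to
# the first free position (re-reading its motif there), mirroring a regex
# scan that resumes after each match. Drops runs that fall below minrep
# after the shift.
resolve_period_overlaps <- function(runs, su, minrep) {
  if (nrow(runs) <= 1L) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  p <- runs$period[1]
  last_end <- 0L
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    if (s <= last_end) {
      s <- last_end + 1L
      cp <- (runs$region_end[i] - s + 1L) %/% p
      if (cp < minrep) next
      runs$start[i] <- s
      runs$copies[i] <- cp
      runs$end[i] <- s + cp * p - 1L
      runs$motif[i] <- substr(su, s, s + p - 1L)
    }
    keep[i] <- TRUE
    last_end <- runs$end[i]
  }
  runs[keep, , drop = FALSE]
}

# Drop loci whose interval is contained within another locus's interval.
# Keeps the longer locus; on an equal interval, the shorter period wins.
filter_contained <- function(loci) {
  if (nrow(loci) <= 1L) return(loci)
  ord <- order(loci$start, -loci$end, nchar(loci$motif))
  loci <- loci[ord, , drop = FALSE]
  maxend <- -1L
  keep <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (loci$end[i] <= maxend) next
    keep[i] <- TRUE
    maxend <- loci$end[i]
  }
  loci[keep, , drop = FALSE]
}

#' Find SSR loci in a single sequence
#'
#' Scans one DNA string for maximal whole-copy tandem runs of primitive
#' motifs within the configured unit-length range. The search is
#' case-insensitive; non-ACGT characters never match. Coordinates are
#' 1-based inclusive and local to the given sequence.
#'
#' @param sequence A single DNA string.
#' @param config A \code{\link{mining_config}}.
#' @return data.frame with columns start, end, repetitions, motif
#'   (reported in the phase in which it occurs at \code{start}, uppercase),
#'   sorted by start.
#' @export
find_ssrs <- function(sequence, config = mining_config()) {
  su <- toupper(sequence)
  x <- utf8ToInt(su)
  valid <- x == 65L | x == 67L | x == 71L | x == 84L
  all_runs <- list()
  for (p in config$min_unit:config$max_unit) {
    minrep <- config$min_repeats[[as.character(p)]]
    runs <- collect_runs(su, x, valid, p, minrep)
    runs <- runs[runs$copies >= minrep, , drop = FALSE]
    if (nrow(runs)) {
      all_runs[[length(all_runs) + 1L]] <-
        resolve_period_overlaps(runs, su, minrep)
    }
  }
  finalize_loci(all_runs, config)
}

# shared tail of find_ssrs / merge_chunk_loci
finalize_loci <- function(run_list, config) {
  if (!length(run_list)) {
    out <- empty_loci()
    return(out[, c("start", "end", "repetitions", "motif")])
  }
  runs <- do.call(rbind, run_list)
  loci <- data.frame(start = runs$start, end = runs$end,
                     repetitions = runs$copies, motif = runs$motif,
                     stringsAsFactors = FALSE)
  if (config$containment_filter) loci <- filter_contained(loci)
  loci <- loci[order(loci$start, nchar(loci$motif)), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Merge per-chunk loci into parent-coordinate loci
#'
#' Collapses duplicate loci reported from overlapping chunks and coalesces
#' runs of rotation-equivalent motifs that overlap or abut in phase
#' (pieces of one tandem run split at a chunk border). When the parent
#' sequence is supplied, each merged run is re-anchored on it: extended by
#' whole units in both directions, its motif re-read at the merged start,
#' and the copy-number threshold re-applied, so chunked mining reproduces
#' unchunked mining exactly.
#'
#' @param runs data.frame of per-chunk runs lifted to parent coordinates
#'   (columns start, end, motif; copies/period derived if absent).
#' @param sequence The parent DNA string (strongly recommended).
#' @param config A \code{\link{mining_config}}.
#' @return data.frame start, end, repetitions, motif in parent coordinates.
#' @export
merge_chunk_loci <- function(runs, sequence = NULL,
                             config = mining_config()) {
  if (is.null(runs) || nrow(runs) == 0L) {
    return(finalize_loci(list(), config))
  }
  runs$period <- nchar(runs$motif)
  runs <- unique(runs[, c("start", "end", "motif", "period")])
  su <- if (!is.null(sequence)) toupper(sequence) else NULL
  out <- list()
  for (p in sort(unique(runs$period))) {
    rp <- runs[runs$period == p, , drop = FALSE]
    rp <- rp[order(rp$start, rp$end), , drop = FALSE]
    # coalesce in-phase overlapping/abutting pieces
    merged <- list()
    cur <- rp[1, , drop = FALSE]
    if (nrow(rp) > 1L) {
      for (i in 2L:nrow(rp)) {
        nxt <- rp[i, , drop = FALSE]
        in_phase <- nxt$motif ==
          rotate_word(cur$motif, (nxt$start - cur$start) %% p)
        if (nxt$start <= cur$end + 1L && in_phase) {
          cur$end <- max(cur$end, nxt$end)
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- nxt
        }
      }
    }
    merged[[length(merged) + 1L]] <- cur
    mp <- do.call(rbind, merged)
    # re-anchor on the parent
    minrep <- minrep_for(config, p)
    res <- lapply(seq_len(nrow(mp)), function(i) {
      s <- mp$start[i]; e <- mp$end[i]
      if (!is.null(su)) {
        unit <- substr(su, s, s + p - 1L)
        while (s - p >= 1L && substr(su, s - p, s - 1L) == unit) s <- s - p
        cp <- (e - s + 1L) %/% p
        e <- s + cp * p - 1L
        while (substr(su, e + 1L, e + p) == unit) e <- e + p
        cp <- (e - s + 1L) %/% p
        data.frame(start = s, end = e, region_end = e, copies = cp,
                   period = p, motif = unit, stringsAsFactors = FALSE)
      } else {
        cp <- (e - s + 1L) %/% p
        data.frame(start = s, end = s + cp * p - 1L,
                   region_end = e, copies = cp, period = p,
                   motif = mp$motif[i], stringsAsFactors = FALSE)
      }
    })
    rr <- unique(do.call(rbind, res))
    rr <- rr[rr$copies >= minrep, , drop = FALSE]
    if (nrow(rr)) {
      if (!is.null(su)) rr <- resolve_period_overlaps(rr, su, minrep)
      out[[length(out) + 1L]] <- rr
    }
  }
  finalize_loci(out, config)
}

minrep_for <- function(config, p) {
  key <- as.character(p)
  if (key %in% names(config$min_repeats)) config$min_repeats[[key]] else 2L
}

#' Mine SSR loci from a sequence collection
#'
#' Runs the full mining pipeline per record: chunk (for sequences longer
#' than \code{chunk_size}), find runs per chunk, lift local coordinates to
#' the parent, merge border pieces, and assemble the locus table in the
#' layout of the `.ssr` file (Name, Seq_Len, StartPos, EndPos, Repetitions,
#' Motif).
#'
#' @param seqs Named character vector of sequences (see
#'   \code{\link{read_fasta}}).
#' @param config A \code{\link{mining_config}}.
#' @return List with elements \code{loci} (data.frame seq_id, seq_len,
#'   start, end, repetitions, motif) and \code{summary} (list n_sequences,
#'   total_length, n_loci).
#' @export
mine_genome <- function(seqs, config = mining_config()) {
  if (length(seqs) == 0L) stopf("no input sequences")
  per_seq <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    id <- names(seqs)[i]
    n <- nchar(s)
    if (n <= config$chunk_size) {
      loci <- find_ssrs(s, config)
    } else {
      chunks <- chunk_sequence(s, config$chunk_size, config$overlap,
                               parent_id = id)
      pieces <- lapply(seq_len(nrow(chunks)), function(k) {
        cs <- chunks$sequence[k]
        csu <- toupper(cs)
        x <- utf8ToInt(csu)
        valid <- x == 65L | x == 67L | x == 71L | x == 84L
        pr <- lapply(config$min_unit:config$max_unit, function(p) {
          collect_runs(csu, x, valid, p, minrep_for(config, p),
                       relax_edges = TRUE)
        })
        pr <- do.call(rbind, pr)
        if (nrow(pr)) {
          pr$start <- pr$start + chunks$offset[k]
          pr$end <- pr$end + chunks$offset[k]
        }
        pr[, c("start", "end", "motif")]
      })
      pooled <- do.call(rbind, pieces)
      loci <- merge_chunk_loci(pooled, sequence = s, config = config)
    }
    if (nrow(loci) == 0L) return(empty_loci())
    data.frame(seq_id = id, seq_len = n,
               start = loci$start, end = loci$end,
               repetitions = loci$repetitions, motif = loci$motif,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, per_seq)
  rownames(loci) <- NULL
  summary <- list(n_sequences = length(seqs),
                  total_length = sum(nchar(seqs)),
                  n_loci = nrow(loci))
  list(loci = loci, summary = summary)
}

#' Write / read the `.ssr` locus table
#'
#' Tab-separated with one header line and columns Name (with a leading
#' \code{>}), Seq_Len, StartPos, EndPos, Repetitions, Motif.
#'
#' @param loci Locus data.frame from \code{\link{mine_genome}}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ssr <- function(loci, path) {
  out <- data.frame(Name = paste0(">", loci$seq_id),
                    Seq_Len = loci$seq_len,
                    StartPos = loci$start,
                    EndPos = loci$end,
                    Repetitions = loci$repetitions,
                    Motif = loci$motif,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ssr
#' @export
read_ssr <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "integer", "integer",
                                        "integer", "integer", "character"))
  data.frame(seq_id = sub("^>", "", x$Name), seq_len = x$Seq_Len,
             start = x$StartPos, end = x$EndPos,
             repetitions = x$Repetitions, motif = x$Motif,
             stringsAsFactors = FALSE)
}

#' Write the `.sat1` input summary
#'
#' Key-value text file with the number of input sequences, their total
#' length, and the number of SSR loci found.
#'
#' @param summary Summary list from \code{\link{mine_genome}}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sat1 <- function(summary, path) {
  writeLines(c(sprintf("Total_sequences\t%d", summary$n_sequences),
               sprintf("Total_length_bp\t%d", summary$total_length),
               sprintf("Total_SSR_loci\t%d", summary$n_loci)),
             path)
  invisible(path)
}

#' Write a FASTA file with SSR tracts highlighted
#'
#' Flanking sequence is written in lowercase and SSR tracts in uppercase,
#' so repeats stand out in any text viewer or alignment display.
#'
#' @param seqs Named character vector of sequences.
#' @param loci Locus data.frame (seq_id, start, end).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_highlight_fasta <- function(seqs, loci, path) {
  out <- vapply(seq_along(seqs), function(i) {
    s <- tolower(seqs[[i]])
    rows <- loci[loci$seq_id == names(seqs)[i], , drop = FALSE]
    if (nrow(rows)) {
      for (j in seq_len(nrow(rows))) {
        substr(s, rows$start[j], rows$end[j]) <-
          toupper(substr(s, rows$start[j], rows$end[j]))
      }
    }
    s
  }, character(1))
  names(out) <- names(seqs)
  write_fasta(out, path)
}
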