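# Synthetic genomes with planted SSR loci and mutated allele variants.
#
# The background model is i.i.d. nucleotides at a specified GC content
# with a repair pass that removes accidental tandem runs, so that the
# planted loci (and only they) survive mining at any threshold at least as
# strict as the scrub thresholds below. Every generated genome is checked
# against its truth table before it is returned.

# scrub thresholds: background must be free of these (stricter than any
# default mining preset, leaving a safety margin of one copy)
.scrub_config <- function() {
  mining_config(min_unit = 1L, max_unit = 6L,
                min_repeats = c("1" = 8L, "2" = 4L, "3" = 3L, "4" = 3L,
                                "5" = 3L, "6" = 3L),
                containment_filter = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate a synthetic genome with planted SSR loci
#'
#' Builds one or more sequences of i.i.d. background nucleotides with
#' tandem-repeat tracts planted at requested (or random non-overlapping)
#' positions. Accidental background repeats, and any background context
#' that would extend or merge with a planted tract, are repaired by point
#' mutation until mining recovers exactly the planted truth. Deterministic
#' for a fixed seed.
#'
#' @param plants data.frame with columns motif, copies and optionally
#'   seq_id (default "seq1") and start (NA = place randomly).
#' @param seq_lengths Named integer vector of sequence lengths (names
#'   become sequence IDs).
#' @param gc Background GC content (default 0.5).
#' @param seed Integer RNG seed.
#' @param spacer Minimum background gap between planted tracts (bp).
#' @return List with \code{seqs} (named character vector) and \code{truth}
#'   (data.frame seq_id, start, end, motif, copies).
#' @export
generate_genome <- function(plants, seq_lengths = c(seq1 = 10000L),
                            gc = 0.5, seed = 1L, spacer = 10L) {
  if (is.null(plants$seq_id)) plants$seq_id <- names(seq_lengths)[1]
  if (is.null(plants$start)) plants$start <- NA_integer_
  plants$copies <- as.integer(plants$copies)
  plants$motif <- toupper(plants$motif)
  if (any(!plants$seq_id %in% names(seq_lengths))) {
    stopf("plant seq_id not in seq_lengths")
  }
  if (any(plants$copies < 2L)) stopf("planted tracts need >= 2 copies")
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    for (sid in names(seq_lengths)) {
      n <- as.integer(seq_lengths[[sid]])
      pl <- plants[plants$seq_id == sid, , drop = FALSE]
      tract_len <- nchar(pl$motif) * pl$copies
      if (sum(tract_len + spacer) > n) {
        stopf("planted tracts do not fit in sequence '%s'", sid)
      }
      # fix given positions first, then place the rest randomly
      occupied <- list()
      pl$end <- NA_integer_
      given <- which(!is.na(pl$start))
      for (i in given) {
        pl$end[i] <- pl$start[i] + tract_len[i] - 1L
        if (pl$start[i] < 1L || pl$end[i] > n) {
          stopf("planted tract outside sequence '%s'", sid)
        }
        occupied[[length(occupied) + 1L]] <-
          c(pl$start[i] - spacer, pl$end[i] + spacer)
      }
      for (i in setdiff(seq_len(nrow(pl)), given)) {
        placed <- FALSE
        for (try in 1:1000) {
          s <- sample.int(n - tract_len[i] + 1L, 1L)
          e <- s + tract_len[i] - 1L
          clash <- any(vapply(occupied, function(iv) {
            s <= iv[2] && e >= iv[1]
          }, logical(1)))
          if (!clash) {
            pl$start[i] <- s
            pl$end[i] <- e
            occupied[[length(occupied) + 1L]] <- c(s - spacer, e + spacer)
            placed <- TRUE
            break
          }
        }
        if (!placed) stopf("could not place planted tract %d on '%s'", i, sid)
      }
      chars <- strsplit(random_dna(n, gc), "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(pl))) {
        chars[pl$start[i]:pl$end[i]] <-
          strsplit(strrep(pl$motif[i], pl$copies[i]), "", fixed = TRUE)[[1]]
      }
      s <- repair_background(paste(chars, collapse = ""), pl)
      seqs[[sid]] <- s
      if (nrow(pl)) {
        truth[[length(truth) + 1L]] <-
          data.frame(seq_id = sid, start = pl$start, end = pl$end,
                     motif = pl$motif, copies = pl$copies,
                     stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 motif = character(), copies = integer(),
                 stringsAsFactors = FALSE)
    truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    check_truth(seqs, truth)
    list(seqs = seqs, truth = truth)
  })
}

# Mutate background bases until a permissive scan reports exactly the
# planted tracts. Planted bases are never touched.
repair_background <- function(s, pl, max_iter = 500L) {
  cfg <- .scrub_config()
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    found <- find_ssrs(s, cfg)
    planted_ok <- logical(nrow(found))
    for (j in seq_len(nrow(found))) {
      planted_ok[j] <- nrow(pl) > 0L &&
        any(pl$start == found$start[j] & pl$end == found$end[j] &
              pl$motif == found$motif[j])
    }
    bad <- found[!planted_ok, , drop = FALSE]
    if (nrow(bad) == 0L) return(s)
    for (j in seq_len(nrow(bad))) {
      cand <- setdiff(bad$start[j]:bad$end[j],
                      unlist(lapply(seq_len(nrow(pl)), function(i) {
                        pl$start[i]:pl$end[i]
                      })))
      if (!length(cand)) next  # fully inside a plant: cannot arise
      pos <- cand[sample.int(length(cand), 1L)]
      old <- substr(s, pos, pos)
      substr(s, pos, pos) <- sample(setdiff(bases, toupper(old)), 1L)
    }
  }
  stopf("background repair did not converge")
}

# invariant check: truth tracts are literally present in the sequence
check_truth <- function(seqs, truth) {
  for (i in seq_len(nrow(truth))) {
    tract <- substr(seqs[[truth$seq_id[i]]], truth$start[i], truth$end[i])
    if (tract != strrep(truth$motif[i], truth$copies[i])) {
      stopf("truth table inconsistent with generated sequence at row %d", i)
    }
  }
  invisible(TRUE)
}

#' Mutate planted SSR allele lengths
#'
#' Applies whole-unit copy-number changes to selected planted tracts,
#' producing a variant genome whose flanking sequence is byte-identical to
#' the original. Coordinates of downstream loci shift accordingly in the
#' returned truth table.
#'
#' @param seqs Named character vector from \code{\link{generate_genome}}.
#' @param truth Truth table from \code{\link{generate_genome}}.
#' @param deltas Integer vector of copy-number changes, one per truth row
#'   (0 = unchanged; negative = deletion of copies).
#' @return List with \code{seqs}, \code{truth} (updated coordinates and
#'   copies, plus a size_delta column in bp).
#' @export
mutate_alleles <- function(seqs, truth, deltas) {
  if (length(deltas) != nrow(truth)) {
    stopf("need one delta per truth row")
  }
  deltas <- as.integer(deltas)
  new_truth <- truth
  new_truth$size_delta <- 0L
  for (sid in unique(truth$seq_id)) {
    rows <- which(truth$seq_id == sid)
    rows <- rows[order(truth$start[rows], decreasing = TRUE)]
    s <- seqs[[sid]]
    for (i in rows) {
      if (deltas[i] == 0L) next
      p <- nchar(truth$motif[i])
      new_copies <- truth$copies[i] + deltas[i]
      if (new_copies < 0L) {
        stopf("deletion exceeds tract length at truth row %d", i)
      }
      tract <- strrep(truth$motif[i], new_copies)
      s <- paste0(substr(s, 1L, truth$start[i] - 1L), tract,
                  substring(s, truth$end[i] + 1L))
      shift <- deltas[i] * p
      new_truth$copies[i] <- new_copies
      new_truth$end[i] <- new_truth$start[i] +
        new_copies * p - 1L
      new_truth$size_delta[i] <- shift
      later <- new_truth$seq_id == sid & truth$start > truth$start[i]
      new_truth$start[later] <- new_truth$start[later] + shift
      new_truth$end[later] <- new_truth$end[later] + shift
    }
    seqs[[sid]] <- s
  }
  keep <- new_truth$copies > 0L
  check_truth(seqs, new_truth[keep, , drop = FALSE])
  list(seqs = seqs, truth = new_truth)
}

#' Write a truth table to TSV
#'
#' @param truth Truth data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
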