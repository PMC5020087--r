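# Primer-pair design from SSR flanking windows and marker deduplication.
#
# Primer thermodynamics use the unified nearest-neighbor parameter set
# (SantaLucia 1998 / Allawi & SantaLucia 1997) with the von Ahsen
# monovalent-equivalent salt correction for Mg2+, under PCR-typical
# conditions: 50 mM monovalent cation, 1.5 mM Mg2+, 0.6 mM dNTP, 50 nM
# oligo. Under these conditions a well-behaved 20-mer of balanced GC sits
# close to the 60 degC design target.

# dH (kcal/mol) and dS (cal/mol/K) per 5'->3' dinucleotide step
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation per terminal base pair
.init_dh <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.init_ds <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

.gas_const <- 1.987  # cal/mol/K

#' Primer design parameters
#'
#' @param flank Flanking window length on each side of a locus (bp).
#' @param product_min,product_max Allowed amplicon size range (bp).
#' @param tm_opt Target primer melting temperature (degC).
#' @param tm_min,tm_max Allowed primer Tm range (degC).
#' @param len_min,len_max Allowed primer length range (bp).
#' @param gc_min,gc_max Allowed primer GC content range (percent).
#' @param na_mM,mg_mM,dntp_mM,oligo_nM Reaction conditions for the Tm
#'   model.
#' @return List of class \code{primer_params}.
#' @export
primer_params <- function(flank = 400L, product_min = 100L,
                          product_max = 400L, tm_opt = 60,
                          tm_min = 57, tm_max = 63,
                          len_min = 18L, len_max = 27L,
                          gc_min = 20, gc_max = 80,
                          na_mM = 50, mg_mM = 1.5, dntp_mM = 0.6,
                          oligo_nM = 50) {
  if (product_min < 2L * len_min) {
    stopf("product_min (%d) must be >= twice the minimum primer length (%d)",
          product_min, len_min)
  }
  if (product_max < product_min) stopf("product_max < product_min")
  if (len_max < len_min) stopf("len_max < len_min")
  structure(list(flank = as.integer(flank),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 tm_opt = tm_opt, tm_min = tm_min, tm_max = tm_max,
                 len_min = as.integer(len_min),
                 len_max = as.integer(len_max),
                 gc_min = gc_min, gc_max = gc_max,
                 na_mM = na_mM, mg_mM = mg_mM, dntp_mM = dntp_mM,
                 oligo_nM = oligo_nM),
            class = "primer_params")
}

# monovalent-equivalent cation concentration (mol/L)
effective_monovalent <- function(params) {
  mg_term <- max(params$mg_mM - params$dntp_mM, 0)
  (params$na_mM + 120 * sqrt(mg_term)) * 1e-3
}

#' Nearest-neighbor primer melting temperature
#'
#' @param primer Character vector of primer sequences (ACGT only).
#' @param params A \code{\link{primer_params}} (reaction conditions).
#' @return Numeric vector of Tm in degC.
#' @export
primer_tm <- function(primer, params = primer_params()) {
  mon <- effective_monovalent(params)
  k <- params$oligo_nM * 1e-9
  vapply(toupper(primer), function(s) {
    n <- nchar(s)
    if (n < 2L) stopf("primer too short for nearest-neighbor Tm")
    if (grepl("[^ACGT]", s)) stopf("primer contains non-ACGT characters")
    steps <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(.nn_dh[steps]) + .init_dh[[substr(s, 1, 1)]] +
      .init_dh[[substr(s, n, n)]]
    ds <- sum(.nn_ds[steps]) + .init_ds[[substr(s, 1, 1)]] +
      .init_ds[[substr(s, n, n)]]
    kk <- k
    if (s == revcomp(s)) {  # self-complementary duplex
      ds <- ds - 1.4
    }
    ds <- ds + 0.368 * (n - 1) * log(mon)
    1000 * dh / (ds + .gas_const * log(kk)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Enumerate all valid primer candidates wholly inside [lo, hi] of a window.
# Uses prefix sums over the window for O(1) per-candidate GC, validity,
# homopolymer and nearest-neighbor thermodynamic sums.
primer_candidates <- function(window, lo, hi, params) {
  none <- data.frame(start = integer(), end = integer(), len = integer(),
                     tm = numeric(), gc = numeric(), penalty = numeric(),
                     stringsAsFactors = FALSE)
  if (hi - lo + 1L < params$len_min) return(none)
  su <- toupper(window)
  n <- nchar(su)
  ch <- strsplit(su, "", fixed = TRUE)[[1]]
  valid <- ch %in% c("A", "C", "G", "T")
  gc <- ch %in% c("G", "C")
  cs_valid <- c(0L, cumsum(valid))
  cs_gc <- c(0L, cumsum(gc))
  steps <- paste0(ch[-n], ch[-1])
  dh_step <- unname(.nn_dh[steps]); dh_step[is.na(dh_step)] <- 0
  ds_step <- unname(.nn_ds[steps]); ds_step[is.na(ds_step)] <- 0
  cs_dh <- c(0, cumsum(dh_step))
  cs_ds <- c(0, cumsum(ds_step))
  # positions starting a homopolymer hexamer
  if (n >= 6L) {
    same <- ch[-n] == ch[-1]
    run6 <- same[1:(n - 5)] & same[2:(n - 4)] & same[3:(n - 3)] &
      same[4:(n - 2)] & same[5:(n - 1)]
    cs_bad <- c(0L, cumsum(run6))
  } else {
    cs_bad <- rep(0L, n + 1L)
  }
  mon <- effective_monovalent(params)
  lk <- .gas_const * log(params$oligo_nM * 1e-9)
  cands <- list()
  for (len in params$len_min:params$len_max) {
    if (hi - lo + 1L < len) break
    s <- lo:(hi - len + 1L)
    e <- s + len - 1L
    ok <- (cs_valid[e + 1L] - cs_valid[s]) == len
    gcc <- 100 * (cs_gc[e + 1L] - cs_gc[s]) / len
    ok <- ok & gcc >= params$gc_min & gcc <= params$gc_max
    # reject a homopolymer of 6+ anywhere inside
    bad_hi <- pmax(e - 5L, s - 1L)
    ok <- ok & (cs_bad[bad_hi + 1L] - cs_bad[s]) == 0L
    if (!any(ok)) next
    s <- s[ok]; e <- e[ok]; gcc <- gcc[ok]
    dh <- cs_dh[e] - cs_dh[s] +
      unname(.init_dh[ch[s]]) + unname(.init_dh[ch[e]])
    ds <- cs_ds[e] - cs_ds[s] +
      unname(.init_ds[ch[s]]) + unname(.init_ds[ch[e]]) +
      0.368 * (len - 1) * log(mon)
    tm <- 1000 * dh / (ds + lk) - 273.15
    okt <- tm >= params$tm_min & tm <= params$tm_max
    if (!any(okt)) next
    cands[[length(cands) + 1L]] <-
      data.frame(start = s[okt], end = e[okt], len = len,
                 tm = tm[okt], gc = gcc[okt], stringsAsFactors = FALSE)
  }
  if (!length(cands)) return(none)
  out <- do.call(rbind, cands)
  # drop palindromic (self-complementary) candidates: primer-dimer prone,
  # and their duplex symmetry shifts the effective Tm
  sub <- substring(su, out$start, out$end)
  out <- out[sub != revcomp(sub), , drop = FALSE]
  if (!nrow(out)) return(none)
  out$penalty <- abs(out$tm - params$tm_opt) + 0.2 * abs(out$len - 20L)
  out[order(out$penalty, out$start, out$len), , drop = FALSE]
}

#' Design a primer pair flanking one SSR locus
#'
#' Enumerates every length/position candidate in the left and right flanks
#' of the locus within the window (primers never overlap the SSR tract),
#' filters on length, GC content, melting temperature and homopolymer
#' content, and returns the lowest-penalty pair whose product size lies in
#' the configured range. Penalty is \code{|Tm - tm_opt| + 0.2 |len - 20|}
#' per primer.
#'
#' @param window Flanking window sequence (see \code{\link{extract_flank}}).
#' @param locus_start,locus_end 1-based locus interval within the window.
#' @param params A \code{\link{primer_params}}.
#' @return On success a list with left/right primer sequences (both written
#'   5'->3', the right primer on the reverse strand), window coordinates,
#'   product size and Tm values; otherwise an object of class
#'   \code{primer_failure} carrying the failure \code{reason}.
#' @export
design_primer_pair <- function(window, locus_start, locus_end,
                               params = primer_params()) {
  fail <- function(reason) {
    structure(list(reason = reason), class = "primer_failure")
  }
  wlen <- nchar(window)
  if (locus_start < 1L || locus_end > wlen || locus_end < locus_start) {
    stopf("locus interval [%d, %d] outside window of length %d",
          locus_start, locus_end, wlen)
  }
  if (wlen < params$product_min) return(fail("window_too_short"))
  if (locus_start - 1L < params$len_min) return(fail("no_left_flank"))
  if (wlen - locus_end < params$len_min) return(fail("no_right_flank"))
  lefts <- primer_candidates(window, 1L, locus_start - 1L, params)
  if (nrow(lefts) == 0L) return(fail("no_left_candidates"))
  rights <- primer_candidates(window, locus_end + 1L, wlen, params)
  if (nrow(rights) == 0L) return(fail("no_right_candidates"))

  best <- NULL
  pick <- function(l_df, r_df) {
    bb <- NULL
    min_rp <- min(r_df$penalty)
    for (i in seq_len(nrow(l_df))) {
      lp <- l_df$penalty[i]
      if (!is.null(bb) && lp + min_rp >= bb$penalty) break
      prod <- r_df$end - l_df$start[i] + 1L
      ok <- prod >= params$product_min & prod <= params$product_max &
        r_df$start > locus_end
      if (!any(ok)) next
      j <- which(ok)[1]  # r_df is sorted by penalty
      tot <- lp + r_df$penalty[j]
      if (is.null(bb) || tot < bb$penalty) {
        bb <- list(li = i, rj = j, penalty = tot)
      }
    }
    bb
  }
  # fast path over the lowest-penalty candidates, full scan as fallback
  kl <- utils::head(lefts, 200L)
  kr <- utils::head(rights, 200L)
  sel <- pick(kl, kr)
  if (is.null(sel)) sel <- pick(lefts, rights)
  if (is.null(sel)) return(fail("no_compatible_pair"))
  l <- lefts[sel$li, ]
  r <- rights[sel$rj, ]
  su <- toupper(window)
  list(left = substr(su, l$start, l$end),
       right = revcomp(substr(su, r$start, r$end)),
       left_start = l$start, left_end = l$end,
       right_start = r$start, right_end = r$end,
       product_size = r$end - l$start + 1L,
       tm_left = l$tm, tm_right = r$tm,
       penalty = sel$penalty)
}

#' Design primer pairs for every locus in a collection
#'
#' Extracts a flanking window around each locus (so the design engine never
#' sees the full-length sequence) and attempts exactly one design per
#' locus. Failures are logged and never fatal.
#'
#' @param loci Locus data.frame from \code{\link{mine_genome}}.
#' @param seqs Named character vector of source sequences.
#' @param params A \code{\link{primer_params}}.
#' @return List with \code{pairs} (data.frame of designed pairs with
#'   parent coordinates and provenance) and \code{failures} (data.frame
#'   seq_id, start, end, reason).
#' @export
design_all <- function(loci, seqs, params = primer_params()) {
  pairs <- list()
  fails <- list()
  for (i in seq_len(nrow(loci))) {
    sid <- loci$seq_id[i]
    if (!sid %in% names(seqs)) {
      stopf("locus references unknown sequence '%s'", sid)
    }
    win <- extract_flank(seqs[[sid]], loci$start[i], loci$end[i],
                         params$flank)
    ls <- loci$start[i] - win$start + 1L
    le <- loci$end[i] - win$start + 1L
    pr <- design_primer_pair(win$sequence, ls, le, params)
    if (inherits(pr, "primer_failure")) {
      fails[[length(fails) + 1L]] <-
        data.frame(seq_id = sid, start = loci$start[i], end = loci$end[i],
                   reason = pr$reason, stringsAsFactors = FALSE)
    } else {
      pairs[[length(pairs) + 1L]] <-
        data.frame(seq_id = sid, locus_start = loci$start[i],
                   locus_end = loci$end[i], motif = loci$motif[i],
                   left_primer = pr$left, right_primer = pr$right,
                   left_start = win$start + pr$left_start - 1L,
                   right_end = win$start + pr$right_end - 1L,
                   product_size = pr$product_size,
                   tm_left = pr$tm_left, tm_right = pr$tm_right,
                   stringsAsFactors = FALSE)
    }
  }
  empty_pairs <- data.frame(seq_id = character(), locus_start = integer(),
                            locus_end = integer(), motif = character(),
                            left_primer = character(),
                            right_primer = character(),
                            left_start = integer(), right_end = integer(),
                            product_size = integer(), tm_left = numeric(),
                            tm_right = numeric(), stringsAsFactors = FALSE)
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(seq_id = character(), start = integer(),
                    end = integer(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Deduplicate primer pairs into unique markers
#'
#' Primer pairs are clustered when 100\% identical as an exact
#' (left, right) string pair; each cluster receives a serial marker ID
#' ("MK1", "MK2", ...) in order of first occurrence and keeps every source
#' locus.
#'
#' @param pairs Pair data.frame from \code{\link{design_all}}.
#' @return List of class \code{marker_set} with \code{markers} (marker_id,
#'   left_primer, right_primer, product_size, motif, n_loci) and
#'   \code{sources} (marker_id, seq_id, start, end).
#' @export
deduplicate_markers <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(list(
      markers = data.frame(marker_id = character(),
                           left_primer = character(),
                           right_primer = character(),
                           product_size = integer(), motif = character(),
                           n_loci = integer(), stringsAsFactors = FALSE),
      sources = data.frame(marker_id = character(), seq_id = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)),
      class = "marker_set"))
  }
  key <- paste(pairs$left_primer, pairs$right_primer, sep = "|")
  first <- !duplicated(key)
  ids <- stats::setNames(paste0("MK", seq_len(sum(first))), key[first])
  markers <- data.frame(marker_id = unname(ids),
                        left_primer = pairs$left_primer[first],
                        right_primer = pairs$right_primer[first],
                        product_size = pairs$product_size[first],
                        motif = pairs$motif[first],
                        n_loci = as.integer(table(key)[key[first]]),
                        stringsAsFactors = FALSE)
  sources <- data.frame(marker_id = unname(ids[key]),
                        seq_id = pairs$seq_id,
                        start = pairs$locus_start,
                        end = pairs$locus_end,
                        stringsAsFactors = FALSE)
  structure(list(markers = markers, sources = sources),
            class = "marker_set")
}

#' Write / read markers in STS tab format
#'
#' \code{write_sts} emits the NCBI STS-style table (marker ID with a
#' leading \code{>}, forward primer, reverse primer, expected product
#' size); \code{write_mk} adds the repeated motif and the source loci.
#'
#' @param markers A \code{marker_set} from
#'   \code{\link{deduplicate_markers}}, or its \code{markers} data.frame.
#' @param path Output path.
#' @return Invisibly, `path`; readers return the corresponding data.frame.
#' @export
write_sts <- function(markers, path) {
  m <- if (inherits(markers, "marker_set")) markers$markers else markers
  if (nrow(m) == 0L) {
    writeLines(paste("Marker_ID", "Left_primer_sequence",
                     "Right_primer_sequence", "Product_size", sep = "\t"),
               path)
    return(invisible(path))
  }
  out <- data.frame(Marker_ID = paste0(">", m$marker_id),
                    Left_primer_sequence = m$left_primer,
                    Right_primer_sequence = m$right_primer,
                    Product_size = m$product_size,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sts
#' @export
read_sts <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character",
                                        "character", "integer"))
  data.frame(marker_id = sub("^>", "", x$Marker_ID),
             left_primer = x$Left_primer_sequence,
             right_primer = x$Right_primer_sequence,
             product_size = x$Product_size,
             stringsAsFactors = FALSE)
}

#' @rdname write_sts
#' @export
write_mk <- function(markers, path) {
  if (!inherits(markers, "marker_set")) {
    stopf("write_mk needs a marker_set (markers + sources)")
  }
  if (nrow(markers$markers) == 0L) {
    writeLines(paste("Marker_ID", "Left_primer_sequence",
                     "Right_primer_sequence", "Product_size",
                     "Repeated_motif", "Source_loci", sep = "\t"),
               path)
    return(invisible(path))
  }
  src <- split(paste0(markers$sources$seq_id, ":",
                      markers$sources$start, "-", markers$sources$end),
               markers$sources$marker_id)
  m <- markers$markers
  out <- data.frame(Marker_ID = paste0(">", m$marker_id),
                    Left_primer_sequence = m$left_primer,
                    Right_primer_sequence = m$right_primer,
                    Product_size = m$product_size,
                    Repeated_motif = m$motif,
                    Source_loci = vapply(m$marker_id, function(id) {
                      paste(src[[id]], collapse = ";")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sts
#' @export
read_mk <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  parts <- strsplit(x$Source_loci, ";", fixed = TRUE)
  sources <- do.call(rbind, lapply(seq_along(parts), function(i) {
    m <- regmatches(parts[[i]],
                    regexec("^(.+):([0-9]+)-([0-9]+)$", parts[[i]]))
    data.frame(marker_id = sub("^>", "", x$Marker_ID[i]),
               seq_id = vapply(m, `[`, character(1), 2),
               start = as.integer(vapply(m, `[`, character(1), 3)),
               end = as.integer(vapply(m, `[`, character(1), 4)),
               stringsAsFactors = FALSE)
  }))
  markers <- data.frame(marker_id = sub("^>", "", x$Marker_ID),
                        left_primer = x$Left_primer_sequence,
                        right_primer = x$Right_primer_sequence,
                        product_size = as.integer(x$Product_size),
                        motif = x$Repeated_motif,
                        n_loci = lengths(parts),
                        stringsAsFactors = FALSE)
  structure(list(markers = markers, sources = sources),
            class = "marker_set")
}
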