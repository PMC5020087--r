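# Independent brute-force reference miner: a literal greedy left-to-right
# scan per period (the regex-engine reading of maximal tandem runs),
# followed by pairwise containment filtering. Deliberately O(n^2)-ish and
# structured nothing like the package's periodicity-block implementation.

oracle_find_ssrs <- function(sequence, config) {
  su <- toupper(sequence)
  n <- nchar(su)
  all_runs <- list()
  for (p in config$min_unit:config$max_unit) {
    minrep <- config$min_repeats[[as.character(p)]]
    q <- 1L
    while (q + p * minrep - 1L <= n) {
      found <- FALSE
      for (s in q:(n - p * minrep + 1L)) {
        unit <- substr(su, s, s + p - 1L)
        if (grepl("[^ACGT]", unit)) next
        if (!is_primitive(unit)) next
        copies <- 1L
        while (substr(su, s + copies * p, s + (copies + 1L) * p - 1L) == unit)
          copies <- copies + 1L
        if (copies < minrep) next
        all_runs[[length(all_runs) + 1L]] <- data.frame(
          start = s, end = s + copies * p - 1L, repetitions = copies,
          motif = unit, stringsAsFactors = FALSE)
        q <- s + copies * p
        found <- TRUE
        break
      }
      if (!found) break
    }
  }
  loci <- if (length(all_runs)) do.call(rbind, all_runs) else
    data.frame(start = integer(), end = integer(),
               repetitions = integer(), motif = character(),
               stringsAsFactors = FALSE)
  if (config$containment_filter && nrow(loci) > 1L) {
    len <- loci$end - loci$start + 1L
    per <- nchar(loci$motif)
    drop <- logical(nrow(loci))
    for (i in seq_len(nrow(loci))) {
      for (j in seq_len(nrow(loci))) {
        if (i == j) next
        if (loci$start[j] <= loci$start[i] && loci$end[j] >= loci$end[i] &&
            (len[j] > len[i] || (len[j] == len[i] && per[j] < per[i]))) {
          drop[i] <- TRUE
        }
      }
    }
    loci <- loci[!drop, , drop = FALSE]
  }
  loci <- loci[order(loci$start, nchar(loci$motif)), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# random test sequence with a repeat-friendly base composition
random_repeatish_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T", "A", "T"), n, replace = TRUE),
        collapse = "")
}
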