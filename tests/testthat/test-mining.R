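test_that("motif library enumerates primitive words in order", {
  expect_identical(build_motif_library(1, 1), c("A", "C", "G", "T"))

  # independent enumeration with a rotation-free primitivity check
  brute <- function(p) {
    words <- apply(do.call(expand.grid,
                           rep(list(c("A", "C", "G", "T")), p)),
                   1, paste, collapse = "")
    keep <- vapply(words, function(w) {
      for (d in seq_len(p - 1)) {
        if (p %% d == 0 &&
            paste(rep(substr(w, 1, d), p / d), collapse = "") == w) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    sort(words[keep])
  }
  lib2 <- build_motif_library(2, 2)
  expect_length(lib2, 12L)
  expect_identical(lib2, brute(2))
  lib13 <- build_motif_library(1, 3)
  expect_length(lib13, 76L)
  expect_identical(lib13, c(brute(1), brute(2), brute(3)))
  # ordered by length then lexicographically
  expect_identical(lib13, lib13[order(nchar(lib13), lib13)])
  expect_error(build_motif_library(0, 2), "min_unit")
})

test_that("find_ssrs reports maximal whole-copy runs above threshold", {
  loci <- find_ssrs(paste0("GG", strrep("TA", 6), "GG"))
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$motif, "TA")
  expect_identical(loci$repetitions, 6L)
  expect_identical(loci$end - loci$start + 1L, 12L)

  # below the 5-copy dimer threshold: nothing
  expect_identical(nrow(find_ssrs(paste0("GG", strrep("TA", 4), "GG"))), 0L)

  # 46 bp GT tract: 23 repetitions
  loci2 <- find_ssrs(paste0("CCC", strrep("GT", 23), "ACC"))
  expect_identical(loci2$repetitions, 23L)
  expect_identical(loci2$end - loci2$start + 1L, 46L)

  # case-insensitive; Ns never match
  expect_identical(find_ssrs(paste0("nn", strrep("ta", 6), "NN"))$motif, "TA")
  expect_identical(nrow(find_ssrs(strrep("N", 100))), 0L)
  expect_identical(nrow(find_ssrs("")), 0L)
})

test_that("mined loci satisfy the locus invariants", {
  set.seed(21)
  cfg <- mining_config(min_repeats = 4)
  for (i in 1:10) {
    s <- random_repeatish_seq(4000)
    loci <- find_ssrs(s, cfg)
    if (nrow(loci) == 0) next
    expect_true(all(loci$end - loci$start + 1L ==
                      loci$repetitions * nchar(loci$motif)))
    expect_true(all(is_primitive(loci$motif)))
    for (j in seq_len(nrow(loci))) {
      expect_identical(toupper(substr(s, loci$start[j], loci$end[j])),
                       strrep(loci$motif[j], loci$repetitions[j]))
    }
    # same-period runs never overlap
    for (p in unique(nchar(loci$motif))) {
      lp <- loci[nchar(loci$motif) == p, ]
      if (nrow(lp) > 1) {
        expect_true(all(lp$start[-1] > lp$end[-nrow(lp)]))
      }
    }
  }
})

test_that("miner matches the brute-force greedy oracle exactly", {
  set.seed(31)
  cfgs <- list(mining_config(min_repeats = 4),
               mining_config(min_unit = 1, max_unit = 6,
                             min_repeats = c("1" = 12)),
               mining_config(min_repeats = 3, containment_filter = FALSE))
  for (i in 1:12) {
    s <- random_repeatish_seq(2500)
    # salt with planted repeats and ambiguity codes
    s <- paste0(substr(s, 1, 400), strrep("AT", 7), substr(s, 401, 900),
                strrep("CAG", 5), "NN", substring(s, 901))
    for (cfg in cfgs) {
      got <- find_ssrs(s, cfg)
      rownames(got) <- NULL
      expect_identical(got, oracle_find_ssrs(s, cfg))
    }
  }
})

test_that("reverse-complement mining mirrors planted fixtures", {
  g <- standard_fixture(seed = 13)
  s <- g$seqs[[1]]
  L <- nchar(s)
  fwd <- find_ssrs(s)
  rev <- find_ssrs(revcomp(s))
  expect_identical(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                         motif = rev$motif, stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$start), ]
  # the leftmost-greedy phase rule anchors a run at the left edge of its
  # periodic region in both orientations, so mirrored coordinates agree
  # up to a sub-period shift when the region has partial trailing copies
  p <- nchar(fwd$motif)
  expect_true(all(abs(mirrored$start - fwd$start) < p))
  expect_true(all(abs(mirrored$end - fwd$end) < p))
  expect_identical(mirrored$end - mirrored$start, fwd$end - fwd$start)
  # motifs are rotation-equivalent to the reverse complement
  for (j in seq_len(nrow(fwd))) {
    expect_true(revcomp(mirrored$motif[j]) %in%
                  ssrforge:::word_rotations(fwd$motif[j]))
  }
})

test_that("reverse-complement mining preserves run multiset on random sequence", {
  set.seed(41)
  for (i in 1:5) {
    s <- random_repeatish_seq(5000)
    fwd <- find_ssrs(s, mining_config(min_repeats = 4))
    rev <- find_ssrs(revcomp(s), mining_config(min_repeats = 4))
    expect_identical(nrow(fwd), nrow(rev))
    key <- function(x) sort(paste(nchar(x$motif), x$repetitions))
    expect_identical(key(fwd), key(rev))
  }
})

test_that("chunk-split pieces of one run merge back into a single locus", {
  # duplicate loci from overlapping chunks collapse
  runs <- data.frame(start = c(100L, 100L), end = c(121L, 121L),
                     motif = c("GT", "GT"), stringsAsFactors = FALSE)
  s <- paste0(strrep("C", 99), strrep("GT", 11), strrep("C", 300))
  merged <- merge_chunk_loci(runs, s)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$repetitions, 11L)

  # left piece (GT)x11 + in-phase right piece (TG)x14 -> one run
  tract <- strrep("GT", 25)
  s2 <- paste0(strrep("C", 99), tract, strrep("A", 200))
  pieces <- data.frame(start = c(100L, 121L), end = c(121L, 148L),
                       motif = c("GT", "TG"), stringsAsFactors = FALSE)
  m2 <- merge_chunk_loci(pieces, s2)
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$start, 100L)
  expect_identical(m2$repetitions, 25L)
  expect_identical(m2$motif, "GT")

  # two same-motif runs separated by one non-repeat base stay separate
  s3 <- paste0(strrep("C", 99), strrep("GT", 6), "A", strrep("GT", 6),
               strrep("C", 100))
  pieces3 <- data.frame(start = c(100L, 113L), end = c(111L, 124L),
                        motif = c("GT", "GT"), stringsAsFactors = FALSE)
  expect_identical(nrow(merge_chunk_loci(pieces3, s3)), 2L)
})

test_that("chunked and unchunked mining are identical", {
  # boundary-spanning tract wider than the overlap
  plants <- data.frame(motif = c("GT", "TA", "AAG"),
                       copies = c(30L, 8L, 6L),
                       start = c(4960L, 2000L, 8000L))
  g <- generate_genome(plants, c(s1 = 12000L), seed = 3)
  small <- mine_genome(g$seqs, mining_config(chunk_size = 5000,
                                             overlap = 20))$loci
  big <- mine_genome(g$seqs)$loci
  expect_identical(small, big)
  expect_true(any(small$start < 5000 & small$end > 5000))

  # random sequence, awkward chunk size
  set.seed(91)
  seqs <- c(chr1 = random_repeatish_seq(60000))
  a <- mine_genome(seqs, mining_config(chunk_size = 7003, overlap = 20,
                                       min_repeats = 4))$loci
  b <- mine_genome(seqs, mining_config(min_repeats = 4))$loci
  expect_identical(a, b)
})

test_that("mine_genome recovers planted fixtures and writes .ssr/.sat1", {
  plants2 <- data.frame(
    motif = rep(c("TA", "AAG", "GT", "ATC", "AC"), 2),
    copies = rep(c(6L, 5L, 7L, 6L, 8L), 2),
    seq_id = rep(c("c1", "c2"), each = 5))
  g <- generate_genome(plants2, c(c1 = 30000L, c2 = 30000L), seed = 17)
  res <- mine_genome(g$seqs)
  expect_identical(res$loci[, c("seq_id", "start", "end", "motif")],
                   g$truth[, c("seq_id", "start", "end", "motif")])
  expect_identical(res$loci$repetitions, g$truth$copies)
  expect_identical(res$summary$n_sequences, 2L)
  expect_identical(res$summary$total_length, 60000L)
  expect_identical(res$summary$n_loci, 10L)

  p <- withr::local_tempfile(fileext = ".ssr")
  write_ssr(res$loci, p)
  header <- readLines(p, n = 1)
  expect_identical(header,
                   "Name\tSeq_Len\tStartPos\tEndPos\tRepetitions\tMotif")
  expect_true(startsWith(readLines(p)[2], ">"))
  expect_identical(read_ssr(p), res$loci)

  p1 <- withr::local_tempfile(fileext = ".sat1")
  write_sat1(res$summary, p1)
  expect_match(readLines(p1)[2], "60000")
})

test_that("highlighted FASTA uppercases exactly the SSR tracts", {
  g <- standard_fixture()
  loci <- mine_genome(g$seqs)$loci
  p <- withr::local_tempfile(fileext = ".fa")
  write_highlight_fasta(g$seqs, loci, p)
  hl <- read_fasta(p)[[1]]
  upper <- gregexpr("[A-Z]+", hl)[[1]]
  expect_identical(as.integer(upper), loci$start)
  expect_identical(attr(upper, "match.length"), loci$end - loci$start + 1L)
})
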