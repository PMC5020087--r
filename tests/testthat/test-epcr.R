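test_that("find_primer_sites locates planted sites on both strands", {
  primer <- "GATTACAGATTACAGATT"
  set.seed(67)
  bg <- random_repeatish_seq(2000)
  s <- paste0(substr(bg, 1, 500), primer, substr(bg, 501, 1500),
              revcomp(primer), substring(bg, 1501))
  hits <- find_primer_sites(s, primer)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_identical(fwd$position, 501L)
  expect_identical(rev$position, 501L + nchar(primer) + 1000L)

  # mismatch budget
  mut <- s
  substr(mut, 505, 505) <- "C"  # internal mismatch in fwd site
  expect_identical(nrow(find_primer_sites(mut, primer)[
    find_primer_sites(mut, primer)$strand == "+", , drop = FALSE]), 0L)
  relaxed <- epcr_params(max_mismatch = 1)
  h1 <- find_primer_sites(mut, primer, relaxed)
  expect_identical(h1$position[h1$strand == "+"], 501L)
  expect_identical(h1$mismatches[h1$strand == "+"], 1L)

  # a mismatch in the exact 3' terminal bases disqualifies even in budget
  mut3 <- s
  substr(mut3, 518, 518) <- "C"  # last base of the fwd site
  h3 <- find_primer_sites(mut3, primer, relaxed)
  expect_identical(nrow(h3[h3$strand == "+", ]), 0L)
})

test_that("find_primer_sites agrees with a sliding-window oracle", {
  set.seed(71)
  params <- epcr_params(max_mismatch = 1)
  for (rep in 1:3) {
    s <- random_repeatish_seq(5000)
    # primer taken from the template, replanted with one mismatch and as
    # a reverse-complement copy, so each strand has hits to agree on
    primer <- toupper(substr(s, 1000, 1017))
    near <- primer
    substr(near, 9, 9) <- setdiff(c("A", "C"), substr(near, 9, 9))[1]
    s <- paste0(s, near, revcomp(primer), random_repeatish_seq(50))
    got <- find_primer_sites(s, primer, params)
    # brute force: compare every window against primer and its RC
    oracle <- list()
    pl <- nchar(primer)
    pv <- strsplit(toupper(primer), "")[[1]]
    rv <- strsplit(revcomp(toupper(primer)), "")[[1]]
    sv <- strsplit(toupper(s), "")[[1]]
    for (i in 1:(nchar(s) - pl + 1)) {
      win <- sv[i:(i + pl - 1)]
      mmf <- sum(win != pv)
      # forward: primer 3' end = last 3 bases
      if (mmf <= 1 && all(win[(pl - 2):pl] == pv[(pl - 2):pl])) {
        oracle[[length(oracle) + 1]] <-
          data.frame(position = i, strand = "+", mismatches = mmf)
      }
      mmr <- sum(win != rv)
      # reverse: primer 3' end maps to the window start
      if (mmr <= 1 && all(win[1:3] == rv[1:3])) {
        oracle[[length(oracle) + 1]] <-
          data.frame(position = i, strand = "-", mismatches = mmr)
      }
    }
    oracle <- do.call(rbind, oracle)
    expect_gt(nrow(oracle), 1L)
    oracle <- oracle[order(oracle$position, oracle$strand), ]
    oracle$strand <- as.character(oracle$strand)
    oracle$mismatches <- as.integer(oracle$mismatches)
    rownames(oracle) <- NULL
    rownames(got) <- NULL
    expect_identical(got, oracle)
  }
})

test_that("markers re-map to their source with the declared size", {
  g <- standard_fixture(seed = 73)
  loci <- mine_genome(g$seqs)$loci
  mk <- deduplicate_markers(design_all(loci, g$seqs)$pairs)
  amps <- epcr(mk, g$seqs)
  # design -> mapping closure: every marker amplifies its declared size
  # at a source locus
  expect_setequal(unique(amps$marker_id), mk$markers$marker_id)
  m <- merge(amps, mk$markers, by = "marker_id")
  expect_true(all(tapply(m$size == m$product_size, m$marker_id, any)))
  src <- merge(amps, mk$sources, by = c("marker_id", "seq_id"))
  expect_true(all(src$start.x <= src$start.y & src$end.x >= src$end.y))
})

test_that("allele sizes track planted indels and deletions produce NA", {
  g <- standard_fixture(seed = 79)
  loci <- mine_genome(g$seqs)$loci
  mk <- deduplicate_markers(design_all(loci, g$seqs)$pairs)
  # variant 1: +2 copies of the first (dimer) tract -> +4 bp allele
  deltas <- rep(0L, nrow(g$truth))
  deltas[1] <- 2L
  v1 <- mutate_alleles(g$seqs, g$truth, deltas)
  names(v1$seqs) <- "variant1"
  # variant 2: delete the first tract entirely
  deltas2 <- rep(0L, nrow(g$truth))
  deltas2[1] <- -g$truth$copies[1]
  v2 <- mutate_alleles(g$seqs, g$truth, deltas2)
  names(v2$seqs) <- "variant2"

  targets <- c(g$seqs, v1$seqs, v2$seqs)
  amps <- epcr(mk, targets)
  score <- score_polymorphism(amps, mk, targets)

  p <- nchar(g$truth$motif[1])
  affected <- mk$sources$marker_id[mk$sources$start == g$truth$start[1]]
  base <- as.integer(score$matrix[score$matrix$marker_id == affected,
                                  "seq1"])
  expect_identical(as.integer(score$matrix[
    score$matrix$marker_id == affected, "variant1"]), base + 2L * p)
  # tract deleted below detectability: primers still flank a shorter gap,
  # so either a shifted allele or (if out of bounds) NA; it must differ
  cell2 <- score$matrix[score$matrix$marker_id == affected, "variant2"]
  expect_false(identical(cell2, as.character(base)))
  expect_true(score$polymorphic[[affected]])
  # unaffected markers are monomorphic across all targets
  others <- setdiff(mk$markers$marker_id, affected)
  expect_false(any(score$polymorphic[others]))
})

test_that("polymorphism scoring follows the allele-matrix conventions", {
  markers <- data.frame(marker_id = c("NIX1", "NIX101398", "NIXNONE"),
                        left_primer = "A", right_primer = "A",
                        product_size = c(338L, 202L, 100L),
                        stringsAsFactors = FALSE)
  seqs <- c(gA = "x", gB = "x", gC = "x")
  amps <- data.frame(
    marker_id = c("NIX1", "NIX1", "NIX101398", "NIX101398", "NIX101398"),
    seq_id = c("gA", "gB", "gA", "gC", "gC"),
    start = 1L, end = 1L,
    size = c(338L, 338L, 202L, 200L, 204L),
    strand = "+", mm_left = 0L, mm_right = 0L, stringsAsFactors = FALSE)
  sc <- score_polymorphism(amps, markers, seqs)
  row1 <- sc$matrix[sc$matrix$marker_id == "NIX1", ]
  expect_identical(unlist(row1[c("gA", "gB", "gC")], use.names = FALSE),
                   c("338", "338", "NA"))
  expect_false(sc$polymorphic[["NIX1"]])
  row2 <- sc$matrix[sc$matrix$marker_id == "NIX101398", ]
  # multi-band cell: ascending sizes joined with "+"
  expect_identical(row2[["gC"]], "200+204")
  expect_true(sc$polymorphic[["NIX101398"]])
  # no amplification anywhere: all NA, not polymorphic
  row3 <- sc$matrix[sc$matrix$marker_id == "NIXNONE", ]
  expect_true(all(unlist(row3[c("gA", "gB", "gC")]) == "NA"))
  expect_false(sc$polymorphic[["NIXNONE"]])
})

test_that("mapping summary computes the five .sat4 quantities", {
  markers <- data.frame(marker_id = c("M1", "M2", "M3"),
                        left_primer = "A", right_primer = "A",
                        product_size = 100L, stringsAsFactors = FALSE)
  seqs <- c(s1 = "x", s2 = "x", s3 = "x")
  amps <- data.frame(marker_id = c("M1", "M1", "M1", "M2", "M2"),
                     seq_id = c("s1", "s1", "s2", "s1", "s2"),
                     start = 1L, end = 1L,
                     size = c(100L, 104L, 100L, 90L, 90L),
                     strand = "+", mm_left = 0L, mm_right = 0L,
                     stringsAsFactors = FALSE)
  sm <- summarize_mapping(amps, markers, seqs)
  expect_identical(sm$n_markers, 3L)
  expect_identical(sm$n_markers_mapped, 2L)
  expect_identical(sm$n_sequences_with_marker, 2L)
  expect_identical(sm$total_amplicons, 5L)
  expect_equal(sm$mean_amplicons_per_mapped_marker, 2.5)
  expect_identical(as.integer(sm$allele_count_distribution[c("1", "2")]),
                   c(1L, 1L))

  expect_message(sm0 <- summarize_mapping(amps[0, ], markers, seqs),
                 "no markers mapped")
  expect_identical(sm0$n_markers_mapped, 0L)
  expect_identical(sm0$mean_amplicons_per_mapped_marker, 0)
})

test_that("e-PCR is strand-symmetric", {
  g <- standard_fixture(seed = 83)
  loci <- mine_genome(g$seqs)$loci
  mk <- deduplicate_markers(design_all(loci, g$seqs)$pairs)
  fwd <- epcr(mk, g$seqs)
  rcseqs <- vapply(g$seqs, revcomp, character(1))
  rev <- epcr(mk, rcseqs)
  expect_identical(nrow(fwd), nrow(rev))
  expect_identical(sort(fwd$size), sort(rev$size))
  L <- nchar(g$seqs[[1]])
  expect_setequal(L - rev$end + 1L, fwd$start)
  expect_setequal(L - rev$start + 1L, fwd$end)
})

test_that("e-mapping result files are written consistently", {
  g <- standard_fixture(seed = 89)
  loci <- mine_genome(g$seqs)$loci
  mk <- deduplicate_markers(design_all(loci, g$seqs)$pairs)
  amps <- epcr(mk, g$seqs)
  sc <- score_polymorphism(amps, mk, g$seqs)
  sm <- summarize_mapping(amps, mk, g$seqs)
  d <- withr::local_tempdir()
  write_amp(amps, file.path(d, "o.amp"))
  expect_identical(read_amp(file.path(d, "o.amp")), amps)
  write_frg(sc, file.path(d, "o.frg"))
  frg <- readLines(file.path(d, "o.frg"))
  expect_identical(length(frg), nrow(mk$markers) + 1L)
  write_emap(amps, g$seqs, file.path(d, "o.emap"))
  emap <- readLines(file.path(d, "o.emap"))
  expect_match(emap[1], "^seq1\t")
  write_sat4(sm, file.path(d, "o.sat4"))
  expect_match(readLines(file.path(d, "o.sat4"))[1], "Total_markers")
})
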