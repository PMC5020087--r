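# Shared fixtures built in code.

tmp_file <- function(lines, ext = ".fa") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# The published example locus table: 11 rows of sequence ID, sequence
# length, 1-based start/end, repetition count and motif.
example_loci <- function() {
  data.frame(
    seq_id = c(rep("scaffold_1", 4), rep("scaffold_9", 7)),
    seq_len = c(rep(42145699L, 4), rep(58970518L, 7)),
    start = c(2693L, 3225L, 10151L, 30866L, 58865464L, 58898017L,
              58944715L, 58953059L, 58953641L, 58968425L, 58968954L),
    end = c(2704L, 3236L, 10160L, 30875L, 58865478L, 58898062L,
            58944726L, 58953070L, 58953654L, 58968434L, 58968965L),
    repetitions = c(6L, 6L, 5L, 5L, 5L, 23L, 6L, 6L, 7L, 5L, 6L),
    motif = c("TA", "AG", "TA", "TA", "CAC", "GT", "GT", "GT", "TG",
              "TA", "AG"),
    stringsAsFactors = FALSE)
}

# The published example marker table.
example_markers <- function() {
  data.frame(
    marker_id = c("MK1", "MK2", "MK3"),
    left_primer = c("GTCATTTGCCGACCAAACAT", "TGATGCACCCTTTGTGGTTA",
                    "TGGCTAGATTCAAATCGTTCAG"),
    right_primer = c("CGGGAGAGGTAAAGGGAAGA", "CAAAATTGGCATCAAACACG",
                     "CTAAGCACTACCCCGAGCAT"),
    product_size = c(338L, 149L, 214L),
    stringsAsFactors = FALSE)
}

# a small planted-genome fixture shared by design/epcr/pipeline tests
standard_fixture <- function(seed = 7L) {
  plants <- data.frame(motif = c("TA", "AAG", "GT", "ACGT", "CAC"),
                       copies = c(6L, 5L, 8L, 5L, 5L))
  generate_genome(plants, c(seq1 = 20000L), seed = seed)
}
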