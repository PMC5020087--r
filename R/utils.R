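# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. IUPAC
#' ambiguity codes are complemented; case is preserved.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""),
         character(1))
}

# left-rotate a word by k characters: rotate("ACG", 1) -> "CGA"
rotate_word <- function(word, k) {
  n <- nchar(word)
  k <- k %% n
  if (k == 0L) return(word)
  paste0(substr(word, k + 1L, n), substr(word, 1L, k))
}

# all distinct rotations of a word
word_rotations <- function(word) {
  unique(vapply(seq_len(nchar(word)) - 1L, rotate_word, character(1),
                word = word))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not itself a whole-number repetition of a
#' shorter word (so \code{ATAT} is not primitive, \code{AT} is). Only
#' primitive motifs enter the motif library, which guarantees each tandem
#' run is attributed once, to its minimal period.
#'
#' @param word Character vector of motifs.
#' @return Logical vector.
#' @export
is_primitive <- function(word) {
  vapply(word, function(w) {
    n <- nchar(w)
    if (n <= 1L) return(TRUE)
    for (d in seq_len(n %/% 2)) {
      if (n %% d == 0L &&
          strrep(substr(w, 1L, d), n %/% d) == w) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# empty locus table with the canonical column set
empty_loci <- function() {
  data.frame(seq_id = character(), seq_len = integer(),
             start = integer(), end = integer(),
             repetitions = integer(), motif = character(),
             stringsAsFactors = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
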