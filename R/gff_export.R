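# GFF3 export of SSR loci and markers for genome browsers.
#
# Feature lines are formatted directly (deterministic output, no
# timestamps); rtracklayer's GFF3 importer serves as the syntax checker
# and round-trip reader in the test suite.

# percent-encode a GFF3 attribute value
gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

write_gff3 <- function(rows, path, seqlens = NULL) {
  pragmas <- "##gff-version 3"
  if (!is.null(seqlens) && length(seqlens)) {
    pragmas <- c(pragmas,
                 sprintf("##sequence-region %s 1 %d", names(seqlens),
                         as.integer(seqlens)))
  }
  writeLines(c(pragmas, rows), path)
  invisible(path)
}

#' Export SSR loci as a GFF3 feature file
#'
#' One feature of Sequence Ontology type "microsatellite" per locus,
#' strand "+", with the motif and repetition count carried as attributes.
#' The file begins with the \code{##gff-version 3} pragma and, when
#' sequence lengths are known, \code{##sequence-region} pragmas.
#'
#' @param loci Locus data.frame from \code{\link{mine_genome}} (the
#'   seq_len column, if present, supplies the sequence-region pragmas).
#' @param path Output path.
#' @param source Source tag for column 2.
#' @return Invisibly, `path`.
#' @export
loci_to_gff3 <- function(loci, path, source = "ssrforge") {
  seqlens <- NULL
  if (nrow(loci) && "seq_len" %in% names(loci)) {
    u <- unique(loci[, c("seq_id", "seq_len")])
    seqlens <- stats::setNames(u$seq_len, u$seq_id)
  }
  rows <- character(0)
  if (nrow(loci)) {
    attrs <- sprintf("ID=SSR%d;Name=(%s)x%d;motif=%s;repetitions=%d",
                     seq_len(nrow(loci)), gff3_encode(loci$motif),
                     loci$repetitions, gff3_encode(loci$motif),
                     loci$repetitions)
    rows <- paste(loci$seq_id, source, "microsatellite", loci$start,
                  loci$end, ".", "+", ".", attrs, sep = "\t")
  }
  write_gff3(rows, path, seqlens)
}

#' Export markers as a GFF3 feature file
#'
#' One feature of type "STS" per marker placement, spanning the predicted
#' amplicon on the source genome, with the marker ID, product size and
#' primer sequences as attributes. Duplicated markers (several source
#' placements) yield one row per placement sharing the marker Name; a
#' marker with no placement is skipped with a warning.
#'
#' @param markers A \code{marker_set} or markers data.frame.
#' @param amplicons Amplicons of the markers on their source genome
#'   (\code{\link{epcr}} output).
#' @param path Output path.
#' @param source Source tag for column 2.
#' @return Invisibly, `path`.
#' @export
markers_to_gff3 <- function(markers, amplicons, path,
                            source = "ssrforge") {
  m <- if (inherits(markers, "marker_set")) markers$markers else markers
  placed <- amplicons[amplicons$marker_id %in% m$marker_id, , drop = FALSE]
  missing <- setdiff(m$marker_id, placed$marker_id)
  if (length(missing)) {
    warning(sprintf("%d marker(s) without source placement skipped: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
  }
  rows <- character(0)
  if (nrow(placed)) {
    idx <- match(placed$marker_id, m$marker_id)
    attrs <- sprintf(
      "ID=%s.%d;Name=%s;product_size=%d;left_primer=%s;right_primer=%s",
      gff3_encode(placed$marker_id), seq_len(nrow(placed)),
      gff3_encode(placed$marker_id), placed$size,
      m$left_primer[idx], m$right_primer[idx])
    rows <- paste(placed$seq_id, source, "STS", placed$start, placed$end,
                  ".", placed$strand, ".", attrs, sep = "\t")
  }
  write_gff3(rows, path)
}

#' Validate GFF3 file structure
#'
#' Structural syntax check: version pragma, 9 tab-separated columns,
#' numeric 1-based coordinates with start <= end, and parseability by the
#' rtracklayer GFF3 importer.
#'
#' @param path Path to a GFF3 file.
#' @return TRUE (invisibly) or an error describing the first violation.
#' @export
validate_gff3 <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^##gff-version 3", lines[1])) {
    stopf("missing ##gff-version 3 pragma")
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != 9L)) {
      stopf("GFF3 feature lines must have 9 tab-separated columns")
    }
    starts <- as.integer(vapply(fields, `[`, character(1), 4))
    ends <- as.integer(vapply(fields, `[`, character(1), 5))
    if (anyNA(starts) || anyNA(ends) || any(starts < 1L) ||
        any(starts > ends)) {
      stopf("invalid GFF3 coordinates")
    }
    rtracklayer::import(path, format = "gff3")
  }
  invisible(TRUE)
}
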