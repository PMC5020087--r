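# Statistical graphics for the locus classifications: unit-length
# distribution (bar + pie), motif composition (ranked bars), SSR length
# distribution (bars over the observed length range), and SSR count versus
# sequence length (scatter with a least-squares fit). Rendering is
# deterministic (cairo devices, fixed dimensions, no timestamps) so output
# files can be compared byte for byte.

#' Plot configuration
#'
#' @param outdir Output directory (created if missing).
#' @param formats Image formats, any of "png" and "svg".
#' @param width,height Device size in inches.
#' @param dpi Raster resolution for PNG.
#' @param palette Base palette name used for fills.
#' @return List of class \code{plot_config}.
#' @export
plot_config <- function(outdir = ".", formats = c("png", "svg"),
                        width = 7, height = 5, dpi = 96,
                        palette = "Set 2") {
  formats <- match.arg(formats, c("png", "svg"), several.ok = TRUE)
  structure(list(outdir = outdir, formats = formats, width = width,
                 height = height, dpi = dpi, palette = palette),
            class = "plot_config")
}

# open device(s), draw, close; returns written file paths
render_plot <- function(name, config, draw) {
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  paths <- character(0)
  for (fmt in config$formats) {
    path <- file.path(config$outdir, paste0(name, ".", fmt))
    if (fmt == "png") {
      grDevices::png(path, width = config$width * config$dpi,
                     height = config$height * config$dpi,
                     res = config$dpi, type = "cairo")
    } else {
      grDevices::svg(path, width = config$width, height = config$height)
    }
    tryCatch(draw(), finally = grDevices::dev.off())
    paths <- c(paths, path)
  }
  paths
}

plot_fill <- function(config, n) {
  grDevices::hcl.colors(max(n, 3L), palette = config$palette)[seq_len(n)]
}

#' Plot the motif unit-length distribution
#'
#' Emits a bar chart and a pie chart of SSR counts per motif unit length.
#'
#' @param table Unit-length table from \code{\link{classify_unit_length}}.
#' @param config A \code{\link{plot_config}}.
#' @return Invisibly, the written file paths.
#' @export
plot_unit_length <- function(table, config = plot_config()) {
  if (nrow(table) == 0L) stopf("cannot plot an empty unit-length table")
  tab <- table[order(table$unit_length), , drop = FALSE]
  cols <- plot_fill(config, nrow(tab))
  p1 <- render_plot("unit_length_bar", config, function() {
    graphics::barplot(tab$count, names.arg = paste0(tab$unit_length, "-mer"),
                      col = cols, border = NA,
                      xlab = "Motif unit length",
                      ylab = "SSR count",
                      main = "SSR motif unit length distribution")
  })
  p2 <- render_plot("unit_length_pie", config, function() {
    graphics::pie(tab$count,
                  labels = sprintf("%d-mer (%.2f%%)", tab$unit_length,
                                   tab$percentage),
                  col = cols, clockwise = TRUE,
                  main = "SSR motif unit length distribution")
  })
  invisible(c(p1, p2))
}

#' Plot the motif composition distribution
#'
#' Bar chart of SSR counts per motif, ranked in descending order.
#'
#' @param table Motif table from \code{\link{classify_motif}}.
#' @param config A \code{\link{plot_config}}.
#' @param top Plot at most this many top-ranked motifs.
#' @return Invisibly, the written file paths.
#' @export
plot_motif_nucleotides <- function(table, config = plot_config(),
                                   top = 30L) {
  if (nrow(table) == 0L) stopf("cannot plot an empty motif table")
  tab <- utils::head(table[order(-table$count, table$motif), , drop = FALSE],
                     top)
  invisible(render_plot("motif_composition", config, function() {
    graphics::barplot(tab$count, names.arg = tab$motif,
                      col = plot_fill(config, nrow(tab)), border = NA,
                      las = 2, cex.names = 0.7,
                      xlab = "Motif", ylab = "SSR count",
                      main = "SSR motif composition")
  }))
}

#' Plot the SSR length distribution
#'
#' Bar chart of SSR counts over the observed tract-length range.
#'
#' @param table Length table from \code{\link{length_distribution}}.
#' @param config A \code{\link{plot_config}}.
#' @return Invisibly, the written file paths.
#' @export
plot_length_distribution <- function(table, config = plot_config()) {
  if (nrow(table) == 0L) stopf("cannot plot an empty length table")
  rng <- range(table$ssr_length)
  lens <- rng[1]:rng[2]
  counts <- table$count[match(lens, table$ssr_length)]
  counts[is.na(counts)] <- 0L
  invisible(render_plot("ssr_length", config, function() {
    graphics::barplot(counts, names.arg = lens,
                      col = plot_fill(config, 1L), border = NA, las = 2,
                      cex.names = 0.7,
                      xlab = "SSR length (bp)", ylab = "SSR count",
                      main = "SSR length distribution")
  }))
}

#' Plot SSR count versus sequence length
#'
#' Scatter plot with one point per sequence and a least-squares fit; the
#' SSR count over whole chromosomes is expected to scale linearly with
#' chromosome length.
#'
#' @param table Frequency table from \code{\link{per_sequence_frequency}}.
#' @param config A \code{\link{plot_config}}.
#' @return Invisibly, a list with the written `paths` and the fitted
#'   `slope` (SSR per bp).
#' @export
plot_count_vs_length <- function(table, config = plot_config()) {
  if (nrow(table) < 2L) {
    stopf("count-vs-length plot needs at least 2 sequences")
  }
  fit <- stats::lm(count ~ length, data = table)
  paths <- render_plot("count_vs_length", config, function() {
    graphics::plot(table$length, table$count, pch = 19,
                   col = plot_fill(config, 1L),
                   xlab = "Sequence length (bp)", ylab = "SSR count",
                   main = "SSR count vs. sequence length")
    graphics::abline(fit, lty = 2)
  })
  invisible(list(paths = paths, slope = unname(stats::coef(fit)[2])))
}

#' Render all statistical plots
#'
#' @param stats An \code{\link{ssr_stats}} object.
#' @param config A \code{\link{plot_config}}.
#' @return Invisibly, all written file paths.
#' @export
plot_all_stats <- function(stats, config = plot_config()) {
  paths <- c(plot_unit_length(stats$unit_length, config),
             plot_motif_nucleotides(stats$motif, config),
             plot_length_distribution(stats$ssr_length, config))
  if (nrow(stats$frequency) >= 2L) {
    paths <- c(paths, plot_count_vs_length(stats$frequency, config)$paths)
  }
  invisible(paths)
}
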