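# One-step pipeline driver: mine -> stats -> plot -> design -> emap ->
# export, driven by a flat key=value settings file. Any contiguous subset
# of stages can run; a stage whose upstream artifact is missing fails with
# an error naming the stage.

#' Read a flat key=value settings file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' are ignored. Values are returned as strings.
#'
#' @param path Path to the settings file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("settings file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stopf("malformed settings line: %s", lines[bad][1])
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

# parse "1=12,2=5" or a single number into a named min_repeats spec
parse_min_repeats <- function(x) {
  if (is.null(x)) return(5L)
  x <- as.character(x)
  if (!grepl("=", x)) return(as.integer(x))
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(as.integer(vapply(kv, `[`, character(1), 2)),
                  trimws(vapply(kv, `[`, character(1), 1)))
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_num <- function(config, key, default) {
  as.numeric(cfg_get(config, key, default))
}

#' Run the SSR analysis pipeline
#'
#' Executes the requested stages in order (mine, stats, plot, design,
#' emap, export) against a settings list or file. Recognised settings:
#' \describe{
#'   \item{fasta}{input FASTA (required for mine/design/export)}
#'   \item{out_prefix}{path prefix for all outputs (default "ssrforge_out")}
#'   \item{stages}{comma list, default "mine,stats,plot,design,emap,export"}
#'   \item{min_unit, max_unit, min_repeats, chunk_size, overlap}{mining
#'     parameters; min_repeats accepts "5" or "1=12,2=5,..."}
#'   \item{flank, product_min, product_max, tm}{primer design parameters}
#'   \item{targets_fasta}{FASTA screened by e-PCR (default: the input)}
#'   \item{mismatch, margin}{e-PCR parameters}
#'   \item{freq_scale}{frequency scale constant (default 1e6)}
#'   \item{plot_formats}{comma list of png,svg (default both)}
#'   \item{seed}{recorded in the run manifest}
#' }
#' Later stages reuse on-disk artifacts from earlier runs (e.g. a
#' stats-only run needs an existing `.ssr` next to the prefix).
#'
#' @param config Settings file path or named list.
#' @return Invisibly, a named list of written output files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  stages <- strsplit(cfg_get(config, "stages",
                             "mine,stats,plot,design,emap,export"),
                     ",", fixed = TRUE)[[1]]
  stages <- trimws(stages)
  known <- c("mine", "stats", "plot", "design", "emap", "export")
  if (any(!stages %in% known)) {
    stopf("unknown stage(s): %s", paste(setdiff(stages, known),
                                        collapse = ", "))
  }
  stages <- known[known %in% stages]
  prefix <- cfg_get(config, "out_prefix", "ssrforge_out")
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- list(ssr = paste0(prefix, ".ssr"),
                sat1 = paste0(prefix, ".sat1"),
                sat2 = paste0(prefix, ".sat2"),
                mk = paste0(prefix, ".mk"),
                sts = paste0(prefix, ".sts"),
                amp = paste0(prefix, ".amp"),
                frg = paste0(prefix, ".frg"),
                emap = paste0(prefix, ".emap"),
                sat4 = paste0(prefix, ".sat4"),
                gff3 = paste0(prefix, ".gff3"),
                manifest = paste0(prefix, ".manifest"))
  written <- character(0)
  logmsg <- function(fmt, ...) {
    message(sprintf(paste0("[ssrforge] ", fmt), ...))
  }
  need <- function(path, stage, producer) {
    if (!file.exists(path)) {
      stopf("stage '%s' requires %s (run the '%s' stage first)",
            stage, path, producer)
    }
    path
  }
  load_fasta <- function(stage) {
    f <- cfg_get(config, "fasta")
    if (is.null(f)) stopf("stage '%s' requires the 'fasta' setting", stage)
    read_fasta(f)
  }
  mcfg <- mining_config(
    min_unit = cfg_num(config, "min_unit", 2),
    max_unit = cfg_num(config, "max_unit", 6),
    min_repeats = parse_min_repeats(cfg_get(config, "min_repeats")),
    chunk_size = cfg_num(config, "chunk_size", 2e6),
    overlap = cfg_num(config, "overlap", 20))

  if ("mine" %in% stages) {
    seqs <- load_fasta("mine")
    logmsg("mining %d sequence(s), %d bp total", length(seqs),
           sum(nchar(seqs)))
    res <- mine_genome(seqs, mcfg)
    write_ssr(res$loci, paths$ssr)
    write_sat1(res$summary, paths$sat1)
    written <- c(written, paths$ssr, paths$sat1)
    logmsg("found %d SSR loci", res$summary$n_loci)
  }
  if ("stats" %in% stages) {
    loci <- read_ssr(need(paths$ssr, "stats", "mine"))
    lens <- stats::setNames(unique(loci[, c("seq_id", "seq_len")])$seq_len,
                            unique(loci[, c("seq_id", "seq_len")])$seq_id)
    if (!is.null(cfg_get(config, "fasta")) &&
        file.exists(cfg_get(config, "fasta"))) {
      lens <- nchar(read_fasta(cfg_get(config, "fasta")))
    }
    st <- ssr_stats(loci, lens, scale = cfg_num(config, "freq_scale", 1e6))
    write_sat2(st, paths$sat2)
    written <- c(written, paths$sat2)
  }
  if ("plot" %in% stages) {
    st <- read_sat2(need(paths$sat2, "plot", "stats"))
    pcfg <- plot_config(
      outdir = paste0(prefix, "_plots"),
      formats = trimws(strsplit(cfg_get(config, "plot_formats",
                                        "png,svg"), ",")[[1]]))
    written <- c(written, plot_all_stats(st, pcfg))
  }
  pparams <- primer_params(
    flank = cfg_num(config, "flank", 400),
    product_min = cfg_num(config, "product_min", 100),
    product_max = cfg_num(config, "product_max", 400),
    tm_opt = cfg_num(config, "tm", 60))
  if ("design" %in% stages) {
    loci <- read_ssr(need(paths$ssr, "design", "mine"))
    seqs <- load_fasta("design")
    des <- design_all(loci, seqs, pparams)
    markers <- deduplicate_markers(des$pairs)
    write_sts(markers, paths$sts)
    write_mk(markers, paths$mk)
    written <- c(written, paths$sts, paths$mk)
    logmsg("designed %d primer pairs -> %d unique markers (%d failures)",
           nrow(des$pairs), nrow(markers$markers), nrow(des$failures))
  }
  if ("emap" %in% stages) {
    mk <- read_sts(need(paths$sts, "emap", "design"))
    tf <- cfg_get(config, "targets_fasta", cfg_get(config, "fasta"))
    if (is.null(tf)) stopf("stage 'emap' requires a FASTA to screen")
    targets <- read_fasta(tf)
    eparams <- epcr_params(
      max_mismatch = cfg_num(config, "mismatch", 0),
      size_margin = cfg_num(config, "margin", Inf))
    amps <- epcr(mk, targets, eparams)
    score <- score_polymorphism(amps, mk, targets)
    summ <- summarize_mapping(amps, mk, targets)
    write_amp(amps, paths$amp)
    write_frg(score, paths$frg)
    write_emap(amps, targets, paths$emap)
    write_sat4(summ, paths$sat4)
    written <- c(written, paths$amp, paths$frg, paths$emap, paths$sat4)
    logmsg("%d amplicons from %d mapped markers",
           summ$total_amplicons, summ$n_markers_mapped)
  }
  if ("export" %in% stages) {
    loci <- read_ssr(need(paths$ssr, "export", "mine"))
    loci_to_gff3(loci, paths$gff3)
    if (file.exists(paths$sts) && file.exists(paths$amp)) {
      mk <- read_sts(paths$sts)
      amps <- read_amp(paths$amp)
      mgff <- paste0(prefix, "_markers.gff3")
      suppressWarnings(markers_to_gff3(mk, amps, mgff))
      written <- c(written, mgff)
    }
    written <- c(written, paths$gff3)
  }
  manifest <- c(
    sprintf("ssrforge_version\t%s",
            as.character(utils::packageVersion("ssrforge"))),
    sprintf("stages\t%s", paste(stages, collapse = ",")),
    sprintf("seed\t%s", cfg_get(config, "seed", "NA")),
    vapply(setdiff(names(config), "stages"), function(k) {
      sprintf("setting\t%s=%s", k, config[[k]])
    }, character(1)))
  writeLines(manifest, paths$manifest)
  invisible(c(as.list(stats::setNames(written, basename(written))),
              manifest = paths$manifest))
}
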