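#' Run a pipeline stage from a configuration
#'
#' Single programmatic entry point tying the stages together: `scan`
#' (genome-wide editability report), `design` (designs covering one target),
#' `offtarget` (conversion calling plus the off-target summary), `profile`
#' (editing-window aggregation) and `simulate` (synthetic genome and read
#' set). The configuration is a named list or a path to a JSON file with a
#' `task` field and task-specific fields; every JSON report embeds the full
#' parameter set and package version, and identical configurations produce
#' byte-identical reports. A thin command-line wrapper over this function
#' ships at `system.file("scripts", "ddcbetools", package = "ddcbetools")`.
#'
#' Task fields (paths are resolved as given):
#' \describe{
#'   \item{scan}{`genome` (FASTA path), `circular` (default TRUE), `out`
#'     (JSON path), optional `motifs_tsv`, and any [scan_params()] fields.}
#'   \item{design}{`genome`, `circular`, `position`, `strand`, optional
#'     `one_based`, `out` (TSV path), optional `summary_json`.}
#'   \item{offtarget}{`genome`, `circular`, `alignments` (SAM/BAM),
#'     optional `targets` (BED path: 0-based half-open), `out` (JSON),
#'     optional `positions_tsv`, and any [caller_params()] fields.}
#'   \item{profile}{`freqs` (TSV: `site_id`, `offset`, `percent`), `out`
#'     (JSON), optional `profile_tsv`, optional `threshold_fraction`.}
#'   \item{simulate}{`length`, `gc_fraction`, `circular`, `seed`, `depth`,
#'     `read_length`, `sequencing_error_rate`, optional `edits` (TSV:
#'     `pos`, `fraction`), `out_prefix` (writes `<prefix>.fasta`,
#'     `<prefix>.sam`, `<prefix>.truth.json`).}
#' }
#'
#' @param config A named list or path to a JSON configuration file.
#' @return Invisibly, a named list of the files written.
#' @export
dd_run <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  task <- config$task
  if (is.null(task) || !task %in% c("scan", "design", "offtarget", "profile",
                                    "simulate")) {
    stop("config$task must be one of scan, design, offtarget, profile, ",
         "simulate", call. = FALSE)
  }
  switch(task,
         scan = run_scan(config),
         design = run_design(config),
         offtarget = run_offtarget(config),
         profile = run_profile(config),
         simulate = run_simulate(config))
}

need <- function(config, field) {
  v <- config[[field]]
  if (is.null(v)) {
    stop("configuration is missing required field '", field, "'",
         call. = FALSE)
  }
  v
}

config_scan_params <- function(config) {
  keep <- intersect(names(config), names(formals(scan_params)))
  do.call(scan_params, config[keep])
}

config_caller_params <- function(config) {
  keep <- intersect(names(config), names(formals(caller_params)))
  do.call(caller_params, config[keep])
}

report_meta <- function(params) {
  list(tool = "ddcbetools",
       version = as.character(utils::packageVersion("ddcbetools")),
       parameters = unclass(params))
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

run_scan <- function(config) {
  genome <- read_genome_fasta(need(config, "genome"),
                              circular = config$circular %||% TRUE)
  params <- config_scan_params(config)
  rep <- editability_report(genome, params)
  out <- need(config, "out")
  payload <- c(report_meta(params),
               list(genome = genome$name, genome_length = genome$length,
                    topology = rep$topology, counts = rep$counts,
                    mddcbe_only_fraction_display =
                      sprintf("%.1f%%", rep$counts$mddcbe_only_fraction),
                    sensitivity = rep$sensitivity))
  write_report_json(payload, out)
  written <- list(out = out)
  if (!is.null(config$motifs_tsv)) {
    m <- rep$motifs
    m$c_pos1 <- m$c_pos + 1L
    readr::write_tsv(m[, c("c_pos", "c_pos1", "strand", "ddcbe", "mddcbe",
                           "editable_by")], config$motifs_tsv)
    written$motifs_tsv <- config$motifs_tsv
  }
  invisible(written)
}

run_design <- function(config) {
  genome <- read_genome_fasta(need(config, "genome"),
                              circular = config$circular %||% TRUE)
  params <- config_scan_params(config)
  designs <- design_for_target(genome, need(config, "position"),
                               need(config, "strand"),
                               scan_params = params,
                               one_based = isTRUE(config$one_based))
  out <- need(config, "out")
  readr::write_tsv(designs, out)
  written <- list(out = out)
  if (!is.null(config$summary_json)) {
    payload <- c(report_meta(params),
                 list(position = config$position, strand = config$strand,
                      n_monomeric = sum(designs$design_type == "monomeric"),
                      n_dimeric = sum(designs$design_type == "dimeric")))
    write_report_json(payload, config$summary_json)
    written$summary_json <- config$summary_json
  }
  invisible(written)
}

read_bed_windows <- function(path) {
  if (!file.exists(path)) {
    stop("targets file not found: ", path, call. = FALSE)
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  tibble::tibble(start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
}

run_offtarget <- function(config) {
  genome <- read_genome_fasta(need(config, "genome"),
                              circular = config$circular %||% TRUE)
  params <- config_caller_params(config)
  conv <- pileup_conversions(need(config, "alignments"), genome, params)
  windows <- if (!is.null(config$targets)) read_bed_windows(config$targets)
             else NULL
  summ <- summarize_offtarget(conv, windows, params)
  out <- need(config, "out")
  payload <- c(report_meta(params),
               list(genome = genome$name, summary = summ$summary,
                    candidates = summ$candidates))
  write_report_json(payload, out)
  written <- list(out = out)
  if (!is.null(config$positions_tsv)) {
    readr::write_tsv(summ$positions, config$positions_tsv)
    written$positions_tsv <- config$positions_tsv
  }
  invisible(written)
}

run_profile <- function(config) {
  path <- need(config, "freqs")
  if (!file.exists(path)) {
    stop("frequency table not found: ", path, call. = FALSE)
  }
  freqs <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("offset", "percent") %in% names(freqs)))
  thr <- config$threshold_fraction %||% 0.5
  win <- aggregate_window(freqs, threshold_fraction = thr)
  out <- need(config, "out")
  payload <- c(report_meta(list(threshold_fraction = thr)),
               list(window = as.list(glance(win))))
  write_report_json(payload, out)
  written <- list(out = out)
  if (!is.null(config$profile_tsv)) {
    readr::write_tsv(win$profile, config$profile_tsv)
    written$profile_tsv <- config$profile_tsv
  }
  invisible(written)
}

run_simulate <- function(config) {
  prefix <- need(config, "out_prefix")
  sim <- simulate_genome(need(config, "length"),
                         gc_fraction = config$gc_fraction %||% 0.44,
                         circular = config$circular %||% TRUE,
                         seed = config$seed %||% 1L)
  edits <- NULL
  if (!is.null(config$edits)) {
    if (!file.exists(config$edits)) {
      stop("edits file not found: ", config$edits, call. = FALSE)
    }
    edits <- readr::read_tsv(config$edits, show_col_types = FALSE)
  }
  spec <- edit_spec(per_position = edits,
                    sequencing_error_rate =
                      config$sequencing_error_rate %||% 0,
                    depth = config$depth %||% 100L,
                    read_length = config$read_length %||% 100L,
                    seed = config$seed %||% 1L)
  fasta <- paste0(prefix, ".fasta")
  samp <- paste0(prefix, ".sam")
  truthp <- paste0(prefix, ".truth.json")
  write_genome_fasta(sim$genome, fasta)
  res <- simulate_reads(sim$genome, spec, samp)
  write_report_json(c(report_meta(list(seed = spec$seed)),
                      list(truth = res$truth)), truthp)
  invisible(list(fasta = fasta, sam = samp, truth_json = truthp))
}
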