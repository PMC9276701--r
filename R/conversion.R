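#' Parameters for per-position conversion-rate calling
#'
#' `min_candidate_rate` (0.1%) defines which positions are reported as
#' off-target candidates; `snv_exclusion_rate` (50%) removes positions that
#' behave as pre-existing cell-line variants rather than editing. Depth and
#' quality thresholds are conventional amplicon-sequencing defaults and are
#' echoed in every summary.
#'
#' @param min_candidate_rate Minimum conversion rate for a candidate
#'   position (fraction).
#' @param snv_exclusion_rate Positions at or above this conversion rate are
#'   excluded as single-nucleotide variants (fraction; inclusive bound).
#' @param min_depth Minimum filtered read depth for a defined rate.
#' @param min_base_quality,min_mapping_quality Phred thresholds applied
#'   before counting.
#' @return A validated `dd_caller_params` list.
#' @export
caller_params <- function(min_candidate_rate = 0.001,
                          snv_exclusion_rate = 0.5,
                          min_depth = 100L,
                          min_base_quality = 20L,
                          min_mapping_quality = 20L) {
  p <- list(min_candidate_rate = as.numeric(min_candidate_rate),
            snv_exclusion_rate = as.numeric(snv_exclusion_rate),
            min_depth = as.integer(min_depth),
            min_base_quality = as.integer(min_base_quality),
            min_mapping_quality = as.integer(min_mapping_quality))
  stopifnot(p$min_candidate_rate > 0,
            p$min_candidate_rate < p$snv_exclusion_rate,
            p$snv_exclusion_rate <= 1,
            p$min_depth >= 1L)
  structure(p, class = "dd_caller_params")
}

#' Per-position C-to-T / G-to-A conversion rates from aligned reads
#'
#' Computes, for every reference cytosine and guanine, the fraction of
#' high-quality covering reads showing the deamination product: T at a
#' reference C, or A at a reference G (the same biological C-to-T event read
#' from the other strand). The denominator counts reads with a high-quality
#' base call of any nucleotide at the position; mismatches to other bases
#' stay in the denominator only, and deletions and N calls are excluded.
#' Positions with depth below `min_depth` are flagged (`pass_depth = FALSE`,
#' rate `NA`) rather than reported as zero.
#'
#' Input may be plain-text SAM (converted and sorted internally) or BAM.
#' Paired reads with overlapping mates are counted per record; deduplicate
#' or clip overlaps upstream if double-counting matters for your protocol.
#'
#' @param alignments Path to a SAM or BAM file aligned to `genome`.
#' @param genome The reference [dd_genome()]; its name and length must match
#'   the alignment header.
#' @param params A [caller_params()].
#' @return A tibble with one row per reference C/G position: `pos` (0-based),
#'   `pos1`, `ref`, `depth`, `converted`, `rate`, `pass_depth`.
#' @export
pileup_conversions <- function(alignments, genome, params = caller_params()) {
  stopifnot(inherits(genome, "dd_genome"), inherits(params, "dd_caller_params"))
  if (!file.exists(alignments)) {
    stop("alignment file not found: ", alignments, call. = FALSE)
  }
  bam <- as_sorted_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(genome$name %in% names(hdr))) {
    stop("reference name mismatch: alignments are against [",
         paste(names(hdr), collapse = ", "), "], genome is '",
         genome$name, "'", call. = FALSE)
  }
  if (hdr[[genome$name]] != genome$length) {
    stop("reference length mismatch for '", genome$name, "': header says ",
         hdr[[genome$name]], ", genome has ", genome$length, call. = FALSE)
  }
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = params$min_base_quality,
    min_mapq = params$min_mapping_quality,
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  pu <- Rsamtools::pileup(bam, pileupParam = pp)

  ch <- seq_chars(genome)
  ref_pos0 <- which(ch == "C" | ch == "G") - 1L
  out <- tibble::tibble(
    pos = ref_pos0,
    pos1 = ref_pos0 + 1L,
    ref = ch[ref_pos0 + 1L],
    depth = 0L,
    converted = 0L
  )
  if (nrow(pu) > 0L) {
    pu <- pu[pu$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
    depth_by_pos <- tapply(pu$count, pu$pos, sum)
    idx <- match(out$pos1, as.integer(names(depth_by_pos)))
    out$depth <- ifelse(is.na(idx), 0L, as.integer(depth_by_pos)[idx])
    conv_nt <- ifelse(out$ref == "C", "T", "A")
    key_pu <- paste(pu$pos, pu$nucleotide)
    cidx <- match(paste(out$pos1, conv_nt), key_pu)
    out$converted <- ifelse(is.na(cidx), 0L, pu$count[cidx])
  }
  out$pass_depth <- out$depth >= params$min_depth
  out$rate <- ifelse(out$pass_depth, out$converted / pmax(out$depth, 1L),
                     NA_real_)
  out
}

# SAM input is converted to a coordinate-sorted, indexed BAM in tempdir();
# BAM input is sorted if needed.
as_sorted_bam <- function(path) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  sorted <- Rsamtools::sortBam(bam, tempfile(fileext = ""))
  Rsamtools::indexBam(sorted)
  sorted
}

#' Editing frequencies inside a target window
#'
#' Restricts a [pileup_conversions()] table to one window and expresses the
#' conversion rates as percentages of sequencing reads carrying the base
#' conversion among total filtered reads. Numbers are identical to the
#' genome-wide computation at those positions.
#'
#' @param conversions A tibble from [pileup_conversions()].
#' @param window Numeric length-2 vector `c(start, end)`, 0-based half-open,
#'   or a data frame with `start`/`end` columns (first row used).
#' @return The windowed rows with an added `percent` column.
#' @export
quantify_on_target <- function(conversions, window) {
  w <- as_window(window)
  out <- conversions[conversions$pos >= w[[1]] & conversions$pos < w[[2]], ,
                     drop = FALSE]
  out$percent <- 100 * out$rate
  tibble::as_tibble(out)
}

as_window <- function(window) {
  if (is.data.frame(window)) {
    stopifnot(all(c("start", "end") %in% names(window)), nrow(window) >= 1L)
    w <- c(window$start[[1]], window$end[[1]])
  } else {
    stopifnot(is.numeric(window), length(window) == 2L)
    w <- as.numeric(window)
  }
  if (w[[2]] <= w[[1]]) stop("window end must exceed start", call. = FALSE)
  w
}

#' Genome-wide off-target editing summary
#'
#' Applies the standard exclusion filters to a per-position conversion table:
#' positions inside any on-target window are excluded, positions with
#' conversion rate at or above `snv_exclusion_rate` (default 50%) are
#' excluded as cell-line variants, and the average editing frequency is the
#' arithmetic mean over ALL retained C/G positions - not only those passing
#' the candidate threshold, which is why an untreated control can average
#' well below the 0.1% candidate cutoff. Candidate positions (rate at or
#' above `min_candidate_rate` after exclusion) are listed separately.
#'
#' Only positions with a defined rate (`pass_depth`) enter the summary; the
#' number of low-depth positions dropped is reported.
#'
#' @param conversions A tibble from [pileup_conversions()].
#' @param target_windows On-target windows to exclude: a data frame with
#'   `start`/`end` columns (0-based half-open), a list of length-2 vectors,
#'   or `NULL`.
#' @param params A [caller_params()].
#' @return A `dd_offtarget` object with elements `positions` (per-position
#'   tibble with a `category` column), `candidates`, `summary` (named list)
#'   and `params`. `tidy()`, `glance()` and `autoplot()` methods are
#'   provided.
#' @export
summarize_offtarget <- function(conversions, target_windows = NULL,
                                params = caller_params()) {
  stopifnot(inherits(params, "dd_caller_params"))
  windows <- normalize_windows(target_windows)
  n_low <- sum(!conversions$pass_depth)
  pos <- conversions[conversions$pass_depth, , drop = FALSE]
  in_target <- rep(FALSE, nrow(pos))
  for (w in windows) {
    in_target <- in_target | (pos$pos >= w[[1]] & pos$pos < w[[2]])
  }
  pos$category <- dplyr::case_when(
    in_target ~ "target",
    pos$rate >= params$snv_exclusion_rate ~ "snv",
    TRUE ~ "retained"
  )
  retained <- pos[pos$category == "retained", , drop = FALSE]
  if (nrow(retained) == 0L) {
    stop("no positions retained after exclusions; refusing to report a mean ",
         "of nothing", call. = FALSE)
  }
  candidates <- retained[retained$rate >= params$min_candidate_rate, ,
                         drop = FALSE]
  candidates <- dplyr::arrange(candidates, .data$pos)
  summary <- list(
    mean_offtarget_rate = mean(retained$rate),
    mean_offtarget_pct = 100 * mean(retained$rate),
    n_positions_retained = nrow(retained),
    n_excluded_snv = sum(pos$category == "snv"),
    n_excluded_target = sum(pos$category == "target"),
    n_low_depth = n_low,
    n_candidates = nrow(candidates)
  )
  structure(
    list(positions = tibble::as_tibble(pos),
         candidates = tibble::as_tibble(candidates),
         summary = summary, params = params),
    class = "dd_offtarget"
  )
}

normalize_windows <- function(target_windows) {
  if (is.null(target_windows)) return(list())
  if (is.data.frame(target_windows)) {
    stopifnot(all(c("start", "end") %in% names(target_windows)))
    return(purrr::map2(target_windows$start, target_windows$end, c))
  }
  if (is.numeric(target_windows) && length(target_windows) == 2L) {
    return(list(as.numeric(target_windows)))
  }
  stopifnot(is.list(target_windows))
  lapply(target_windows, as_window)
}

#' @export
print.dd_offtarget <- function(x, ...) {
  s <- x$summary
  cat("<dd_offtarget>\n")
  cat(sprintf("  mean off-target rate: %.4f%% over %d retained C/G positions\n",
              s$mean_offtarget_pct, s$n_positions_retained))
  cat(sprintf("  excluded: %d SNV (>= %.0f%%), %d on-target; %d low-depth\n",
              s$n_excluded_snv, 100 * x$params$snv_exclusion_rate,
              s$n_excluded_target, s$n_low_depth))
  cat(sprintf("  candidates (>= %.2f%%): %d\n",
              100 * x$params$min_candidate_rate, s$n_candidates))
  invisible(x)
}

#' @rdname summarize_offtarget
#' @param x,object A `dd_offtarget` object.
#' @param ... Unused.
#' @method tidy dd_offtarget
#' @export
tidy.dd_offtarget <- function(x, ...) x$positions

#' @rdname summarize_offtarget
#' @method glance dd_offtarget
#' @export
glance.dd_offtarget <- function(x, ...) tibble::as_tibble(x$summary)

#' @rdname summarize_offtarget
#' @method autoplot dd_offtarget
#' @export
autoplot.dd_offtarget <- function(object, ...) {
  p <- object$positions
  ggplot2::ggplot(p, ggplot2::aes(x = .data$pos1, y = 100 * .data$rate,
                                  colour = .data$category)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 100 * object$params$min_candidate_rate,
                        linetype = "dashed") +
    ggplot2::labs(x = "position (1-based)", y = "conversion rate (%)",
                  colour = NULL,
                  title = sprintf("mean off-target %.4f%%",
                                  object$summary$mean_offtarget_pct)) +
    ggplot2::theme_minimal()
}
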