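#' Map per-position editing frequencies to TALE-site-relative offsets
#'
#' Converts genome coordinates to strand-relative offsets counted 1-based
#' from the 3'-terminal thymidine of a TALE binding site, the coordinate
#' system in which the monomeric editing window is defined. For a `+`
#' strand site the offset of forward coordinate `p` is `p - (end - 1)`; for
#' a `-` strand site orientation flips and the offset is `start - p`.
#' Positions at or upstream of the 3'-terminal base (offset <= 0) are
#' dropped.
#'
#' @param freqs A data frame with columns `pos` (0-based forward-strand
#'   coordinate) and `percent` (editing percentage, 0-100).
#' @param site The TALE site: a list or one-row data frame with `start`,
#'   `end` (0-based half-open) and `strand`.
#' @param genome Optional [dd_genome()]; when supplied, coordinates outside
#'   the genome are an error and offsets wrap on circular genomes.
#' @return A tibble with columns `offset` and `percent`, sorted by offset.
#' @examples
#' align_profile_to_site(data.frame(pos = 18, percent = 30),
#'                       list(start = 0, end = 14, strand = "+"))
#' @export
align_profile_to_site <- function(freqs, site, genome = NULL) {
  stopifnot(is.data.frame(freqs), all(c("pos", "percent") %in% names(freqs)))
  if (is.data.frame(site)) site <- as.list(site[1L, ])
  stopifnot(all(c("start", "end", "strand") %in% names(site)))
  check_strand(site$strand)
  pos <- as.integer(freqs$pos)
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "dd_genome"))
    if (any(pos < 0L | pos >= genome$length)) {
      bad <- pos[pos < 0L | pos >= genome$length][[1]]
      stop("coordinate ", bad, " outside genome of length ", genome$length,
           call. = FALSE)
    }
  }
  t3 <- if (site$strand == "+") as.integer(site$end) - 1L else as.integer(site$start)
  offset <- if (site$strand == "+") pos - t3 else t3 - pos
  if (!is.null(genome) && genome$circular) {
    offset <- ((offset %% genome$length) + genome$length) %% genome$length
  }
  keep <- offset >= 1L
  out <- tibble::tibble(offset = offset[keep],
                        percent = as.numeric(freqs$percent)[keep])
  dplyr::arrange(out, .data$offset)
}

#' Aggregate site profiles into an editing-window call
#'
#' Averages editing percentages per offset across profiles and calls the
#' editing window as the maximal contiguous run of offsets whose mean is at
#' least `threshold_fraction` of the peak mean; among equally long runs the
#' one containing the peak (then the earliest) is reported. The empirical
#' editing window is only loosely defined, so the relative-height rule and
#' its threshold are explicit and echoed in the result. Uniform (flat, nonzero) profiles degenerate to
#' a window spanning all observed offsets; all-zero profiles yield an empty
#' window.
#'
#' @param profiles Either a data frame with columns `offset`, `percent` and
#'   optionally `profile_id`, or a list of per-site tibbles from
#'   [align_profile_to_site()].
#' @param threshold_fraction Fraction of the peak mean an offset must reach
#'   to be part of the window.
#' @return A `dd_window_profile` object with elements `profile` (tibble:
#'   `offset`, `mean_percent`, `n_obs`), `window` (inclusive integer bounds,
#'   or `integer(0)`), `threshold_fraction` and `peak_offset`. `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
aggregate_window <- function(profiles, threshold_fraction = 0.5) {
  stopifnot(is.numeric(threshold_fraction), threshold_fraction > 0,
            threshold_fraction <= 1)
  if (is.data.frame(profiles)) {
    long <- tibble::as_tibble(profiles)
  } else {
    stopifnot(is.list(profiles), length(profiles) >= 1L)
    long <- dplyr::bind_rows(profiles, .id = "profile_id")
  }
  stopifnot(all(c("offset", "percent") %in% names(long)), nrow(long) >= 1L)
  stopifnot(all(long$percent >= 0), all(long$percent <= 100))
  prof <- long |>
    dplyr::group_by(offset = as.integer(.data$offset)) |>
    dplyr::summarise(mean_percent = mean(.data$percent),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$offset)
  peak <- max(prof$mean_percent)
  if (peak <= 0) {
    window <- integer(0)
    peak_offset <- NA_integer_
  } else {
    qualifies <- prof$mean_percent >= threshold_fraction * peak
    peak_offset <- prof$offset[which.max(prof$mean_percent)]
    # contiguous runs over integer offsets (gaps in observed offsets break
    # runs as do non-qualifying offsets); keep the longest qualifying run,
    # ties resolved toward the run holding the peak, then the earliest
    run_id <- cumsum(c(TRUE, diff(prof$offset) != 1L | diff(qualifies) != 0L))
    runs <- unique(run_id[qualifies])
    run_len <- vapply(runs, function(r) sum(run_id == r), integer(1))
    best <- runs[run_len == max(run_len)]
    peak_run <- run_id[prof$offset == peak_offset]
    pick <- if (peak_run %in% best) peak_run else best[[1]]
    in_run <- qualifies & run_id == pick
    window <- c(min(prof$offset[in_run]), max(prof$offset[in_run]))
  }
  structure(
    list(profile = prof, window = window,
         threshold_fraction = threshold_fraction,
         peak_offset = peak_offset),
    class = "dd_window_profile"
  )
}

#' @export
print.dd_window_profile <- function(x, ...) {
  cat("<dd_window_profile>\n")
  if (length(x$window) == 2L) {
    cat(sprintf("  called editing window: offsets %d-%d (>= %.0f%% of peak at %d)\n",
                x$window[[1]], x$window[[2]], 100 * x$threshold_fraction,
                x$peak_offset))
  } else {
    cat("  called editing window: empty (flat profile)\n")
  }
  cat(sprintf("  %d offsets profiled\n", nrow(x$profile)))
  invisible(x)
}

#' @rdname aggregate_window
#' @param x,object A `dd_window_profile` object.
#' @param ... Unused.
#' @method tidy dd_window_profile
#' @export
tidy.dd_window_profile <- function(x, ...) x$profile

#' @rdname aggregate_window
#' @method glance dd_window_profile
#' @export
glance.dd_window_profile <- function(x, ...) {
  tibble::tibble(
    window_lower = if (length(x$window) == 2L) x$window[[1]] else NA_integer_,
    window_upper = if (length(x$window) == 2L) x$window[[2]] else NA_integer_,
    peak_offset = x$peak_offset,
    threshold_fraction = x$threshold_fraction,
    n_offsets = nrow(x$profile)
  )
}

#' @rdname aggregate_window
#' @method autoplot dd_window_profile
#' @export
autoplot.dd_window_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$offset, y = .data$mean_percent)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "offset downstream of TALE site 3' thymidine",
                  y = "mean editing (%)") +
    ggplot2::theme_minimal()
  if (length(object$window) == 2L) {
    p <- p + ggplot2::annotate("rect",
                               xmin = object$window[[1]] - 0.5,
                               xmax = object$window[[2]] + 0.5,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  p
}
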