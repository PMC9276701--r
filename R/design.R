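#' Parameters of the preferred monomeric editing window
#'
#' The monomeric editor converts cytosines most frequently at offsets 4-11
#' downstream of the TALE site's 3'-terminal thymidine; designs placing the
#' target inside this window are preferred.
#'
#' @param preferred_min,preferred_max Inclusive offset bounds of the
#'   preferred window (1-based from the 3'-terminal thymidine).
#' @return A validated `dd_window_params` list.
#' @export
window_params <- function(preferred_min = 4L, preferred_max = 11L) {
  p <- list(preferred_min = as.integer(preferred_min),
            preferred_max = as.integer(preferred_max))
  stopifnot(p$preferred_min >= 1L, p$preferred_min <= p$preferred_max)
  structure(p, class = "dd_window_params")
}

#' Enumerate and rank designs covering one target cytosine
#'
#' Given a target cytosine in a 5'-TC context, returns every dimeric
#' DdCBE pair whose spacer contains the target and every monomeric mDdCBE
#' design reaching it. Monomeric designs are ranked by how the target's
#' offset sits relative to the preferred editing window: `rank_score =
#' 1 / (1 + d)` where `d` is the distance from the offset to the window (0
#' inside), ties broken by shorter offset then smaller site start. Dimeric
#' designs carry no offset-based score (no intra-spacer position preference
#' is defined) and are listed after the monomeric ones.
#'
#' @param genome A [dd_genome()].
#' @param position Coordinate of the target cytosine: the forward-strand
#'   coordinate of the C for a `+` motif, of the G whose complement is
#'   edited for a `-` motif. 0-based unless `one_based = TRUE`.
#' @param strand Strand on which the dinucleotide reads TC.
#' @param scan_params A [scan_params()].
#' @param win A [window_params()].
#' @param one_based Interpret `position` as 1-based (as in mtDNA
#'   literature coordinates).
#' @return A tibble with one row per design: `design_type`
#'   (`"monomeric"`/`"dimeric"`), site coordinates, `target_offset`,
#'   `in_preferred_window` and `rank_score` (NA for dimeric designs).
#' @export
design_for_target <- function(genome, position, strand,
                              scan_params = ddcbetools::scan_params(),
                              win = window_params(), one_based = FALSE) {
  stopifnot(inherits(genome, "dd_genome"))
  check_strand(strand)
  pos <- as.integer(position) - if (one_based) 1L else 0L
  L <- genome$length
  if (genome$circular) pos <- ((pos %% L) + L) %% L
  if (pos < 0L || pos >= L) {
    stop("position ", position, " outside genome of length ", L, call. = FALSE)
  }
  ctx_start <- if (strand == "+") pos - 1L else pos
  if (!genome$circular && (ctx_start < 0L || ctx_start + 2L > L)) {
    stop("position ", position, " has no complete dinucleotide context",
         call. = FALSE)
  }
  ctx <- fetch_window(genome, ctx_start, 2L, "+")
  expected <- if (strand == "+") "TC" else "GA"
  if (ctx != expected) {
    stop("position ", position, " (", strand, ") is not a TC-context ",
         "cytosine: observed forward-strand dinucleotide \"", ctx, "\"",
         call. = FALSE)
  }

  md <- find_mddcbe_designs(genome, scan_params, contain = pos)
  dd <- find_ddcbe_designs(genome, scan_params, contain = pos)
  # keep only monomeric designs whose listed motif set includes the target
  # on the right strand, and record its offset
  mono <- NULL
  if (nrow(md) > 0L) {
    off <- purrr::map_dbl(md$motifs, function(m) {
      i <- which(m$c_pos == pos & m$strand == strand)
      if (length(i) == 0L) NA_real_ else as.numeric(m$offset[[i[[1]]]])
    })
    keep <- !is.na(off)
    if (any(keep)) {
      mono <- tibble::tibble(
        design_type = "monomeric",
        site_start = md$site_start[keep], site_end = md$site_end[keep],
        site_strand = md$site_strand[keep],
        site_length = md$site_length[keep],
        spacer_start = NA_integer_, spacer_end = NA_integer_,
        right_start = NA_integer_, right_end = NA_integer_,
        target_offset = as.integer(off[keep])
      )
      d <- pmax(win$preferred_min - mono$target_offset,
                mono$target_offset - win$preferred_max, 0L)
      mono$in_preferred_window <- d == 0L
      mono$rank_score <- 1 / (1 + d)
      mono <- dplyr::arrange(mono, dplyr::desc(.data$rank_score),
                             .data$target_offset, .data$site_start)
    }
  }
  dim <- NULL
  if (nrow(dd) > 0L) {
    keep <- purrr::map_lgl(dd$motifs, function(m) {
      any(m$c_pos == pos & m$strand == strand)
    })
    if (any(keep)) {
      dim <- tibble::tibble(
        design_type = "dimeric",
        site_start = dd$left_start[keep], site_end = dd$left_end[keep],
        site_strand = "+",
        site_length = dd$left_length[keep],
        spacer_start = dd$spacer_start[keep], spacer_end = dd$spacer_end[keep],
        right_start = dd$right_start[keep], right_end = dd$right_end[keep],
        target_offset = NA_integer_,
        in_preferred_window = NA,
        rank_score = NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(mono, dim)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble::tibble(
      design_type = character(0), site_start = integer(0),
      site_end = integer(0), site_strand = character(0),
      site_length = integer(0), spacer_start = integer(0),
      spacer_end = integer(0), right_start = integer(0),
      right_end = integer(0), target_offset = integer(0),
      in_preferred_window = logical(0), rank_score = numeric(0))
  }
  out
}
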