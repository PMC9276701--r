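#' Parameters for the DdCBE / mDdCBE targetability scan
#'
#' Houses the site, spacer and window constraints used throughout the scan:
#' the TALE array-binding sequence must start and end with thymidine (on the
#' bound strand) and be 14-20 bp long; a dimeric DdCBE pair needs a 14-18 bp
#' spacer between convergent left (+ strand) and right (- strand) sites
#' containing at least one TC motif; a monomeric mDdCBE reaches TC motifs
#' within 18 bp downstream of the 3'-terminal thymidine of a single site.
#'
#' Two conventions these criteria leave open are exposed: `window_anchor`
#' selects whether the monomeric 18-bp window is measured to the motif's C
#' (default) or its T, and `spacer_motif_rule` selects whether a spacer must
#' contain the whole TC dinucleotide (default) or just the target C. The
#' defaults are the conventions under which the human mitochondrial
#' reference yields its reported monomeric-only fraction of 8.4%;
#' [editability_report()] tabulates the alternatives.
#'
#' @param tale_len_min,tale_len_max Allowed TALE binding-site lengths (bp).
#' @param spacer_len_min,spacer_len_max Allowed dimeric spacer lengths (bp).
#' @param mono_window Reach of the monomeric editor downstream of the site's
#'   3'-terminal thymidine (bp).
#' @param require_terminal_T Require thymidine at both ends of the bound
#'   site sequence.
#' @param window_anchor `"c"` or `"t"`: base of the motif whose distance to
#'   the 3'-terminal thymidine must fall within `mono_window`.
#' @param spacer_motif_rule `"dinucleotide"` (both bases of the TC inside the
#'   spacer) or `"c_only"` (just the target C inside).
#' @return A validated `dd_scan_params` list.
#' @export
scan_params <- function(tale_len_min = 14L, tale_len_max = 20L,
                        spacer_len_min = 14L, spacer_len_max = 18L,
                        mono_window = 18L, require_terminal_T = TRUE,
                        window_anchor = c("c", "t"),
                        spacer_motif_rule = c("dinucleotide", "c_only")) {
  window_anchor <- match.arg(window_anchor)
  spacer_motif_rule <- match.arg(spacer_motif_rule)
  p <- list(
    tale_len_min = as.integer(tale_len_min),
    tale_len_max = as.integer(tale_len_max),
    spacer_len_min = as.integer(spacer_len_min),
    spacer_len_max = as.integer(spacer_len_max),
    mono_window = as.integer(mono_window),
    require_terminal_T = isTRUE(require_terminal_T),
    window_anchor = window_anchor,
    spacer_motif_rule = spacer_motif_rule
  )
  stopifnot(
    p$tale_len_min >= 1L, p$tale_len_min <= p$tale_len_max,
    p$spacer_len_min >= 1L, p$spacer_len_min <= p$spacer_len_max,
    p$mono_window >= 1L
  )
  structure(p, class = "dd_scan_params")
}

#' Find all 5'-TC motifs of a genome
#'
#' Every forward-strand "TC" yields a `+` motif recorded at the C; every
#' forward-strand "GA" yields a `-` motif recorded at the G (the forward-
#' strand base whose complement is the edited C). On circular genomes the
#' dinucleotide spanning the origin junction is included.
#'
#' @param genome A [dd_genome()].
#' @return A tibble with columns `c_pos` (0-based forward-strand coordinate
#'   of the target cytosine), `c_pos1` (the same, 1-based) and `strand`,
#'   sorted by `c_pos` then strand.
#' @examples
#' find_tc_motifs(dd_genome("TC", circular = FALSE))
#' @export
find_tc_motifs <- function(genome) {
  stopifnot(inherits(genome, "dd_genome"))
  ch <- seq_chars(genome)
  prev_t <- shift_flags(ch == "T", -1L, genome$circular)
  next_a <- shift_flags(ch == "A", +1L, genome$circular)
  plus <- which(prev_t & ch == "C") - 1L
  minus <- which(ch == "G" & next_a) - 1L
  out <- tibble::tibble(
    c_pos = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus)))
  )
  out$c_pos1 <- out$c_pos + 1L
  dplyr::arrange(out[, c("c_pos", "c_pos1", "strand")], .data$c_pos, .data$strand)
}

# Per-position site-existence flags shared by the design enumerators and the
# vectorized editability engine (all 0-based positions i stored at index i+1):
#   top_t3[t] : some + strand site has its 3'-terminal T at t
#   bot_t3[s] : some - strand site has its 3'-terminal T at forward coord s
scan_site_flags <- function(genome, params) {
  ch <- seq_chars(genome)
  circ <- genome$circular
  L <- genome$length
  lmin <- params$tale_len_min
  lmax <- min(params$tale_len_max, L)  # a site never exceeds the genome
  if (lmin > L) {
    return(list(top_t3 = rep(FALSE, L), bot_t3 = rep(FALSE, L)))
  }
  if (params$require_terminal_T) {
    is_t <- ch == "T"
    is_a <- ch == "A"
    top <- is_t & any_in_window(is_t, -(lmax - 1L), -(lmin - 1L), circ)
    bot <- is_a & any_in_window(is_a, lmin - 1L, lmax - 1L, circ)
  } else {
    i0 <- seq_len(L) - 1L
    if (circ) {
      top <- bot <- rep(TRUE, L)
    } else {
      top <- i0 >= lmin - 1L
      bot <- i0 <= L - lmin
    }
  }
  list(top_t3 = top, bot_t3 = bot)
}

#' Enumerate candidate TALE binding sites
#'
#' Exhaustively lists all intervals of the allowed lengths, on both strands,
#' whose bound-strand sequence starts and ends with thymidine (when
#' `require_terminal_T`). A `-` strand site appears on the forward strand as
#' A at `start` and at `end - 1`. On circular genomes sites may span the
#' origin; their `end` is then the unwrapped image (`start + length`, which
#' can exceed the genome length).
#'
#' @param genome A [dd_genome()].
#' @param params A [scan_params()].
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `strand`, `length` and `bound_seq` (site read 5'->3' on the bound
#'   strand), ordered by (start, length, strand).
#' @export
enumerate_tale_sites <- function(genome, params = scan_params()) {
  stopifnot(inherits(genome, "dd_genome"), inherits(params, "dd_scan_params"))
  ch <- seq_chars(genome)
  L <- genome$length
  circ <- genome$circular
  rows <- list()
  for (len in params$tale_len_min:params$tale_len_max) {
    if (len > L) next
    starts0 <- if (circ) 0:(L - 1L) else if (L >= len) 0:(L - len) else integer(0)
    if (length(starts0) == 0L) next
    first <- ch[starts0 + 1L]
    last <- ch[(if (circ) (starts0 + len - 1L) %% L else starts0 + len - 1L) + 1L]
    plus_ok <- if (params$require_terminal_T) first == "T" & last == "T" else rep(TRUE, length(starts0))
    minus_ok <- if (params$require_terminal_T) first == "A" & last == "A" else rep(TRUE, length(starts0))
    if (any(plus_ok)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = starts0[plus_ok], length = len, strand = "+")
    }
    if (any(minus_ok)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = starts0[minus_ok], length = len, strand = "-")
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0), length = integer(0),
                          bound_seq = character(0)))
  }
  out <- dplyr::bind_rows(rows)
  out$end <- out$start + out$length
  out$bound_seq <- vapply(seq_len(nrow(out)), function(i) {
    fetch_window(genome, out$start[[i]], out$length[[i]], out$strand[[i]])
  }, character(1))
  out <- out[, c("start", "end", "strand", "length", "bound_seq")]
  dplyr::arrange(out, .data$start, .data$length, .data$strand)
}

# --- membership helpers (0-based coordinates) -------------------------------

# Is 0-based position x inside [from, from + len) (mod L when circular)?
pos_in_interval <- function(x, from, len, L, circular) {
  if (circular) ((x - from) %% L) < len else (x >= from & x < from + len)
}

# Spacer membership of a motif under the configured rule. The edited C of a
# "-" motif sits at the motif's forward coordinate; its dinucleotide occupies
# {c_pos, c_pos + 1}, a "+" motif's dinucleotide occupies {c_pos - 1, c_pos}.
motif_in_spacer <- function(c_pos, strand, sp_start, sp_len, L, circular, rule) {
  if (rule == "c_only") {
    return(pos_in_interval(c_pos, sp_start, sp_len, L, circular))
  }
  first <- ifelse(strand == "+", c_pos - 1L, c_pos)
  if (circular) first <- ((first %% L) + L) %% L
  # both adjacent bases inside the spacer <=> pair start within [b, b+len-2]
  pos_in_interval(first, sp_start, sp_len - 1L, L, circular)
}

#' Enumerate dimeric DdCBE pair designs
#'
#' Lists every pair of a left TALE site bound on the + strand and a right
#' TALE site bound on the - strand whose intervening spacer has an allowed
#' length and contains at least one TC motif (either strand) under the
#' configured membership rule. Exactly this one orientation is enumerated:
#' the mirrored assignment is the same physical configuration viewed from
#' the other strand. Coordinates of sites spanning a circular origin are
#' reported unwrapped relative to the left site, so `spacer_start` <
#' `spacer_end` always holds.
#'
#' @param genome A [dd_genome()].
#' @param params A [scan_params()].
#' @param contain Optional 0-based forward-strand coordinate; only designs
#'   whose spacer contains a motif whose target C sits at this coordinate
#'   are returned (used by [design_for_target()] to avoid a genome-wide
#'   enumeration).
#' @return A tibble with one row per design: left/right site coordinates,
#'   `spacer_start`, `spacer_end`, `spacer_length`, `n_motifs`, and a
#'   `motifs` list-column of per-design motif tibbles (`c_pos`, `strand`).
#' @export
find_ddcbe_designs <- function(genome, params = scan_params(), contain = NULL) {
  stopifnot(inherits(genome, "dd_genome"), inherits(params, "dd_scan_params"))
  L <- genome$length
  circ <- genome$circular
  sites <- enumerate_tale_sites(genome, params)
  left <- sites[sites$strand == "+", ]
  right <- sites[sites$strand == "-", ]
  motifs <- find_tc_motifs(genome)
  empty <- tibble::tibble(
    left_start = integer(0), left_end = integer(0), left_length = integer(0),
    right_start = integer(0), right_end = integer(0), right_length = integer(0),
    spacer_start = integer(0), spacer_end = integer(0),
    spacer_length = integer(0), n_motifs = integer(0), motifs = list()
  )
  if (nrow(left) == 0L || nrow(right) == 0L || nrow(motifs) == 0L) return(empty)

  right_key <- split(seq_len(nrow(right)), right$start)
  rows <- list()
  for (sp in params$spacer_len_min:params$spacer_len_max) {
    r_start <- left$end + sp
    key <- if (circ) r_start %% L else r_start
    for (i in seq_len(nrow(left))) {
      if (!circ && key[[i]] + params$tale_len_min > L) next
      hits <- right_key[[as.character(key[[i]])]]
      if (is.null(hits)) next
      sp_start <- if (circ) left$end[[i]] %% L else left$end[[i]]
      keep <- motif_in_spacer(motifs$c_pos, motifs$strand, sp_start, sp,
                              L, circ, params$spacer_motif_rule)
      if (!any(keep)) next
      mot <- motifs[keep, c("c_pos", "strand")]
      if (!is.null(contain) && !any(mot$c_pos == contain)) next
      for (j in hits) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          left_start = left$start[[i]], left_end = left$end[[i]],
          left_length = left$length[[i]],
          right_start = right$start[[j]],
          right_end = right$start[[j]] + right$length[[j]],
          right_length = right$length[[j]],
          spacer_start = sp_start, spacer_end = sp_start + sp,
          spacer_length = sp, n_motifs = nrow(mot), motifs = list(mot)
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$spacer_start, .data$spacer_length,
                 .data$left_length, .data$right_length)
}

#' Enumerate monomeric mDdCBE designs
#'
#' For every TALE site (either strand), lists the TC motifs (either strand)
#' whose anchored base lies at strand-relative offset 1..`mono_window`
#' downstream of the site's 3'-terminal thymidine. The reported `offset` is
#' always the distance to the target cytosine; when `window_anchor = "t"`
#' eligibility is measured to the motif's T instead (so eligible C offsets
#' are 2..`mono_window + 1`). Only sites reaching at least one motif are
#' returned.
#'
#' @inheritParams find_ddcbe_designs
#' @param contain Optional 0-based coordinate of a target C; only designs
#'   reaching it are returned.
#' @return A tibble with one row per design: `site_start`, `site_end`,
#'   `site_strand`, `site_length`, `t3_pos` (forward coordinate of the
#'   3'-terminal thymidine), `n_motifs`, and a `motifs` list-column
#'   (`c_pos`, `strand`, `offset`).
#' @export
find_mddcbe_designs <- function(genome, params = scan_params(), contain = NULL) {
  stopifnot(inherits(genome, "dd_genome"), inherits(params, "dd_scan_params"))
  L <- genome$length
  circ <- genome$circular
  W <- params$mono_window
  motifs <- find_tc_motifs(genome)
  if (!is.null(contain)) motifs <- motifs[motifs$c_pos %in% contain, ]
  empty <- tibble::tibble(
    site_start = integer(0), site_end = integer(0), site_strand = character(0),
    site_length = integer(0), t3_pos = integer(0), n_motifs = integer(0),
    motifs = list()
  )
  if (nrow(motifs) == 0L) return(empty)
  flags <- scan_site_flags(genome, params)

  anchor0 <- motif_anchor(motifs$c_pos, motifs$strand, params$window_anchor,
                          L, circ)
  keep <- !is.na(anchor0)
  motifs <- motifs[keep, ]
  anchor0 <- anchor0[keep]
  if (nrow(motifs) == 0L) return(empty)

  # (t3, site_strand, motif, offset) hits; offsets measured at the anchor,
  # the recorded offset is re-expressed at the C below. On a circular genome
  # distinct offsets only exist up to L - 1.
  hit <- list()
  W_eff <- if (circ) min(W, L - 1L) else W
  for (k in seq_len(W_eff)) {
    up <- anchor0 - k            # + strand site 3' T upstream of the motif
    dn <- anchor0 + k            # - strand site 3' T downstream
    if (circ) {
      up <- ((up %% L) + L) %% L
      dn <- dn %% L
      ok_up <- flags$top_t3[up + 1L]
      ok_dn <- flags$bot_t3[dn + 1L]
    } else {
      ok_up <- up >= 0L & flags$top_t3[pmax(up, 0L) + 1L]
      ok_dn <- dn < L & flags$bot_t3[pmin(dn, L - 1L) + 1L]
    }
    if (any(ok_up)) {
      hit[[length(hit) + 1L]] <- tibble::tibble(
        t3_pos = up[ok_up], site_strand = "+",
        c_pos = motifs$c_pos[ok_up], m_strand = motifs$strand[ok_up])
    }
    if (any(ok_dn)) {
      hit[[length(hit) + 1L]] <- tibble::tibble(
        t3_pos = dn[ok_dn], site_strand = "-",
        c_pos = motifs$c_pos[ok_dn], m_strand = motifs$strand[ok_dn])
    }
  }
  if (length(hit) == 0L) return(empty)
  hits <- dplyr::distinct(dplyr::bind_rows(hit))
  # offset to the C itself (strand-relative distance from the 3' T)
  hits$offset <- ifelse(
    hits$site_strand == "+",
    if (circ) (hits$c_pos - hits$t3_pos) %% L else hits$c_pos - hits$t3_pos,
    if (circ) (hits$t3_pos - hits$c_pos) %% L else hits$t3_pos - hits$c_pos)

  sites <- enumerate_tale_sites(genome, params)
  sites$t3_pos <- ifelse(sites$strand == "+",
                         if (circ) (sites$end - 1L) %% L else sites$end - 1L,
                         sites$start)
  joined <- dplyr::inner_join(
    dplyr::rename(sites, site_start = "start", site_end = "end",
                  site_strand = "strand", site_length = "length"),
    hits, by = c("t3_pos", "site_strand"), relationship = "many-to-many")
  if (nrow(joined) == 0L) return(empty)
  nested <- joined |>
    dplyr::arrange(.data$site_start, .data$site_length, .data$site_strand,
                   .data$offset, .data$c_pos) |>
    dplyr::group_by(.data$site_start, .data$site_end, .data$site_strand,
                    .data$site_length, .data$t3_pos) |>
    tidyr::nest(motifs = c("c_pos", "m_strand", "offset")) |>
    dplyr::ungroup()
  nested$motifs <- purrr::map(nested$motifs, function(m) {
    names(m)[names(m) == "m_strand"] <- "strand"
    m
  })
  nested$n_motifs <- vapply(nested$motifs, nrow, integer(1))
  nested[, c("site_start", "site_end", "site_strand", "site_length",
             "t3_pos", "n_motifs", "motifs")]
}

# Forward-strand coordinate of the base used to measure the monomeric
# window: the C itself, or the motif's T when anchored at "t". NA when the
# anchored base falls off a linear genome (cannot happen for valid motifs).
motif_anchor <- function(c_pos, strand, anchor, L, circular) {
  if (anchor == "c") return(c_pos)
  a <- ifelse(strand == "+", c_pos - 1L, c_pos + 1L)
  if (circular) ((a %% L) + L) %% L else ifelse(a < 0L | a >= L, NA_integer_, a)
}

# Vectorized per-motif editability flags; the engine behind
# editability_report(). Cross-checked in the tests against the design-based
# enumerators on small genomes.
editable_motif_flags <- function(genome, params) {
  L <- genome$length
  circ <- genome$circular
  motifs <- find_tc_motifs(genome)
  flags <- scan_site_flags(genome, params)
  n <- nrow(motifs)
  if (n == 0L) {
    motifs$ddcbe <- logical(0)
    motifs$mddcbe <- logical(0)
    return(motifs)
  }

  # --- dimeric: positions covered by a valid spacer ---
  # left_end[e] : a + site ends (exclusive) at e; right_start[s] : a - site
  # starts at s. For each spacer length sp, mark coverage of the positions a
  # motif may occupy under the membership rule using a difference array on a
  # doubled (circular) or padded (linear) axis.
  left_end <- shift_flags(flags$top_t3, -1L, circ)   # left_end[e] = top_t3[e-1]
  right_start <- flags$bot_t3
  span <- if (circ) 2L * L else L + params$spacer_len_max + 2L
  delta <- integer(span + 1L)
  for (sp in params$spacer_len_min:params$spacer_len_max) {
    ilen <- if (params$spacer_motif_rule == "dinucleotide") sp - 1L else sp
    if (ilen <= 0L) next
    pair_ok <- left_end & shift_flags(right_start, sp, circ)
    b0 <- which(pair_ok) - 1L
    if (length(b0) == 0L) next
    add <- tabulate(b0 + 1L, nbins = span)
    sub <- tabulate(b0 + ilen + 1L, nbins = span)
    delta[seq_len(span)] <- delta[seq_len(span)] + add - sub
  }
  cov <- cumsum(delta[seq_len(span)]) > 0L
  covered_at <- function(x0) {
    if (circ) {
      x0 <- ((x0 %% L) + L) %% L
      cov[x0 + 1L] | cov[x0 + L + 1L]
    } else {
      ok <- x0 >= 0L & x0 < span
      out <- rep(FALSE, length(x0))
      out[ok] <- cov[x0[ok] + 1L]
      out
    }
  }
  probe0 <- if (params$spacer_motif_rule == "dinucleotide") {
    ifelse(motifs$strand == "+", motifs$c_pos - 1L, motifs$c_pos)
  } else {
    motifs$c_pos
  }
  ddcbe <- covered_at(probe0)

  # --- monomeric: a 3'-terminal T within mono_window on either side ---
  W <- min(params$mono_window, L - 1L)
  near_top <- any_in_window(flags$top_t3, -W, -1L, circ)  # upstream + site
  near_bot <- any_in_window(flags$bot_t3, 1L, W, circ)    # downstream - site
  anchor0 <- motif_anchor(motifs$c_pos, motifs$strand, params$window_anchor,
                          L, circ)
  mddcbe <- rep(FALSE, n)
  ok <- !is.na(anchor0)
  mddcbe[ok] <- near_top[anchor0[ok] + 1L] | near_bot[anchor0[ok] + 1L]

  motifs$ddcbe <- ddcbe
  motifs$mddcbe <- mddcbe
  motifs
}

#' Genome-wide editability report (dimeric vs monomeric reach)
#'
#' Classifies every TC motif of the genome by which editor architecture can
#' reach it: a dimeric DdCBE pair (motif inside a valid 14-18 bp spacer
#' between convergent TALE sites), a monomeric mDdCBE (motif within the
#' 18 bp window downstream of a single site's 3'-terminal thymidine), both,
#' or neither. Editability is set membership: a motif reachable through many
#' placements is counted once. The headline quantity is the fraction of all
#' motifs reachable by the monomeric editor only.
#'
#' When `sensitivity = TRUE` the report also tabulates the counts under the
#' alternative conventions (window anchor C vs T, circular vs linear
#' topology, and both spacer membership rules), so the effect of each choice
#' on the headline fraction is visible.
#'
#' @param genome A [dd_genome()].
#' @param params A [scan_params()].
#' @param sensitivity Tabulate counts under alternative conventions.
#' @return A `dd_editability` object with elements `motifs` (per-motif
#'   tibble with `ddcbe`, `mddcbe` flags and an `editable_by` category),
#'   `counts` (named list), `params`, and optionally `sensitivity`
#'   (a tibble). `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @examples
#' g <- dd_genome(paste0("TGGGGGGGGGGGGT", "GGGGGGTCGGGGGG", "AGGGGGGGGGGGGA"),
#'                circular = FALSE)
#' glance(editability_report(g, sensitivity = FALSE))
#' @export
editability_report <- function(genome, params = scan_params(),
                               sensitivity = TRUE) {
  stopifnot(inherits(genome, "dd_genome"), inherits(params, "dd_scan_params"))
  motifs <- editable_motif_flags(genome, params)
  motifs$editable_by <- dplyr::case_when(
    motifs$ddcbe & motifs$mddcbe ~ "both",
    motifs$ddcbe ~ "ddcbe",
    motifs$mddcbe ~ "mddcbe",
    TRUE ~ "none"
  )
  counts <- report_counts(motifs)
  if (counts$total_motifs == 0L) {
    warning("genome contains no TC motifs; fraction reported as 0",
            call. = FALSE)
  }
  sens <- NULL
  if (sensitivity) {
    grid <- expand.grid(window_anchor = c("c", "t"),
                        topology = c("circular", "linear"),
                        spacer_motif_rule = c("dinucleotide", "c_only"),
                        stringsAsFactors = FALSE)
    sens <- purrr::pmap_dfr(grid, function(window_anchor, topology,
                                           spacer_motif_rule) {
      g2 <- genome
      g2$circular <- topology == "circular"
      p2 <- params
      p2$window_anchor <- window_anchor
      p2$spacer_motif_rule <- spacer_motif_rule
      m2 <- editable_motif_flags(g2, p2)
      cbind(tibble::tibble(window_anchor = window_anchor, topology = topology,
                           spacer_motif_rule = spacer_motif_rule),
            tibble::as_tibble(report_counts(m2)))
    })
  }
  structure(
    list(motifs = motifs, counts = counts, params = params,
         sensitivity = sens, genome_name = genome$name,
         genome_length = genome$length,
         topology = if (genome$circular) "circular" else "linear"),
    class = "dd_editability"
  )
}

report_counts <- function(motifs) {
  total <- nrow(motifs)
  dd <- sum(motifs$ddcbe)
  md <- sum(motifs$mddcbe)
  only <- sum(motifs$mddcbe & !motifs$ddcbe)
  list(
    total_motifs = total,
    ddcbe_editable = dd,
    mddcbe_editable = md,
    mddcbe_only = only,
    mddcbe_only_fraction = if (total > 0L) 100 * only / total else 0
  )
}

#' @export
print.dd_editability <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("<dd_editability> %s (%s bp, %s)\n", x$genome_name,
              format(x$genome_length, big.mark = ","), x$topology))
  cat(sprintf("  TC motifs: %d | DdCBE-editable: %d | mDdCBE-editable: %d\n",
              c0$total_motifs, c0$ddcbe_editable, c0$mddcbe_editable))
  cat(sprintf("  mDdCBE-only: %d (%.1f%% of all motifs)\n",
              c0$mddcbe_only, c0$mddcbe_only_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname editability_report
#' @param x A `dd_editability` object.
#' @param ... Unused.
#' @method tidy dd_editability
#' @export
tidy.dd_editability <- function(x, ...) x$motifs

#' @rdname editability_report
#' @method glance dd_editability
#' @export
glance.dd_editability <- function(x, ...) {
  tibble::as_tibble(x$counts)
}

#' @rdname editability_report
#' @param object A `dd_editability` object.
#' @method autoplot dd_editability
#' @export
autoplot.dd_editability <- function(object, ...) {
  m <- object$motifs
  m$editable_by <- factor(m$editable_by,
                          levels = c("both", "ddcbe", "mddcbe", "none"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$editable_by)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(
      x = "editable by", y = "TC motifs",
      title = sprintf("%s: %.1f%% of motifs are mDdCBE-only",
                      object$genome_name,
                      object$counts$mddcbe_only_fraction)) +
    ggplot2::theme_minimal()
}
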