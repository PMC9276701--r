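# Independent brute-force oracle: a literal, loop-based re-statement of the
# selection criteria, sharing no code with the package internals. Everything
# works on a plain sequence string with 0-based coordinates.

o_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

o_char <- function(seq, i0, circ) {
  L <- nchar(seq)
  if (circ) i0 <- ((i0 %% L) + L) %% L
  if (i0 < 0 || i0 >= L) return(NA_character_)
  substr(seq, i0 + 1, i0 + 1)
}

o_window <- function(seq, start, len, circ) {
  paste(vapply(start:(start + len - 1), function(i) o_char(seq, i, circ), ""),
        collapse = "")
}

o_motifs <- function(seq, circ) {
  L <- nchar(seq)
  rows <- list()
  for (i in 0:(L - 1)) {
    a <- o_char(seq, i - 1, circ)
    b <- o_char(seq, i, circ)
    d <- o_char(seq, i + 1, circ)
    if (!is.na(a) && a == "T" && b == "C") {
      rows[[length(rows) + 1]] <- data.frame(c_pos = i, strand = "+")
    }
    if (b == "G" && !is.na(d) && d == "A") {
      rows[[length(rows) + 1]] <- data.frame(c_pos = i, strand = "-")
    }
  }
  if (length(rows) == 0) {
    return(data.frame(c_pos = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$c_pos, out$strand), , drop = FALSE]
}

o_sites <- function(seq, circ, lmin = 14, lmax = 20, require_t = TRUE) {
  L <- nchar(seq)
  rows <- list()
  for (len in lmin:min(lmax, L)) {
    starts <- if (circ) 0:(L - 1) else if (L >= len) 0:(L - len) else integer(0)
    for (s in starts) {
      w <- o_window(seq, s, len, circ)
      plus <- w
      minus <- o_revcomp(w)
      if (!require_t ||
          (substr(plus, 1, 1) == "T" && substr(plus, len, len) == "T")) {
        rows[[length(rows) + 1]] <- data.frame(start = s, len = len,
                                               strand = "+")
      }
      if (!require_t ||
          (substr(minus, 1, 1) == "T" && substr(minus, len, len) == "T")) {
        rows[[length(rows) + 1]] <- data.frame(start = s, len = len,
                                               strand = "-")
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), len = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$len, out$strand), , drop = FALSE]
}

o_pos_in <- function(x, from, len, L, circ) {
  if (circ) ((x - from) %% L) < len else (x >= from && x < from + len)
}

o_motif_in_spacer <- function(c_pos, strand, b, sp, L, circ, rule) {
  if (rule == "c_only") return(o_pos_in(c_pos, b, sp, L, circ))
  first <- if (strand == "+") c_pos - 1 else c_pos
  if (circ) first <- ((first %% L) + L) %% L
  second <- if (circ) (first + 1) %% L else first + 1
  o_pos_in(first, b, sp, L, circ) && o_pos_in(second, b, sp, L, circ)
}

# Every (left + site, right - site) pair with an allowed spacer containing at
# least one motif; returns one row per (pair, motif).
o_ddcbe <- function(seq, circ, spmin = 14, spmax = 18, rule = "dinucleotide",
                    lmin = 14, lmax = 20) {
  L <- nchar(seq)
  sites <- o_sites(seq, circ, lmin, lmax)
  motifs <- o_motifs(seq, circ)
  left <- sites[sites$strand == "+", , drop = FALSE]
  right <- sites[sites$strand == "-", , drop = FALSE]
  rows <- list()
  if (nrow(left) == 0 || nrow(right) == 0 || nrow(motifs) == 0) {
    return(data.frame(left_start = integer(0), left_len = integer(0),
                      right_start = integer(0), right_len = integer(0),
                      spacer = integer(0), c_pos = integer(0),
                      strand = character(0)))
  }
  for (i in seq_len(nrow(left))) {
    e <- left$start[i] + left$len[i]
    for (j in seq_len(nrow(right))) {
      sp <- if (circ) ((right$start[j] - e) %% L + L) %% L
            else right$start[j] - e
      if (is.na(sp) || sp < spmin || sp > spmax) next
      b <- if (circ) ((e %% L) + L) %% L else e
      for (m in seq_len(nrow(motifs))) {
        if (o_motif_in_spacer(motifs$c_pos[m], motifs$strand[m], b, sp, L,
                              circ, rule)) {
          rows[[length(rows) + 1]] <- data.frame(
            left_start = left$start[i], left_len = left$len[i],
            right_start = right$start[j], right_len = right$len[j],
            spacer = sp, c_pos = motifs$c_pos[m], strand = motifs$strand[m])
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(left_start = integer(0), left_len = integer(0),
                      right_start = integer(0), right_len = integer(0),
                      spacer = integer(0), c_pos = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, rows)
}

# Every (site, motif) pair where the anchored base sits at strand-relative
# offset 1..W downstream of the site's 3'-terminal thymidine.
o_mddcbe <- function(seq, circ, W = 18, anchor = "c", lmin = 14, lmax = 20) {
  L <- nchar(seq)
  sites <- o_sites(seq, circ, lmin, lmax)
  motifs <- o_motifs(seq, circ)
  rows <- list()
  if (nrow(sites) > 0 && nrow(motifs) > 0) {
    for (i in seq_len(nrow(sites))) {
      t3 <- if (sites$strand[i] == "+") sites$start[i] + sites$len[i] - 1
            else sites$start[i]
      if (circ) t3 <- ((t3 %% L) + L) %% L
      for (m in seq_len(nrow(motifs))) {
        ap <- if (anchor == "c") motifs$c_pos[m]
              else if (motifs$strand[m] == "+") motifs$c_pos[m] - 1
              else motifs$c_pos[m] + 1
        if (circ) ap <- ((ap %% L) + L) %% L
        else if (ap < 0 || ap >= L) next
        d <- if (sites$strand[i] == "+") ap - t3 else t3 - ap
        if (circ) d <- ((d %% L) + L) %% L
        if (d >= 1 && d <= min(W, if (circ) L - 1 else W)) {
          off_c <- if (sites$strand[i] == "+") motifs$c_pos[m] - t3
                   else t3 - motifs$c_pos[m]
          if (circ) off_c <- ((off_c %% L) + L) %% L
          rows[[length(rows) + 1]] <- data.frame(
            site_start = sites$start[i], site_len = sites$len[i],
            site_strand = sites$strand[i], c_pos = motifs$c_pos[m],
            strand = motifs$strand[m], offset = off_c)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site_start = integer(0), site_len = integer(0),
                      site_strand = character(0), c_pos = integer(0),
                      strand = character(0), offset = integer(0)))
  }
  do.call(rbind, rows)
}

# Editability counts from the brute-force design sets.
o_report <- function(seq, circ, rule = "dinucleotide", anchor = "c",
                     W = 18, spmin = 14, spmax = 18) {
  motifs <- o_motifs(seq, circ)
  key <- function(df) paste(df$c_pos, df$strand)
  dd <- unique(key(o_ddcbe(seq, circ, spmin, spmax, rule)))
  md <- unique(key(o_mddcbe(seq, circ, W, anchor)))
  all_keys <- key(motifs)
  list(total = nrow(motifs),
       dd = sum(all_keys %in% dd),
       md = sum(all_keys %in% md),
       only = sum(all_keys %in% md & !(all_keys %in% dd)))
}
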