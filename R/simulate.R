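#' Planting directives for synthetic genomes
#'
#' Each directive describes a structure written into a simulated genome at a
#' fixed position, so the scan stages can be validated against known truth:
#' a bare TC motif, a monomeric design (TALE site plus a target motif at a
#' chosen offset), or a dimeric design (left site, spacer with one motif,
#' right site). Planted sequences use G/C filler so they introduce no
#' unintended thymidine-ended TALE sites of their own; the random background
#' around them may still contain designs, which is realistic and harmless
#' for round-trip recovery tests.
#'
#' @param at 0-based start coordinate of the planted segment.
#' @param strand Strand of a bare motif.
#' @param target_offset Offset (1-based, from the site's 3'-terminal T) of
#'   the planted target C of a monomeric design.
#' @param site_length,left_length,right_length TALE site lengths (bp).
#' @param spacer_length Dimeric spacer length (bp).
#' @param motif_index 0-based index of the planted C within the spacer
#'   (defaults to the spacer midpoint; must leave the T of the motif inside
#'   the spacer, i.e. be >= 1).
#' @return A planting directive (list) for [simulate_genome()].
#' @name planting
NULL

#' @rdname planting
#' @export
plant_tc_motif <- function(at, strand = "+") {
  check_strand(strand)
  segment <- if (strand == "+") "TC" else "GA"
  c_pos <- if (strand == "+") at + 1L else at
  list(type = "tc_motif", at = as.integer(at), segment = segment,
       c_pos = as.integer(c_pos), strand = strand)
}

#' @rdname planting
#' @export
plant_mddcbe_site <- function(at, target_offset = 5L, site_length = 14L) {
  at <- as.integer(at)
  target_offset <- as.integer(target_offset)
  site_length <- as.integer(site_length)
  stopifnot(target_offset >= 1L, site_length >= 3L)
  site <- paste0("T", strrep("G", site_length - 2L), "T")
  tail <- if (target_offset == 1L) {
    "C"
  } else {
    paste0(strrep("G", target_offset - 2L), "TC")
  }
  t3 <- at + site_length - 1L
  list(type = "mddcbe_site", at = at, segment = paste0(site, tail),
       site_start = at, site_end = at + site_length, t3_pos = t3,
       c_pos = t3 + target_offset, strand = "+",
       target_offset = target_offset)
}

#' @rdname planting
#' @export
plant_ddcbe_pair <- function(at, spacer_length = 14L, motif_index = NULL,
                             left_length = 14L, right_length = 14L) {
  at <- as.integer(at)
  spacer_length <- as.integer(spacer_length)
  left_length <- as.integer(left_length)
  right_length <- as.integer(right_length)
  if (is.null(motif_index)) motif_index <- spacer_length %/% 2L
  motif_index <- as.integer(motif_index)
  stopifnot(motif_index >= 1L, motif_index <= spacer_length - 1L,
            left_length >= 3L, right_length >= 3L)
  left <- paste0("T", strrep("G", left_length - 2L), "T")
  spacer <- paste0(strrep("G", motif_index - 1L), "TC",
                   strrep("G", spacer_length - motif_index - 1L))
  right <- paste0("A", strrep("C", right_length - 2L), "A")
  sp_start <- at + left_length
  list(type = "ddcbe_pair", at = at,
       segment = paste0(left, spacer, right),
       left_start = at, left_end = sp_start,
       spacer_start = sp_start, spacer_end = sp_start + spacer_length,
       right_start = sp_start + spacer_length,
       right_end = sp_start + spacer_length + right_length,
       c_pos = sp_start + motif_index, strand = "+",
       spacer_length = spacer_length)
}

#' Generate a synthetic genome with planted designs
#'
#' Draws a random background at the requested GC fraction and writes the
#' planting directives over it. The same seed always yields a byte-identical
#' sequence.
#'
#' @param length Genome length (bp).
#' @param gc_fraction Background GC content.
#' @param circular Topology flag of the returned genome.
#' @param planted List of directives from [plant_tc_motif()],
#'   [plant_mddcbe_site()] or [plant_ddcbe_pair()]; segments must fit within
#'   the genome without overlapping each other.
#' @param seed Integer seed; fully determines the output.
#' @param name Name of the generated genome.
#' @return A list with elements `genome` (a [dd_genome()]) and `truth`
#'   (a tibble describing every planted element).
#' @export
simulate_genome <- function(length, gc_fraction = 0.44, circular = TRUE,
                            planted = list(), seed = 1L, name = "sim") {
  length <- as.integer(length)
  stopifnot(length >= 1L, gc_fraction >= 0, gc_fraction <= 1)
  segs <- lapply(planted, function(d) {
    stopifnot(is.list(d), !is.null(d$type))
    c(d["at"], list(len = nchar(d$segment)))
  })
  if (length(segs) > 0L) {
    ord <- order(vapply(segs, function(s) s$at, integer(1)))
    prev_end <- -1L
    for (i in ord) {
      s <- segs[[i]]
      if (s$at < 0L || s$at + s$len > length) {
        stop("planted segment [", s$at, ", ", s$at + s$len,
             ") does not fit in genome of length ", length, call. = FALSE)
      }
      if (s$at < prev_end) {
        stop("planted segments overlap at position ", s$at, call. = FALSE)
      }
      prev_end <- s$at + s$len
    }
  }
  ch <- withr::with_seed(seed, {
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                    gc_fraction / 2, (1 - gc_fraction) / 2))
  })
  for (d in planted) {
    seg <- strsplit(d$segment, "", fixed = TRUE)[[1]]
    ch[(d$at + 1L):(d$at + length(seg))] <- seg
  }
  genome <- dd_genome(paste(ch, collapse = ""), name = name,
                      circular = circular)
  truth <- purrr::map_dfr(planted, function(d) {
    tibble::tibble(
      type = d$type, at = d$at,
      c_pos = d$c_pos %||% NA_integer_,
      strand = d$strand %||% NA_character_,
      site_start = d$site_start %||% d$left_start %||% NA_integer_,
      site_end = d$site_end %||% d$left_end %||% NA_integer_,
      target_offset = d$target_offset %||% NA_integer_,
      spacer_start = d$spacer_start %||% NA_integer_,
      spacer_end = d$spacer_end %||% NA_integer_,
      spacer_length = d$spacer_length %||% NA_integer_
    )
  })
  list(genome = genome, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Programmed substitutions for the read simulator
#'
#' Describes the per-position alternate-base fractions a simulated read set
#' should carry: programmed editing (C->T at reference C, G->A at reference
#' G), fixed-fraction cell-line SNVs (e.g. fraction 1.0 for homoplasmic),
#' and a uniform per-base sequencing error rate.
#'
#' @param per_position Data frame of programmed edits: columns `pos`
#'   (0-based), `fraction`, and optionally `alt` (defaults to the
#'   deamination product of the reference base).
#' @param snv_positions Data frame of SNVs with the same columns.
#' @param sequencing_error_rate Per-base error probability (errors go to a
#'   uniformly random different base).
#' @param depth Reads covering each position (exact, by uniform tiling).
#' @param read_length Read length (bp).
#' @param seed Integer seed; fully determines the read set.
#' @return A validated `dd_edit_spec` list.
#' @export
edit_spec <- function(per_position = NULL, snv_positions = NULL,
                      sequencing_error_rate = 0, depth = 100L,
                      read_length = 100L, seed = 1L) {
  norm <- function(df, origin) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    stopifnot(all(c("pos", "fraction") %in% names(df)))
    out <- tibble::tibble(pos = as.integer(df$pos),
                          fraction = as.numeric(df$fraction),
                          alt = if ("alt" %in% names(df))
                            as.character(df$alt) else NA_character_,
                          origin = origin)
    if (any(out$fraction < 0 | out$fraction > 1)) {
      stop("programmed fractions must be in [0, 1]", call. = FALSE)
    }
    out
  }
  programmed <- dplyr::bind_rows(norm(per_position, "edit"),
                                 norm(snv_positions, "snv"))
  if (nrow(programmed) == 0L) programmed <- NULL
  p <- list(
    programmed = programmed,
    sequencing_error_rate = as.numeric(sequencing_error_rate),
    depth = as.integer(depth),
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  )
  stopifnot(p$sequencing_error_rate >= 0, p$sequencing_error_rate <= 1,
            p$depth >= 0L, p$read_length >= 1L)
  if (!is.null(p$programmed) && anyDuplicated(p$programmed$pos) > 0L) {
    stop("duplicate programmed positions", call. = FALSE)
  }
  structure(p, class = "dd_edit_spec")
}

#' Simulate an aligned read set with programmed substitutions
#'
#' Emits pre-aligned, coordinate-sorted SAM records tiling the genome
#' uniformly so that every position is covered by exactly `depth` reads
#' (reads never wrap the origin: the sequence is tiled as written). At each
#' programmed position the alternate base is drawn independently per read at
#' the programmed fraction; sequencing errors are then applied independently
#' at the spec's rate. Base qualities are uniform high (Phred 40) and
#' mapping quality 60, so default caller filters keep every base. The same
#' spec and seed always produce byte-identical output.
#'
#' @param genome A [dd_genome()].
#' @param spec An [edit_spec()]; `read_length` must not exceed the genome
#'   length.
#' @param sam Output SAM path.
#' @param fastq Optional FASTQ path for users who want to run a real
#'   aligner.
#' @return A list with elements `sam`, `fastq` and `truth` (the programmed
#'   table plus simulation parameters).
#' @export
simulate_reads <- function(genome, spec, sam, fastq = NULL) {
  stopifnot(inherits(genome, "dd_genome"), inherits(spec, "dd_edit_spec"))
  L <- genome$length
  if (spec$read_length > L) {
    stop("read_length ", spec$read_length, " exceeds genome length ", L,
         call. = FALSE)
  }
  ref <- genome$sequence
  prog <- spec$programmed
  if (!is.null(prog) && nrow(prog) > 0L) {
    if (any(prog$pos < 0L | prog$pos >= L)) {
      stop("programmed position outside genome", call. = FALSE)
    }
    ref_base <- substring(ref, prog$pos + 1L, prog$pos + 1L)
    default_alt <- dplyr::case_when(ref_base == "C" ~ "T",
                                    ref_base == "G" ~ "A",
                                    TRUE ~ NA_character_)
    prog$alt <- ifelse(is.na(prog$alt), default_alt, prog$alt)
    if (any(is.na(prog$alt))) {
      bad <- prog$pos[is.na(prog$alt)][[1]]
      stop("programmed conversion at position ", bad, " (reference ",
           substring(ref, bad + 1L, bad + 1L), "): only C->T and G->A are ",
           "implied; give an explicit alt", call. = FALSE)
    }
    prog$ref <- ref_base
    prog <- dplyr::arrange(prog, .data$pos)
  }

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$name, L),
              "@PG\tID:ddcbetools\tPN:ddcbetools")
  if (spec$depth == 0L) {
    readr::write_lines(header, sam)
    if (!is.null(fastq)) readr::write_lines(character(0), fastq)
    return(list(sam = sam, fastq = fastq,
                truth = sim_truth(genome, spec, prog)))
  }

  starts <- seq(0L, L - 1L, by = spec$read_length)
  body <- withr::with_seed(spec$seed, {
    lines <- vector("list", length(starts))
    for (ti in seq_along(starts)) {
      s0 <- starts[[ti]]
      len <- min(spec$read_length, L - s0)
      tile_seq <- substring(ref, s0 + 1L, s0 + len)
      reads <- rep(tile_seq, spec$depth)
      if (!is.null(prog) && nrow(prog) > 0L) {
        here <- prog[prog$pos >= s0 & prog$pos < s0 + len, , drop = FALSE]
        for (k in seq_len(nrow(here))) {
          flip <- which(stats::runif(spec$depth) < here$fraction[[k]])
          if (length(flip) > 0L) {
            off <- here$pos[[k]] - s0 + 1L
            substr(reads[flip], off, off) <- here$alt[[k]]
          }
        }
      }
      if (spec$sequencing_error_rate > 0) {
        n_err <- stats::rbinom(spec$depth, len, spec$sequencing_error_rate)
        for (j in which(n_err > 0L)) {
          at <- sample.int(len, n_err[[j]])
          for (a in at) {
            cur <- substr(reads[[j]], a, a)
            substr(reads[j], a, a) <- sample(setdiff(c("A", "C", "G", "T"),
                                                     cur), 1L)
          }
        }
      }
      qual <- strrep("I", len)
      lines[[ti]] <- sprintf("t%05d_l%05d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                             ti, seq_len(spec$depth), genome$name, s0 + 1L,
                             len, reads, qual)
    }
    lines
  })
  readr::write_lines(c(header, unlist(body)), sam)
  if (!is.null(fastq)) {
    fields <- strsplit(unlist(body), "\t", fixed = TRUE)
    qnames <- vapply(fields, `[[`, "", 1L)
    seqs <- vapply(fields, `[[`, "", 10L)
    quals <- vapply(fields, `[[`, "", 11L)
    readr::write_lines(as.vector(rbind(paste0("@", qnames), seqs, "+", quals)),
                       fastq)
  }
  list(sam = sam, fastq = fastq, truth = sim_truth(genome, spec, prog))
}

sim_truth <- function(genome, spec, prog) {
  list(genome = genome$name, genome_length = genome$length,
       depth = spec$depth, read_length = spec$read_length,
       sequencing_error_rate = spec$sequencing_error_rate,
       seed = spec$seed,
       programmed = prog %||% tibble::tibble(pos = integer(0),
                                             fraction = numeric(0),
                                             alt = character(0),
                                             origin = character(0),
                                             ref = character(0)))
}
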