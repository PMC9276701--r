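#' Genome objects for base-editor target scanning
#'
#' A `dd_genome` is a single named nucleotide sequence together with a
#' topology flag. All coordinates in this package are 0-based, half-open, on
#' the forward (reference) strand; strand-specific sequences are derived
#' views. On circular genomes, coordinates are taken modulo the genome
#' length, so windows may span the origin junction.
#'
#' @param sequence A single string over the alphabet A/C/G/T/N. Lowercase
#'   letters and U are normalized (to uppercase / T); any other character is
#'   an error.
#' @param name Identifier for the sequence.
#' @param circular Logical topology flag. Organellar genomes (mtDNA,
#'   chloroplast DNA) are circular; the default is `TRUE`.
#' @return A `dd_genome` object: a list with fields `name`, `sequence`,
#'   `circular` and `length`.
#' @examples
#' g <- dd_genome("acgtACGT", name = "toy", circular = FALSE)
#' g$length
#' @export
dd_genome <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  seq <- normalize_sequence(sequence, name)
  if (nchar(seq) < 1L) {
    stop("genome '", name, "' is empty", call. = FALSE)
  }
  structure(
    list(name = name, sequence = seq, circular = isTRUE(circular),
         length = nchar(seq)),
    class = "dd_genome"
  )
}

normalize_sequence <- function(sequence, name) {
  seq <- chartr("u", "T", chartr("U", "T", toupper(sequence)))
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    stop("record '", name, "' contains non-nucleotide characters after ",
         "normalization: ", paste(unique(strsplit(bad, "")[[1]]), collapse = " "),
         call. = FALSE)
  }
  seq
}

#' @export
print.dd_genome <- function(x, ...) {
  cat(sprintf("<dd_genome> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  head_n <- min(x$length, 60L)
  cat(substr(x$sequence, 1L, head_n), if (x$length > head_n) "..." else "",
      "\n", sep = "")
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' Reads one or all records of a (multi-)FASTA file into [dd_genome()]
#' objects. Sequences are normalized to uppercase; record identifiers are
#' preserved as names. Topology is set from the `circular` flag, defaulting
#' to circular for organellar use.
#'
#' @param path Path to a FASTA file.
#' @param circular Topology flag applied to every record.
#' @param all If `TRUE`, return a list of all records (in input order);
#'   otherwise return the first record.
#' @return A `dd_genome`, or a list of them when `all = TRUE`.
#' @export
read_genome_fasta <- function(path, circular = TRUE, all = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  genomes <- lapply(seq_along(set), function(i) {
    dd_genome(as.character(set[[i]]), name = ids[[i]], circular = circular)
  })
  if (all) genomes else genomes[[1L]]
}

#' Write a genome to a FASTA file
#'
#' @param genome A [dd_genome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "dd_genome"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' The packaged human mitochondrial reference genome (rCRS)
#'
#' Returns the revised Cambridge Reference Sequence (NC_012920), the standard
#' human mitochondrial genome reference (16,569 bp, circular), which ships
#' with the package as a plain-text FASTA. The single ambiguous position
#' (3107, 1-based) is an N placeholder kept for historical coordinate
#' stability.
#'
#' @return A circular [dd_genome()] named `NC_012920`.
#' @export
rcrs_genome <- function() {
  path <- system.file("extdata", "NC_012920.fasta", package = "ddcbetools",
                      mustWork = TRUE)
  read_genome_fasta(path, circular = TRUE)
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick reverse complement over A/C/G/T/N (N maps to N).
#' Applying it twice returns the input.
#'
#' @param seq A nucleotide string (alphabet A/C/G/T/N after normalization).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("TC")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- normalize_sequence(seq, "<input>")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a window of sequence, strand- and circularity-aware
#'
#' Returns the `length`-base window starting at 0-based coordinate `start`,
#' read 5'->3' on the requested strand. On circular genomes coordinates are
#' taken modulo the genome length, so windows may wrap the origin junction;
#' on linear genomes out-of-bounds windows are an error.
#'
#' @param genome A [dd_genome()].
#' @param start 0-based forward-strand coordinate of the window start
#'   (leftmost base on the forward strand).
#' @param length Number of bases (>= 1, and at most the genome length).
#' @param strand `"+"` or `"-"`.
#' @return A nucleotide string of `length` bases.
#' @examples
#' g <- dd_genome("ACGT", circular = TRUE)
#' fetch_window(g, 3, 2)           # wraps: "TA"
#' fetch_window(g, 0, 2, "-")      # reverse complement of "AC": "GT"
#' @export
fetch_window <- function(genome, start, length, strand = "+") {
  stopifnot(inherits(genome, "dd_genome"))
  check_strand(strand)
  start <- as.integer(start)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop("window length must be >= 1", call. = FALSE)
  }
  L <- genome$length
  if (length > L) {
    stop("window length ", length, " exceeds genome length ", L, call. = FALSE)
  }
  if (genome$circular) {
    s <- ((start %% L) + L) %% L
    if (s + length <= L) {
      out <- substr(genome$sequence, s + 1L, s + length)
    } else {
      out <- paste0(substr(genome$sequence, s + 1L, L),
                    substr(genome$sequence, 1L, s + length - L))
    }
  } else {
    if (start < 0L || start + length > L) {
      stop("window [", start, ", ", start + length,
           ") out of bounds on linear genome of length ", L, call. = FALSE)
    }
    out <- substr(genome$sequence, start + 1L, start + length)
  }
  if (strand == "-") reverse_complement(out) else out
}

check_strand <- function(strand) {
  if (!(is.character(strand) && length(strand) == 1L && strand %in% c("+", "-"))) {
    stop("strand must be \"+\" or \"-\"", call. = FALSE)
  }
  invisible(strand)
}

# Character vector view of the sequence, used by the vectorized scanners.
seq_chars <- function(genome) strsplit(genome$sequence, "", fixed = TRUE)[[1]]

# shifted[i] = x at 0-based position (i-1) + off; FALSE outside a linear
# genome, wrapped on a circular one.
shift_flags <- function(x, off, circular) {
  L <- length(x)
  idx0 <- (seq_len(L) - 1L) + off
  if (circular) {
    x[(idx0 %% L) + 1L]
  } else {
    out <- rep(FALSE, L)
    ok <- idx0 >= 0L & idx0 < L
    out[ok] <- x[idx0[ok] + 1L]
    out
  }
}

# any_in_window(x, from, to)[i] = any(x at 0-based offsets from..to of
# position i-1), with circular wrap or linear clipping. |from|,|to| < L.
any_in_window <- function(x, from, to, circular) {
  L <- length(x)
  stopifnot(from <= to, abs(from) < L, abs(to) < L)
  if (circular) {
    y <- as.integer(c(x, x, x))
    cs <- c(0L, cumsum(y))
    i0 <- seq_len(L) - 1L
    a <- L + i0 + from
    b <- L + i0 + to
    (cs[b + 2L] - cs[a + 1L]) > 0L
  } else {
    cs <- c(0L, cumsum(as.integer(x)))
    i0 <- seq_len(L) - 1L
    a <- pmax(i0 + from, 0L)
    b <- pmin(i0 + to, L - 1L)
    out <- rep(FALSE, L)
    ok <- a <= b
    out[ok] <- (cs[b[ok] + 2L] - cs[a[ok] + 1L]) > 0L
    out
  }
}
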