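# Shared generators and tiny writers used across the test files.

random_seq <- function(n, seed, prob = c(0.3, 0.2, 0.2, 0.3)) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
  })
}

rotate_seq <- function(seq, k) {
  L <- nchar(seq)
  k <- ((k %% L) + L) %% L
  if (k == 0) return(seq)
  paste0(substr(seq, k + 1, L), substr(seq, 1, k))
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

# Minimal single-reference SAM writer for hand-computed pileup fixtures.
write_temp_sam <- function(ref_name, ref_len, pos1, seqs, quals = NULL,
                           mapq = 60) {
  path <- withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len),
    sprintf("r%04d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
            seq_along(seqs), ref_name, pos1, mapq, nchar(seqs), seqs, quals)
  )
  writeLines(lines, path)
  path
}

or_empty <- function(x) if (is.null(x)) character(0) else x
or_zero <- function(x) if (length(x) == 0) FALSE else x

# The 42-bp dimeric construct: left + site [0,14), 14-bp spacer with one TC
# (C at 21), right - site [28,42).
ddcbe_construct <- function() {
  paste0("TGGGGGGGGGGGGT", "GGGGGGTCGGGGGG", "AGGGGGGGGGGGGA")
}
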