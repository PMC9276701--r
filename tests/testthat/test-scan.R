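test_that("TC motifs are found on both strands, including the circular junction", {
  m <- find_tc_motifs(dd_genome("TC", circular = FALSE))
  expect_equal(m$c_pos, 1L)
  expect_equal(m$strand, "+")

  m <- find_tc_motifs(dd_genome("GA", circular = FALSE))
  expect_equal(m$c_pos, 0L)
  expect_equal(m$strand, "-")

  # junction dinucleotide "T"+"C" on the circle, absent on the line
  m <- find_tc_motifs(dd_genome("CT", circular = TRUE))
  expect_equal(m$c_pos, 0L)
  expect_equal(m$strand, "+")
  expect_equal(nrow(find_tc_motifs(dd_genome("CT", circular = FALSE))), 0L)
})

test_that("TALE sites require thymidine ends within the allowed lengths", {
  g <- dd_genome(paste0("T", strrep("G", 12), "T"), circular = FALSE)
  s <- enumerate_tale_sites(g)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end, s$strand), c("0", "14", "+"))

  g <- dd_genome(paste0("A", strrep("C", 12), "A"), circular = FALSE)
  s <- enumerate_tale_sites(g)
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "-")
  expect_equal(s$bound_seq, paste0("T", strrep("G", 12), "T"))

  # 21 bp: the only T-ended window exceeds the maximum length
  g <- dd_genome(paste0("T", strrep("G", 19), "T"), circular = FALSE)
  expect_equal(nrow(enumerate_tale_sites(g)), 0L)

  # genome shorter than the minimum site length: empty, not an error
  g <- dd_genome("TTT", circular = FALSE)
  expect_equal(nrow(enumerate_tale_sites(g)), 0L)
})

test_that("the dimeric construct yields exactly one pair design", {
  g <- dd_genome(ddcbe_construct(), circular = FALSE)
  d <- find_ddcbe_designs(g)
  expect_equal(nrow(d), 1L)
  expect_equal(d$left_start, 0L)
  expect_equal(d$left_end, 14L)
  expect_equal(d$right_start, 28L)
  expect_equal(d$right_end, 42L)
  expect_equal(d$spacer_length, 14L)
  expect_true(any(d$motifs[[1]]$c_pos == 21L & d$motifs[[1]]$strand == "+"))

  # widening the spacer to 19 bp kills the design
  wide <- sub("GGGGGGTCGGGGGG", "GGGGGGTCGGGGGGGGGGG", ddcbe_construct(),
              fixed = TRUE)
  expect_equal(nrow(find_ddcbe_designs(dd_genome(wide, circular = FALSE))), 0L)

  # no thymidines, no motifs, no designs
  allg <- dd_genome(strrep("G", 60), circular = FALSE)
  expect_equal(nrow(find_ddcbe_designs(allg)), 0L)
})

test_that("monomeric designs list motifs at their strand-relative offsets", {
  g <- dd_genome(paste0("T", strrep("G", 12), "T", "GGGTCGG"),
                 circular = FALSE)
  d <- find_mddcbe_designs(g)
  # site [0,14) reaches the C at 18 at offset 5; the longer T-ended window
  # [0,18) reaches it at offset 1
  d14 <- d[d$site_start == 0 & d$site_length == 14, ]
  expect_equal(nrow(d14), 1L)
  expect_equal(d14$motifs[[1]]$c_pos, 18L)
  expect_equal(d14$motifs[[1]]$offset, 5L)
  d18 <- d[d$site_start == 0 & d$site_length == 18, ]
  expect_equal(d18$motifs[[1]]$offset, 1L)

  # strand mirror: the reverse-complemented genome yields the same designs
  # on the other strand with identical offsets
  grc <- dd_genome(o_revcomp(g$sequence), circular = FALSE)
  drc <- find_mddcbe_designs(grc)
  expect_equal(nrow(drc), nrow(d))
  expect_setequal(unlist(lapply(drc$motifs, `[[`, "offset")),
                  unlist(lapply(d$motifs, `[[`, "offset")))
  expect_setequal(drc$site_strand, "-")
})

test_that("a motif beyond the monomeric window is out of reach of that site", {
  g <- dd_genome(paste0("T", strrep("G", 12), "T", strrep("G", 17), "TC", "G"),
                 circular = FALSE)
  d <- find_mddcbe_designs(g)
  d14 <- d[d$site_start == 0 & d$site_length == 14, ]
  # offset of the C from site [0,14) is 19 > 18
  expect_equal(nrow(d14), 0L)
  # the full design table still matches the literal oracle
  od <- o_mddcbe(g$sequence, circ = FALSE)
  got <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    data.frame(site_start = d$site_start[i], site_len = d$site_length[i],
               site_strand = d$site_strand[i],
               c_pos = d$motifs[[i]]$c_pos, strand = d$motifs[[i]]$strand,
               offset = d$motifs[[i]]$offset)
  }))
  expect_setequal(do.call(paste, got), do.call(paste, od))
})

test_that("the editability report agrees with the design-based enumeration", {
  for (seed in 1:12) {
    circ <- seed %% 2 == 0
    g <- dd_genome(random_seq(sample(60:140, 1), seed = seed + 100),
                   circular = circ)
    rep <- editability_report(g, sensitivity = FALSE)
    dd <- find_ddcbe_designs(g)
    md <- find_mddcbe_designs(g)
    dd_keys <- or_empty(unique(unlist(lapply(dd$motifs, function(m)
      paste(m$c_pos, m$strand)))))
    md_keys <- or_empty(unique(unlist(lapply(md$motifs, function(m)
      paste(m$c_pos, m$strand)))))
    keys <- paste(rep$motifs$c_pos, rep$motifs$strand)
    expect_setequal(keys[rep$motifs$ddcbe], dd_keys)
    expect_setequal(keys[rep$motifs$mddcbe], md_keys)
  }
})

test_that("editability counts obey set algebra and monotonicity", {
  for (seed in 1:8) {
    g <- dd_genome(random_seq(150, seed = seed + 300),
                   circular = seed %% 2 == 0)
    rep <- glance(editability_report(g, sensitivity = FALSE))
    expect_lte(rep$mddcbe_only, rep$mddcbe_editable)
    expect_lte(rep$mddcbe_editable, rep$total_motifs)
    expect_lte(rep$ddcbe_editable, rep$total_motifs)
    both <- with(editability_report(g, sensitivity = FALSE)$motifs,
                 sum(ddcbe & mddcbe))
    expect_equal(rep$mddcbe_only + both, rep$mddcbe_editable)

    # enlarging the monomeric window or the spacer range never loses motifs
    wider_mono <- glance(editability_report(
      g, scan_params(mono_window = 25), sensitivity = FALSE))
    expect_gte(wider_mono$mddcbe_editable, rep$mddcbe_editable)
    wider_spacer <- glance(editability_report(
      g, scan_params(spacer_len_min = 12, spacer_len_max = 20),
      sensitivity = FALSE))
    expect_gte(wider_spacer$ddcbe_editable, rep$ddcbe_editable)
  }
})

test_that("N bases never match motif or terminal-thymidine patterns", {
  g <- dd_genome("TNCGANTTNT", circular = FALSE)
  m <- find_tc_motifs(g)
  expect_false(any(m$c_pos %in% c(1L, 2L) & m$strand == "+"))
  # NC is not a motif; GA at (3,4) is
  expect_true(any(m$c_pos == 3L & m$strand == "-"))
  # a window with interior N can still be a site if its ends are T
  g2 <- dd_genome(paste0("T", strrep("N", 12), "T"), circular = FALSE)
  expect_equal(nrow(enumerate_tale_sites(g2)), 1L)
})

test_that("a genome without thymidine yields an all-zero report with a warning", {
  g <- dd_genome(strrep("G", 50), circular = FALSE)
  expect_warning(rep <- editability_report(g, sensitivity = FALSE),
                 "no TC motifs")
  expect_equal(glance(rep)$total_motifs, 0L)
  expect_equal(glance(rep)$mddcbe_only_fraction, 0)
})

test_that("report accessors return tidy objects", {
  g <- dd_genome(ddcbe_construct(), circular = FALSE)
  rep <- editability_report(g, sensitivity = FALSE)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_true(all(c("ddcbe", "mddcbe", "editable_by") %in% names(tidy(rep))))
  expect_s3_class(glance(rep), "tbl_df")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_output(print(rep), "mDdCBE-only")
})
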