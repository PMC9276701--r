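test_that("genome simulation is seed-deterministic", {
  a <- simulate_genome(200, seed = 7)
  b <- simulate_genome(200, seed = 7)
  c <- simulate_genome(200, seed = 8)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("planted monomeric sites are recovered by the scan at the planted offset", {
  for (off in c(1L, 5L, 11L, 18L)) {
    sim <- simulate_genome(300, planted = list(plant_mddcbe_site(100, off)),
                           seed = off, circular = FALSE)
    d <- find_mddcbe_designs(sim$genome)
    planted <- sim$truth[1, ]
    hit <- d[d$site_start == planted$site_start &
               d$site_end == planted$site_end & d$site_strand == "+", ]
    expect_equal(nrow(hit), 1L)
    expect_true(any(hit$motifs[[1]]$c_pos == planted$c_pos &
                      hit$motifs[[1]]$offset == off))
  }
})

test_that("planted dimeric pairs are recovered with the planted spacer", {
  for (sp in c(14L, 16L, 18L)) {
    sim <- simulate_genome(300,
                           planted = list(plant_ddcbe_pair(80, spacer_length = sp)),
                           seed = sp, circular = FALSE)
    d <- find_ddcbe_designs(sim$genome)
    planted <- sim$truth[1, ]
    hit <- d[d$spacer_start == planted$spacer_start &
               d$spacer_length == sp, ]
    expect_gte(nrow(hit), 1L)
    expect_true(any(vapply(hit$motifs, function(m)
      any(m$c_pos == planted$c_pos), logical(1))))
  }
})

test_that("planted bare motifs appear in the motif table", {
  sim <- simulate_genome(100, planted = list(plant_tc_motif(40, "+"),
                                             plant_tc_motif(60, "-")),
                         seed = 2, circular = FALSE)
  m <- find_tc_motifs(sim$genome)
  expect_true(any(m$c_pos == 41 & m$strand == "+"))
  expect_true(any(m$c_pos == 60 & m$strand == "-"))
})

test_that("infeasible plantings are rejected", {
  expect_error(simulate_genome(20, planted = list(plant_mddcbe_site(10, 5))),
               "does not fit")
  expect_error(
    simulate_genome(100, planted = list(plant_mddcbe_site(10, 5),
                                        plant_mddcbe_site(15, 5))),
    "overlap")
})

test_that("read simulation is byte-deterministic and honors edge cases", {
  g <- simulate_genome(150, seed = 3, circular = FALSE)$genome
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  spec <- edit_spec(depth = 5L, read_length = 60L, seed = 9)
  simulate_reads(g, spec, s1)
  simulate_reads(g, spec, s2)
  expect_identical(readLines(s1), readLines(s2))

  # depth 0: header-only SAM
  s0 <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(g, edit_spec(depth = 0L, read_length = 60L), s0)
  lines <- readLines(s0)
  expect_true(all(startsWith(lines, "@")))

  # no edits, no errors: every read matches the reference exactly
  body <- readLines(s1)
  body <- body[!startsWith(body, "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (f in fields) {
    start <- as.integer(f[[4]])
    expect_equal(f[[10]], substr(g$sequence, start, start + nchar(f[[10]]) - 1))
  }

  expect_error(edit_spec(per_position = data.frame(pos = 1, fraction = 1.2)),
               "\\[0, 1\\]")
  expect_error(simulate_reads(g, edit_spec(read_length = 500L),
                              withr::local_tempfile(fileext = ".sam")),
               "exceeds genome length")
})

test_that("programmed conversions must imply a deamination product or name an alt", {
  g <- dd_genome("AAAA", name = "r", circular = FALSE)
  expect_error(
    simulate_reads(g, edit_spec(per_position = data.frame(pos = 1, fraction = 0.5),
                                depth = 1L, read_length = 4L),
                   withr::local_tempfile(fileext = ".sam")),
    "explicit alt")
})

test_that("a programmed fraction is recovered by the caller within binomial error", {
  sim <- simulate_genome(200, gc_fraction = 0.5, seed = 12, circular = FALSE)
  g <- sim$genome
  ch <- strsplit(g$sequence, "")[[1]]
  target <- which(ch == "C")[10] - 1L
  sam <- withr::local_tempfile(fileext = ".sam")
  spec <- edit_spec(per_position = data.frame(pos = target, fraction = 0.30),
                    depth = 5000L, read_length = 100L, seed = 42)
  simulate_reads(g, spec, sam)
  conv <- pileup_conversions(sam, g, caller_params())
  rate <- conv$rate[conv$pos == target]
  # 99.9% binomial interval at n = 5000, p = 0.3 is within +/- 0.022
  expect_gt(rate, 0.28)
  expect_lt(rate, 0.32)
  # all other C/G positions are conversion-free (no errors programmed)
  expect_equal(sum(conv$converted) - conv$converted[conv$pos == target], 0L)
})

test_that("fastq export carries one record per read", {
  g <- simulate_genome(120, seed = 5, circular = FALSE)$genome
  sam <- withr::local_tempfile(fileext = ".sam")
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(g, edit_spec(depth = 3L, read_length = 60L), sam, fastq = fq)
  n_reads <- sum(!startsWith(readLines(sam), "@"))
  expect_equal(length(readLines(fq)), 4L * n_reads)
})
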