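low_depth_params <- function(...) caller_params(min_depth = 1L, ...)

test_that("perfectly matching reads give zero conversion at C and G only", {
  g <- dd_genome("ACGT", name = "ref", circular = FALSE)
  sam <- write_temp_sam("ref", 4L, rep(1L, 10), rep("ACGT", 10))
  conv <- pileup_conversions(sam, g, low_depth_params())
  expect_equal(conv$pos, c(1L, 2L))
  expect_equal(conv$ref, c("C", "G"))
  expect_equal(conv$depth, c(10L, 10L))
  expect_equal(conv$rate, c(0, 0))
})

test_that("conversion counts only the deamination product; other mismatches stay in depth", {
  g <- dd_genome("ACGT", name = "ref", circular = FALSE)
  # 2/10 reads carry T at the C position
  sam <- write_temp_sam("ref", 4L, rep(1L, 10),
                        c(rep("ATGT", 2), rep("ACGT", 8)))
  conv <- pileup_conversions(sam, g, low_depth_params())
  expect_equal(conv$rate[conv$pos == 1], 0.2)

  # at the G position: 5 reads A (converted), 1 read C (mismatch, depth only)
  sam <- write_temp_sam("ref", 4L, rep(1L, 10),
                        c(rep("ACAT", 5), "ACCT", rep("ACGT", 4)))
  conv <- pileup_conversions(sam, g, low_depth_params())
  row <- conv[conv$pos == 2, ]
  expect_equal(row$converted, 5L)
  expect_equal(row$depth, 10L)
  expect_equal(row$rate, 0.5)
})

test_that("base quality and depth filters are applied before rates", {
  g <- dd_genome("ACGT", name = "ref", circular = FALSE)
  # the two converted reads carry a low-quality call at the C position
  quals <- c(rep("I#II", 2), rep("IIII", 8))
  sam <- write_temp_sam("ref", 4L, rep(1L, 10),
                        c(rep("ATGT", 2), rep("ACGT", 8)), quals)
  conv <- pileup_conversions(sam, g, low_depth_params(min_base_quality = 20))
  row <- conv[conv$pos == 1, ]
  expect_equal(row$depth, 8L)
  expect_equal(row$converted, 0L)

  # below min_depth the rate is flagged undefined, not zero
  conv <- pileup_conversions(sam, g, caller_params(min_depth = 100))
  expect_false(any(conv$pass_depth))
  expect_true(all(is.na(conv$rate)))
})

test_that("reference mismatches between SAM and genome are errors", {
  g <- dd_genome("ACGT", name = "other", circular = FALSE)
  sam <- write_temp_sam("ref", 4L, 1L, "ACGT")
  expect_error(pileup_conversions(sam, g, low_depth_params()),
               "reference name mismatch")
  g2 <- dd_genome("ACGTA", name = "ref", circular = FALSE)
  expect_error(pileup_conversions(sam, g2, low_depth_params()),
               "length mismatch")
  expect_error(pileup_conversions("nope.sam", g, low_depth_params()),
               "not found")
})

test_that("on-target quantification is the windowed genome-wide computation in percent", {
  g <- dd_genome("ACGTACGT", name = "ref", circular = FALSE)
  sam <- write_temp_sam("ref", 8L, rep(1L, 10),
                        c(rep("ATGTACGT", 3), rep("ACGTACGT", 7)))
  conv <- pileup_conversions(sam, g, low_depth_params())
  win <- quantify_on_target(conv, c(0, 4))
  expect_equal(win$percent[win$pos == 1], 30)
  expect_equal(win, quantify_on_target(conv, data.frame(start = 0, end = 4)))
  full <- conv[conv$pos < 4, ]
  expect_equal(win[names(full)], full)
  expect_equal(nrow(quantify_on_target(conv, c(3, 4))), 0L)  # A/T only
})

test_that("the off-target summary applies SNV and target exclusions and averages all retained positions", {
  conv <- tibble::tibble(
    pos = c(10L, 20L, 30L, 40L),
    pos1 = pos + 1L,
    ref = c("C", "C", "G", "C"),
    depth = 10000L,
    converted = as.integer(c(5, 20, 6000, 500)),
    rate = converted / depth,
    pass_depth = TRUE
  )
  s <- summarize_offtarget(conv, target_windows = data.frame(start = 40, end = 41),
                           params = caller_params(min_depth = 1))
  expect_equal(s$summary$n_excluded_snv, 1L)       # 60% at pos 30
  expect_equal(s$summary$n_excluded_target, 1L)    # pos 40
  expect_equal(s$summary$n_positions_retained, 2L)
  expect_equal(s$summary$mean_offtarget_rate, 0.00125)
  expect_equal(s$candidates$pos, 20L)              # 0.2% >= 0.1%; 0.05% below
  expect_equal(s$summary$n_positions_retained + s$summary$n_excluded_snv +
                 s$summary$n_excluded_target, nrow(conv))
})

test_that("a position at exactly the SNV cutoff is excluded (inclusive bound)", {
  conv <- tibble::tibble(
    pos = c(1L, 2L), pos1 = pos + 1L, ref = "C", depth = 1000L,
    converted = c(500L, 0L), rate = converted / depth, pass_depth = TRUE)
  s <- summarize_offtarget(conv, params = caller_params(min_depth = 1))
  expect_equal(s$summary$n_excluded_snv, 1L)
  expect_false(1L %in% s$positions$pos[s$positions$category == "retained"])
})

test_that("all-zero rates give a zero mean and no candidates; nothing retained is an error", {
  conv <- tibble::tibble(pos = 1:5, pos1 = pos + 1L, ref = "C",
                         depth = 1000L, converted = 0L, rate = 0,
                         pass_depth = TRUE)
  s <- summarize_offtarget(conv, params = caller_params(min_depth = 1))
  expect_equal(s$summary$mean_offtarget_rate, 0)
  expect_equal(nrow(s$candidates), 0L)

  conv$rate <- 0.9
  expect_error(summarize_offtarget(conv, params = caller_params(min_depth = 1)),
               "no positions retained")
})

test_that("off-target results expose tidy accessors", {
  conv <- tibble::tibble(pos = 1:4, pos1 = pos + 1L, ref = "C",
                         depth = 1000L, converted = c(0L, 2L, 0L, 1L),
                         rate = converted / 1000, pass_depth = TRUE)
  s <- summarize_offtarget(conv, params = caller_params(min_depth = 1))
  expect_s3_class(tidy(s), "tbl_df")
  expect_true("category" %in% names(tidy(s)))
  expect_s3_class(glance(s), "tbl_df")
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  expect_output(print(s), "mean off-target")
})
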