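test_that("depth track validation reports offending lines", {
  good <- data.frame(chrom = rep(c("a", "b"), each = 10),
                     window_start = rep(0:9 * 1000L, 2),
                     depth = rep(30L, 20))
  p <- load_windows(good)
  expect_s3_class(p, "depth_profile")
  expect_equal(nrow(p$windows), 20)

  bad <- good; bad$depth[7] <- -1
  expect_error(load_windows(bad), "line 8")
  bad <- good; bad$window_start[5] <- 4500L
  expect_error(load_windows(bad), "multiple")
  bad <- good; bad$window_start[2] <- 0L
  expect_error(load_windows(bad), "duplicate")
  expect_error(load_windows(data.frame(x = 1)), "columns")
})

test_that("uniform depth gives copy number 1 and rescaling cancels", {
  d <- data.frame(chrom = rep(c("a", "b", "c"), each = 50),
                  window_start = rep(0:49 * 1000L, 3),
                  depth = rep(40, 150))
  cn <- chromosome_copy_number(load_windows(d), core_chroms = c("a", "b"))
  expect_true(all(cn$cn == 1.0))
  d2 <- d; d2$depth <- d2$depth * 7
  cn2 <- chromosome_copy_number(load_windows(d2), core_chroms = c("a", "b"))
  expect_equal(cn$cn_raw, cn2$cn_raw)
  # genome-mean baseline mode agrees here
  cn3 <- chromosome_copy_number(load_windows(d), baseline = "genome_mean")
  expect_true(all(cn3$cn == 1.0))
})

test_that("planted copy ratios are recovered within 0.05 with exact event calls", {
  ratios <- c(c01 = 1, c02 = 1, c03 = 1, c04 = 0, c05 = 0.5, c06 = 0.75,
              c07 = 1.5, c08 = 2)
  lens <- setNames(rep(600e3, length(ratios)), names(ratios))
  d <- simulate_depth_profile(lens, ratios, mean_depth = 30, seed = 21)
  cn <- chromosome_copy_number(load_windows(d),
                               core_chroms = c("c01", "c02", "c03"))
  got <- setNames(cn$cn_raw, cn$chrom)
  for (ch in names(ratios)) {
    expect_lt(abs(got[[ch]] - ratios[[ch]]), 0.05)
  }
  # events at a tolerance that separates the planted grid from the boundary
  ev <- setNames(call_cnv_events(cn, tolerance = 0.2)$event, cn$chrom)
  want <- c(c01 = "normal", c02 = "normal", c03 = "normal", c04 = "absent",
            c05 = "loss", c06 = "loss", c07 = "gain", c08 = "gain")
  expect_identical(ev[names(want)], want)
})

test_that("event vocabulary follows the thresholds", {
  expect_identical(call_cnv_events(c(1, 0.5, 0, 2, 0.74, 1.26)),
                   c("normal", "loss", "absent", "gain", "loss", "gain"))
  expect_identical(call_cnv_events(1.2), "normal")
})

test_that("zero baseline is rejected", {
  d <- data.frame(chrom = "a", window_start = 0:9 * 1000L, depth = rep(0, 10))
  expect_error(chromosome_copy_number(load_windows(d), core_chroms = "a"),
               "baseline")
})
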