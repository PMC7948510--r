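test_that("the control threshold is the average per-cell control intensity", {
  expect_equal(control_threshold(data.frame(mean_raw = 7)), 7)
  expect_equal(control_threshold(data.frame(mean_raw = c(2, 4, 6))), 4)
  expect_error(control_threshold(data.frame(mean_raw = numeric(0))),
               "control image")

  quiet <- simulate_control_field(n_nuclei = 12, noise_sd = 0, width = 160,
                                  height = 160, seed = 8)
  rec <- per_cell_mean_intensity(quiet$marker, segment_nuclei(quiet$dapi))
  expect_equal(control_threshold(rec), quiet$truth$marker_bg_level)
})

test_that("positivity uses strict subtraction against the control mean", {
  rec <- data.frame(nucleus_id = 1:4, mean_raw = c(4, 0, 10, 3.999))
  sc <- score_cells(rec, 4)
  expect_equal(sc$mean_corrected, c(0, 0, 6, 0))
  expect_equal(sc$positive, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(score_cells(rec, -1))
})

test_that("fraction positive is the positive/total ratio", {
  all_pos <- score_cells(data.frame(nucleus_id = 1:3, mean_raw = c(9, 9, 9)), 1)
  expect_equal(fraction_positive(all_pos)$frac_positive, 1)
  none <- score_cells(data.frame(nucleus_id = 1:3, mean_raw = c(0, 0, 0)), 1)
  expect_equal(fraction_positive(none)$frac_positive, 0)
  expect_error(fraction_positive(data.frame()), "scored")
  res <- fraction_positive(score_cells(
    data.frame(nucleus_id = 1:4, mean_raw = c(5, 0, 9, 0)), 2), "im1", 2)
  expect_equal(res$n_cells, 4)
  expect_equal(res$n_positive, 2)
  expect_equal(res$frac_positive, 0.5)
  expect_equal(res$control_mean, 2)
})

test_that("raising the control mean never raises a fraction", {
  fld <- small_field(n_nuclei = 40, frac_positive = 0.5, seed = 31)
  rec <- per_cell_mean_intensity(fld$marker, segment_nuclei(fld$dapi))
  thresholds <- seq(0, 30000, length.out = 40)
  fracs <- vapply(thresholds, function(th) {
    fraction_positive(score_cells(rec, th))$frac_positive
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("positive calls are invariant to a common intensity rescaling", {
  fld <- small_field(n_nuclei = 30, frac_positive = 0.4, seed = 32)
  ctrl <- small_control(n_nuclei = 30, seed = 33)
  seg <- segment_nuclei(fld$dapi)
  seg_c <- segment_nuclei(ctrl$dapi)
  call_at_scale <- function(s) {
    th <- control_threshold(
      per_cell_mean_intensity(ctrl$marker * s, seg_c))
    score_cells(per_cell_mean_intensity(fld$marker * s, seg), th)$positive
  }
  base <- call_at_scale(1)
  expect_identical(call_at_scale(0.5), base)
  expect_identical(call_at_scale(2), base)
})

test_that("scoring the control image against itself matches the exact tally", {
  ctrl <- small_control(n_nuclei = 35, seed = 34, noise_sd = 600)
  rec <- per_cell_mean_intensity(ctrl$marker, segment_nuclei(ctrl$dapi))
  th <- control_threshold(rec)
  got <- fraction_positive(score_cells(rec, th))$frac_positive
  expect_equal(got, mean(rec$mean_raw > th))
})

test_that("the full pipeline recovers planted fractions", {
  ctrl <- small_control(n_nuclei = 40, seed = 41)
  for (f in c(0, 0.5, 1)) {
    fld <- small_field(n_nuclei = 40, frac_positive = f, seed = 42 + 10 * f)
    res <- quantify_images(list(fld), ctrl)
    expect_equal(res$per_image$frac_positive, f, tolerance = 0.051)
    expect_equal(res$per_image$n_cells, 40)
  }
  blank <- list(dapi = matrix(0, 64, 64), marker = matrix(0, 64, 64))
  expect_error(quantify_images(list(blank), ctrl), "no nuclei")
  expect_error(quantify_images(list(ctrl), blank), "control image")
})

test_that("group comparison matches a closed-form t oracle", {
  a <- c(0.9, 0.95, 0.92)
  b <- c(0.1, 0.15, 0.12)
  cmp <- compare_groups(a, b)
  # Welch statistic and p-value evaluated from first principles
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(cmp$t_statistic, tstat, tolerance = 1e-12)
  expect_equal(cmp$p_value, p, tolerance = 1e-10)

  pooled <- compare_groups(a, b, pooled = TRUE)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tp <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(pooled$t_statistic, tp, tolerance = 1e-12)
  expect_equal(pooled$p_value, 2 * pt(-abs(tp), 4), tolerance = 1e-10)
})

test_that("group comparison is symmetric and handles degenerate input", {
  a <- c(0.2, 0.4, 0.3)
  b <- c(0.5, 0.6, 0.7)
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)

  # equal means, non-zero variance
  sym <- compare_groups(c(0.4, 0.6), c(0.3, 0.7))
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)

  expect_warning(deg <- compare_groups(c(0.5, 0.5), c(0.5, 0.5)),
                 "degenerate")
  expect_equal(deg$t_statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_warning(deg2 <- compare_groups(c(0.6, 0.6), c(0.2, 0.2)),
                 "degenerate")
  expect_equal(deg2$p_value, 0)
  expect_error(compare_groups(0.5, c(0.2, 0.3)), "at least 2")
})
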