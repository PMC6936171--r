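# LOESS fits, peak extraction, expression calls and group comparisons.

series_zt <- function() {
  sched <- sampling_schedule(photoperiod("winter", "6:30", "18:00"))
  rep(sched$zt, each = 3)
}

test_that("a constant series fits to the constant with zero SE", {
  pts <- data.frame(zt = series_zt(), abundance = 3.7)
  fit <- fit_loess(pts, n_boot = 50, seed = 11)
  expect_true(all(fit$fitted == 3.7))
  expect_true(all(fit$se == 0))
  expect_equal(fit$peak_value, 3.7)
})

test_that("scaling the series scales the fit pointwise", {
  zt <- series_zt()
  y <- 2 + cos(2 * pi * (zt - 6) / 24)
  f1 <- fit_loess(data.frame(zt = zt, abundance = y), n_boot = 0)
  f2 <- fit_loess(data.frame(zt = zt, abundance = 2 * y), n_boot = 0)
  ok <- !is.na(f1$fitted)
  expect_equal(f2$fitted[ok], 2 * f1$fitted[ok], tolerance = 1e-9)
})

test_that("a noiseless cosine peaking at ZT6 is located within the grid", {
  zt <- series_zt()
  y <- pmax(0, cos(2 * pi * (zt - 6) / 24))
  fit <- fit_loess(data.frame(zt = zt, abundance = y), n_boot = 0)
  # sampling interval 2 h, grid 0.1 h: allow interval/2 + grid slack
  expect_lt(abs(fit$peak_zt - 6), 1.1)
})

test_that("find_peak equals the brute-force grid maximum", {
  zt <- series_zt()
  y <- withr::with_seed(3, 1 + cos(2 * pi * (zt - 9) / 24) +
                          rnorm(length(zt), 0, 0.1))
  fit <- fit_loess(data.frame(zt = zt, abundance = y), n_boot = 0)
  for (win in list(c(0, 22), c(4, 18), c(10, 12))) {
    keep <- fit$grid >= win[1] & fit$grid <= win[2] & !is.na(fit$fitted)
    i <- which(keep)[which.max(fit$fitted[keep])]
    pk <- find_peak(fit, win)
    expect_identical(pk[["peak_zt"]], fit$grid[i])
    expect_identical(pk[["peak_value"]], max(fit$fitted[keep]))
  }
  expect_error(find_peak(fit, c(30, 31)), "empty")
})

test_that("peak ties resolve to the earliest grid point", {
  fit <- structure(list(grid = c(0, 11, 22), fitted = c(1, 3, 2),
                        se = c(0, 0, 0), span = 0.5),
                   class = "loess_fit")
  expect_equal(find_peak(fit)[["peak_zt"]], 11)
  fit$fitted <- c(2, 2, 1)
  expect_equal(find_peak(fit)[["peak_zt"]], 0)
})

test_that("expression calls follow the floor and FS-fraction rule", {
  mk <- function(v) structure(list(peak_value = v), class = "loess_fit")
  expect_identical(expression_call(mk(0), mk(1)), "not_expressed")
  expect_identical(expression_call(mk(0.5), mk(1)), "expressed")
  expect_identical(expression_call(mk(0.01), mk(1)), "not_expressed")
  expect_identical(expression_call(mk(0.2), NULL, threshold = 0,
                                   floor = 0.5), "not_expressed")
  expect_error(expression_call(mk(1)), "configuration error")
})

test_that("the paired t-test matches its closed form", {
  a <- c(2.3, 4.1, 3.3, 5.0, 4.4)
  b <- c(1.9, 3.8, 3.6, 4.1, 3.9)
  res <- compare_groups(list(a, b), "paired_t")
  orc <- oracle_paired_t(a, b)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-9)
})

test_that("degenerate comparisons are flagged instead of failing", {
  res <- compare_groups(list(c(1, 2, 3), c(1, 2, 3)), "paired_t")
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- compare_groups(list(c(1, 2, 3), c(2, 3, 4)), "paired_t")
  expect_true(res2$degenerate)   # constant nonzero difference
  res3 <- compare_groups(list(c(1, 1), c(1, 1), c(1, 1)), "anova_tukey")
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)
})

test_that("ANOVA + Tukey flags a separated group and matches aov", {
  g <- list(a = c(1.1, 0.9, 1.0, 1.2), b = c(1.0, 1.3, 0.8, 1.1),
            c = c(3.0, 3.2, 2.9, 3.1))
  res <- compare_groups(g, "anova_tukey")
  expect_true(res$significant)
  tuk <- res$tukey
  expect_true(all(tuk$significant[grepl("c", tuk$pair)]))
  expect_false(any(tuk$significant[tuk$pair == "b-a"]))
})
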