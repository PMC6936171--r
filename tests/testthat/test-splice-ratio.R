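# log(AS/FS) ratios, fold range, temperature regression.

mk_series <- function(zt, rep_, ab) {
  data.frame(zt = zt, replicate = rep_, norm_abundance = ab)
}

test_that("equal abundances give ratio 0 and a 10x gap gives 1", {
  zt <- rep(c(0, 6, 12, 18), each = 2)
  r <- rep(1:2, 4)
  rs0 <- ratio_series(mk_series(zt, r, rep(5, 8)),
                      mk_series(zt, r, rep(5, 8)), pseudo = 0)
  expect_true(all(rs0$log_ratio == 0))
  rs1 <- ratio_series(mk_series(zt, r, rep(50, 8)),
                      mk_series(zt, r, rep(5, 8)), pseudo = 0)
  expect_true(all(abs(rs1$log_ratio - 1) < 1e-12))
})

test_that("misaligned series raise an alignment error naming the keys", {
  a <- mk_series(c(0, 6), c(1, 1), c(1, 1))
  b <- mk_series(c(0, 12), c(1, 1), c(1, 1))
  expect_error(ratio_series(a, b, pseudo = 0), "alignment error.*12")
})

test_that("swapping AS and FS negates every log ratio", {
  withr::with_seed(5, {
    zt <- rep(seq(0, 22, by = 2), each = 3)
    r <- rep(1:3, 12)
    as_ab <- rlnorm(36, 0, 1)
    fs_ab <- rlnorm(36, 1, 1)
    f <- ratio_series(mk_series(zt, r, as_ab), mk_series(zt, r, fs_ab),
                      pseudo = 0.01)
    g <- ratio_series(mk_series(zt, r, fs_ab), mk_series(zt, r, as_ab),
                      pseudo = 0.01)
    expect_equal(f$log_ratio, -g$log_ratio, tolerance = 1e-12)
  })
})

test_that("a noisy constant log10 ratio of -1 is recovered", {
  withr::with_seed(9, {
    zt <- rep(seq(0, 26, by = 2), each = 3)[1:42]
    r <- rep(1:3, 14)
    fs <- rlnorm(42, log(100), 0.2)
    as_ab <- fs * 10^(-1 + rnorm(42, 0, 0.05))
    rs <- ratio_series(mk_series(zt, r, as_ab), mk_series(zt, r, fs),
                       pseudo = 0)
    expect_equal(mean(rs$log_ratio), -1, tolerance = 0.02)
  })
})

test_that("below-detection points follow the pseudo-count rule", {
  zt <- c(0, 6, 12, 18); r <- rep(1L, 4)
  rs <- ratio_series(mk_series(zt, r, c(0, 1, 2, 0)),
                     mk_series(zt, r, c(4, 4, 4, 0)), pseudo = 0.5)
  expect_identical(attr(rs, "n_dropped"), 1L)   # both-zero point dropped
  expect_identical(nrow(rs), 3L)
  expect_equal(rs$log_ratio[1], log10(0.5 / 4.5))
  expect_equal(attr(rs, "pseudo"), 0.5)
  expect_equal(default_pseudocount(c(0, 0.4, 2)), 0.2)
})

test_that("fold range is base^(max - min) and base-invariant", {
  zt <- c(0, 6, 12, 18); r <- rep(1L, 4)
  const <- ratio_series(mk_series(zt, r, rep(2, 4)),
                        mk_series(zt, r, rep(4, 4)), pseudo = 0)
  expect_equal(ratio_fold_range(const), 1)
  span2 <- mk_series(zt, r, c(0.4, 4, 40, 4))    # log10 ratios -1,0,1,0
  rs10 <- ratio_series(span2, mk_series(zt, r, rep(4, 4)), pseudo = 0)
  expect_equal(ratio_fold_range(rs10), 100)
  rse <- ratio_series(span2, mk_series(zt, r, rep(4, 4)), pseudo = 0,
                      base = exp(1))
  expect_equal(ratio_fold_range(rse), 100, tolerance = 1e-9)
  # the literal ratio-of-log-values alternative stays available
  expect_equal(ratio_fold_range(rs10, literal_log_ratio = TRUE), -1)
})

test_that("a generated 77-fold linear-scale range is recovered", {
  zt <- rep(seq(0, 26, by = 2), each = 3)[1:42]
  r <- rep(1:3, 14)
  amp <- log10(77) / 2
  lr <- -1 + amp * cos(2 * pi * (zt - 22) / 24)
  fs <- rep(100, 42)
  rs <- ratio_series(mk_series(zt, r, fs * 10^lr), mk_series(zt, r, fs),
                     pseudo = 0)
  expect_equal(ratio_fold_range(rs), 77, tolerance = 1e-6)
  # LOESS smoothing attenuates the extremes of a 24-h wave, so the
  # smoothed fold can only shrink; the >10-fold classification must hold
  sm <- ratio_fold_range(rs, smooth = TRUE)
  expect_lte(sm, 77 * (1 + 1e-9))
  expect_gt(sm, 10)
})

test_that("temperature regression matches the closed-form OLS oracle", {
  x <- c(12.1, 15.3, 18.2, 22.9, 26.4)
  y <- c(-0.4, -0.55, -0.72, -0.96, -1.13)
  rs <- data.frame(log_ratio = y, clock_time = 1:5)
  res <- temp_regression(rs, temp_c = x)
  orc <- oracle_ols(x, y)
  expect_equal(res$slope, orc$slope, tolerance = 1e-9)
  expect_equal(res$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(res$r_squared, orc$r_squared, tolerance = 1e-9)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-9)
  expect_equal(res$r_squared, cor(x, y)^2, tolerance = 1e-9)
})

test_that("a noiseless line is fit exactly and flagged negative", {
  x <- seq(10, 30, length.out = 10)
  y <- 0.2 - 0.05 * x
  # suppressed: summary.lm warns about the essentially perfect fit
  res <- suppressWarnings(
    temp_regression(data.frame(log_ratio = y), temp_c = x))
  expect_equal(res$slope, -0.05, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_true(res$significant_negative)
  expect_error(temp_regression(data.frame(log_ratio = y[1:2]),
                               temp_c = x[1:2]), "insufficient data")
})

test_that("permuting temperature kills significance at the null rate", {
  withr::with_seed(21, {
    n <- 42
    temp <- 20 + 5 * cos(2 * pi * (seq_len(n) %% 14) / 14) + rnorm(n, 0, 1)
    lr <- rnorm(n, -1, 0.3)
    hits <- vapply(1:1000, function(i) {
      res <- temp_regression(data.frame(log_ratio = lr),
                             temp_c = sample(temp))
      res$significant_negative
    }, logical(1))
    # two-sided alpha = 0.05 splits to ~2.5% on the negative side
    expect_gt(mean(hits), 0.01)
    expect_lt(mean(hits), 0.045)
  })
})

test_that("temperature interpolation covers and matches the log", {
  temps <- data.frame(clock_time = 0:30, temp_c = 15 + 0.5 * (0:30))
  expect_equal(temperature_at(temps, c(4.5, 26)), c(17.25, 28))
  expect_error(temperature_at(temps, 31.5), "does not cover")
})
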