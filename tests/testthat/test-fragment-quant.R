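# Ladder sizing, peak assignment, reference normalization, peak calling.

test_that("sizing on a linear ladder is exact, including fixed points", {
  lad_m <- c(100, 200, 300)
  lad_bp <- c(100, 200, 300)
  out <- size_peaks(lad_m, lad_bp, c(150, 200))
  expect_equal(out$size_bp, c(150, 200))
  expect_false(any(out$extrapolated))
  out_ls <- size_peaks(lad_m, lad_bp, c(150, 200),
                       method = "local_southern")
  expect_equal(out_ls$size_bp, c(150, 200), tolerance = 1e-9)
})

test_that("sizing under a curved migration model stays within 1 bp", {
  # generating model: m = 200 + 4 bp - 0.001 bp^2 (monotone over range);
  # the analytic inverse is the oracle
  mig <- function(bp) 200 + 4 * bp - 0.001 * bp^2
  inv <- function(m) (4 - sqrt(16 - 4 * 0.001 * (m - 200))) / (2 * 0.001)
  lad_bp <- seq(50, 500, by = 75)
  lad_m <- mig(lad_bp)
  true_bp <- withr::with_seed(7, runif(20, 60, 490))
  targets <- mig(true_bp)
  for (method in c("piecewise_linear", "local_southern")) {
    out <- size_peaks(lad_m, lad_bp, targets, method = method)
    expect_equal(out$size_bp, inv(targets), tolerance = 1,
                 info = method)
    expect_lt(max(abs(out$size_bp - true_bp)), 1)
  }
  # local Southern's reciprocal model should beat plain interpolation
  pl <- size_peaks(lad_m, lad_bp, targets)$size_bp
  ls <- size_peaks(lad_m, lad_bp, targets,
                   method = "local_southern")$size_bp
  expect_lt(mean(abs(ls - true_bp)), mean(abs(pl - true_bp)) + 1e-9)
})

test_that("sizing is strictly monotone and flags extrapolation", {
  lad_m <- c(120, 260, 350, 520)
  lad_bp <- c(50, 150, 230, 400)
  targets <- sort(withr::with_seed(1, runif(30, 100, 560)))
  out <- size_peaks(lad_m, lad_bp, targets)
  expect_true(all(diff(out$size_bp) > 0))
  expect_identical(out$extrapolated, targets < 120 | targets > 520)
  expect_error(size_peaks(c(200, 100), c(100, 200), 150),
               "calibration error")
})

test_that("peaks assign to the nearest amplicon within tolerance", {
  defs <- data.frame(gene_id = c("g", "g"), isoform_id = c("FS", "I5R"),
                     expected_size = c(304, 448))
  peaks <- data.frame(sample_id = "s1", size_bp = c(303.8, 310),
                      area = c(50, 7))
  rec <- assign_isoforms(peaks, defs, tol = 2)
  expect_identical(rec$raw_area[rec$isoform_id == "FS"], 50)
  expect_identical(rec$raw_area[rec$isoform_id == "I5R"], 0)
  expect_true(rec$below_detection[rec$isoform_id == "I5R"])
  expect_identical(attr(rec, "unassigned")$size_bp, 310)
  defs$expected_size <- c(304, 306)
  expect_error(assign_isoforms(peaks, defs, tol = 2), "ambiguous panel")
})

test_that("normalization divides by the geometric mean of the references", {
  rec <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    gene_id = c("g", "ref1", "ref2", "g", "ref1", "ref2"),
    isoform_id = "FS",
    raw_area = c(10, 4, 9, 10, 8, 18),
    below_detection = FALSE)
  out <- normalize_abundances(rec, c("ref1", "ref2"))
  expect_equal(out$norm_abundance[out$sample_id == "s1"], 10 / 6)
  # doubling the reference signal exactly halves the normalized value
  expect_equal(out$norm_abundance[out$sample_id == "s2"], 10 / 12)
  expect_false(any(out$gene_id %in% c("ref1", "ref2")))
})

test_that("normalization is invariant to a per-sample gain", {
  rec <- data.frame(sample_id = "s1", gene_id = c("g", "g", "ref1"),
                    isoform_id = c("FS", "I1R", "FS"),
                    raw_area = c(30, 6, 12), below_detection = FALSE)
  scaled <- rec
  scaled$raw_area <- scaled$raw_area * 7.3
  a <- normalize_abundances(rec, "ref1")$norm_abundance
  b <- normalize_abundances(scaled, "ref1")$norm_abundance
  expect_equal(a, b)
})

test_that("samples without reference signal are dropped with a record", {
  rec <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                    gene_id = c("g", "ref1", "g", "ref1"),
                    isoform_id = "FS",
                    raw_area = c(10, 5, 10, 0),
                    below_detection = c(FALSE, FALSE, FALSE, TRUE))
  out <- normalize_abundances(rec, "ref1")
  expect_identical(attr(out, "dropped_samples"), "s2")
  expect_false("s2" %in% out$sample_id)
  # zeros in targets propagate with their flag
  rec2 <- data.frame(sample_id = "s1", gene_id = c("g", "ref1"),
                     isoform_id = c("I1R", "FS"), raw_area = c(0, 5),
                     below_detection = c(TRUE, FALSE))
  out2 <- normalize_abundances(rec2, "ref1")
  expect_identical(out2$norm_abundance, 0)
  expect_true(out2$below_detection)
})

test_that("peak calling recovers a known area ratio from a raw trace", {
  # two Gaussian peaks with area ratio 4:1 on a flat baseline
  x <- seq(1000, 2000, by = 1)
  g <- function(mu, area, sd = 8) area * dnorm(x, mu, sd)
  y <- g(1300, 400) + g(1700, 100)
  pk <- call_peaks(x, y, min_frac = 0.05, window = 5)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$migration, c(1300, 1700), tolerance = 2)
  expect_equal(pk$area[1] / pk$area[2], 4, tolerance = 0.05 * 4)
})
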