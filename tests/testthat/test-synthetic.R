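# Synthetic-study generator: determinism, design arithmetic, noise model.

test_that("the same seed reproduces every output byte-identically", {
  s1 <- simulate_abundances(sim_config(seed = 42))
  s2 <- simulate_abundances(sim_config(seed = 42))
  expect_identical(s1, s2)
  s3 <- simulate_abundances(sim_config(seed = 43))
  expect_false(identical(s1$abundances$abundance,
                         s3$abundances$abundance))
  pt1 <- simulate_peak_tables(s1, default_panel(sim_config(42)),
                              sim_config(42))
  pt2 <- simulate_peak_tables(s2, default_panel(sim_config(42)),
                              sim_config(42))
  expect_identical(pt1, pt2)
})

test_that("the default design matches the field schedule", {
  sim <- simulate_abundances(sim_config(seed = 1))
  sm <- sim$samples
  # winter: L1 only; summer: L1 + two internodes; 14 points x 3 replicates
  expect_identical(sum(sm$season_id == "winter"), 14L * 3L)
  expect_identical(sum(sm$season_id == "summer"), 3L * 14L * 3L)
  expect_identical(sort(unique(sm$organ[sm$season_id == "summer"])),
                   c("I1", "I5", "L1"))
  expect_true(all(sm$zt >= 0 & sm$zt < 24))
  # per gene/organ/season: one FS + configured AS isoforms for every sample
  ab <- sim$abundances
  counts <- table(ab$gene_id, ab$isoform_id)
  expect_true(all(counts[c("clockA", "clockB"), "FS"] == nrow(sm)))
})

test_that("zero noise returns the exact generating truth", {
  cfg <- sim_config(seed = 5, noise_sd = 0, ref_noise_sd = 0)
  sim <- simulate_abundances(cfg)
  expect_equal(sim$abundances$abundance, sim$abundances$true_abundance,
               tolerance = 1e-12)
})

test_that("temperature logs cover all sampling instants, winter cooler", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_abundances(cfg)
  expect_false(anyNA(sim$samples$temp_c))
  expect_lt(mean(sim$temperature$temp_c[
      sim$temperature$season_id == "winter"]),
    mean(sim$temperature$temp_c[
      sim$temperature$season_id == "summer"]))
})

test_that("AR(1) noise reproduces its configured marginal sd", {
  phi <- 0.6; sd_target <- 0.5
  x <- withr::with_seed(11, {
    as.numeric(stats::arima.sim(list(ar = phi), n = 10000,
                                sd = sd_target * sqrt(1 - phi^2)))
  })
  expect_equal(sd(x), sd_target, tolerance = 0.1 * sd_target)
})

test_that("peak tables demand a covering panel", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_abundances(cfg)
  panel <- default_panel(cfg)
  expect_error(simulate_peak_tables(sim, panel[0, ], cfg), "empty")
  expect_error(simulate_peak_tables(sim, panel[-1, ], cfg),
               "does not cover")
})

test_that("a gain-free peak table round-trips the exact abundances", {
  cfg <- sim_config(seed = 3, gain_sd = 0)
  sim <- simulate_abundances(cfg)
  panel <- default_panel(cfg)
  pt <- simulate_peak_tables(sim, panel, cfg, area_scale = 1)
  one <- sim$samples$sample_id[1]
  quant <- quantify_peak_tables(pt[pt$sample_id == one, ], panel,
                                cfg$reference_genes$gene_id)
  truth <- sim$abundances[sim$abundances$sample_id == one, ]
  ref <- truth$abundance[truth$gene_id %in% cfg$reference_genes$gene_id]
  for (i in seq_len(nrow(quant))) {
    tv <- truth$abundance[truth$gene_id == quant$gene_id[i] &
                            truth$isoform_id == quant$isoform_id[i]]
    expect_equal(quant$norm_abundance[i], tv / exp(mean(log(ref))),
                 tolerance = 1e-9)
  }
})
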