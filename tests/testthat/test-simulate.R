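# Synthetic-data generator: determinism, hierarchical variance structure,
# fixtures, and that generated signals are recoverable downstream.

test_that("simulation is deterministic under a fixed seed and demands one", {
  cf <- sim_config(n_sites = 3L, site_altitudes = c(550, 800, 1050),
                   n_fish_per_site_year = 3L, taxa_mix = c(1, 0, 0),
                   years = 2016L, tissues = "muscle", seed = 9L)
  a <- simulate_csia(cf)
  b <- simulate_csia(cf)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$standards, b$standards)
  expect_identical(a$truth$site_effects, b$truth$site_effects)
  cf$seed <- NULL
  expect_error(simulate_csia(cf), "seed")
})

test_that("fixtures have the documented shapes", {
  tiny <- tiny_calibrated()$sim
  expect_equal(length(unique(tiny$meta$site_id)), 3L)
  expect_equal(length(unique(tiny$meta$fish_id)), 18L)  # 3 sites x 6 fish
  expect_equal(nrow(tiny$peaks), 18L * 11L * 2L)

  ps <- make_fixture("paper_shape")
  expect_equal(length(unique(ps$sites$site_id)), 15L)
  expect_setequal(unique(ps$meta$year), c(2016L, 2018L))
  expect_equal(length(unique(ps$meta$fish_id[ps$meta$year == 2016])), 159L)
  expect_equal(length(unique(ps$meta$fish_id[ps$meta$year == 2018])), 49L)
  expect_identical(unique(ps$meta$taxon[ps$meta$year == 2018]), "C. gobio")
  expect_equal(sort(unique(ps$meta$tissue)), sort(c("muscle", "brain",
                                                    "liver", "eye")))
  expect_error(make_fixture("huge"), "tiny, paper_shape")
})

test_that("per-sample mass fractions are simplex draws", {
  tiny <- tiny_calibrated()$sim
  w <- tapply(tiny$peaks$mass_fraction,
              paste(tiny$peaks$sample_id, tiny$peaks$isotope), sum)
  expect_equal(as.numeric(w), rep(1, length(w)), tolerance = 1e-9)
  expect_true(all(tiny$peaks$mass_fraction > 0))
})

test_that("the calibration chain recovers the simulated true deltas", {
  sim <- tiny_calibrated()$sim
  cal <- tiny_calibrated()$cal
  truth <- sim$truth$delta_fa
  key <- function(d) paste(d$sample_id, d$fa, d$isotope)
  err <- cal$delta_cal - truth$delta_fa_true[match(key(cal), key(truth))]
  # residual error comes only from standards measurement noise
  expect_lt(max(abs(err[cal$isotope == "13C"])), 0.3)
  expect_lt(max(abs(err[cal$isotope == "2H"])), 6)

  # with noise-free standards the chain is exact to numerical precision
  cf <- sim_config(n_sites = 3L, site_altitudes = c(550, 800, 1050),
                   n_fish_per_site_year = 2L, taxa_mix = c(1, 0, 0),
                   years = 2016L, tissues = "muscle",
                   std_noise_13C = 0, std_noise_2H = 0, seed = 4L)
  sim0 <- simulate_csia(cf)
  m13 <- fit_normalization(sim0$standards[sim0$standards$isotope == "13C", ], "13C")
  m2 <- fit_normalization(sim0$standards[sim0$standards$isotope == "2H", ], "2H")
  cal0 <- methylation_correct(calibrate_peaks(sim0$peaks, m13, m2),
                              sim0$methanol)
  t0 <- sim0$truth$delta_fa
  err0 <- cal0$delta_cal - t0$delta_fa_true[match(key(cal0), key(t0))]
  expect_lt(max(abs(err0)), 1e-8)
})

test_that("inter-FA delta-13C correlation tracks the configured equicorrelation", {
  cf <- sim_config(n_sites = 200L, site_altitudes = rep(700, 200),
                   n_fish_per_site_year = 4L, taxa_mix = c(1, 0, 0),
                   years = 2016L, tissues = "muscle",
                   d13C_altitude_slope = 0, residual_sd_13C = 0.01,
                   seed = 12L)
  sim <- simulate_csia(cf)
  fm <- build_feature_matrix(exact_records(sim), sim$meta)
  site_means <- apply(isotope_block(fm, "13C"), 2, function(v)
    tapply(v, fm$meta$site_id, mean))
  cm <- cor(site_means)
  mean_offdiag <- mean(cm[upper.tri(cm)])
  expect_equal(mean_offdiag, cf$within_isotope_corr_13C, tolerance = 0.05)
})

test_that("regressing simulated delta-13C on altitude recovers the slope", {
  cf <- sim_config(n_fish_per_site_year = 8L, taxa_mix = c(1, 0, 0),
                   years = 2016L, tissues = "muscle",
                   site_effect_sd_13C = 0.3, seed = 21L)
  sim <- simulate_csia(cf)
  fm <- build_feature_matrix(exact_records(sim), sim$meta)
  alt_km <- sim$sites$altitude[match(fm$meta$site_id, sim$sites$site_id)] / 1000
  y <- rowMeans(isotope_block(fm, "13C"))
  fit <- summary(lm(y ~ alt_km))
  est <- fit$coefficients["alt_km", ]
  expect_lt(abs(est["Estimate"] - cf$d13C_altitude_slope),
            2 * est["Std. Error"] + 0.3)
  expect_lt(est["Estimate"], 0)
})

test_that("removing the site signal drives repeatability and accuracy to chance", {
  cf <- sim_config(n_sites = 8L, site_altitudes = rep(700, 8),
                   n_fish_per_site_year = 8L, taxa_mix = c(1, 0, 0),
                   years = 2016L, tissues = "muscle",
                   d13C_altitude_slope = 0,
                   site_effect_sd_13C = 0, site_effect_sd_2H = 0,
                   seed = 31L)
  sim <- simulate_csia(cf)
  fm <- build_feature_matrix(exact_records(sim), sim$meta)
  est <- site_repeatability(fm, "d13C_16:0", n_boot = 0)
  expect_lt(est$R, 0.1)
  cv <- bootstrap_cv_accuracy(fm$features, fm$meta$site_id, n_boot = 60,
                              seed = 3)
  expect_lt(cv$cv_accuracy, 2.5 / 8)  # near chance for 8 sites
})

test_that("doubling per-site n shrinks the site-mean standard error as sqrt(n)", {
  se_of <- function(n_per, seeds) {
    vapply(seeds, function(s) {
      cf <- sim_config(n_sites = 6L, site_altitudes = rep(700, 6),
                       n_fish_per_site_year = n_per, taxa_mix = c(1, 0, 0),
                       years = 2016L, tissues = "muscle",
                       d13C_altitude_slope = 0, site_effect_sd_13C = 0,
                       residual_sd_13C = 1, seed = s)
      sim <- simulate_csia(cf)
      fm <- build_feature_matrix(exact_records(sim), sim$meta)
      mean(tapply(fm$features[, "d13C_16:0"], fm$meta$site_id, function(v)
        sd(v) / sqrt(length(v))))
    }, numeric(1))
  }
  r <- mean(se_of(8L, 1:8)) / mean(se_of(32L, 1:8))
  expect_equal(r, 2, tolerance = 0.3)
})
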