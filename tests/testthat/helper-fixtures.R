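# Shared fixtures, computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Tiny simulated dataset taken through the full calibration chain.
tiny_calibrated <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  sim <- make_fixture("tiny")
  m13 <- fit_normalization(sim$standards[sim$standards$isotope == "13C", ], "13C")
  m2 <- fit_normalization(sim$standards[sim$standards$isotope == "2H", ], "2H")
  cal <- methylation_correct(calibrate_peaks(sim$peaks, m13, m2), sim$methanol)
  fm <- build_feature_matrix(cal, sim$meta)
  .fixture_env$tiny <- list(sim = sim, cal = cal, fm = fm,
                            comp = bulk_delta(cal))
  .fixture_env$tiny
}

# Exactly-calibrated records (no standards noise): delta_cal equals truth.
exact_records <- function(sim) {
  cal <- sim$peaks
  truth <- sim$truth$delta_fa
  key <- function(d) paste(d$sample_id, d$fa, d$isotope)
  cal$delta_cal <- truth$delta_fa_true[match(key(cal), key(truth))]
  cal
}

# Write a small delimited file and return its path.
write_fixture_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# One simulated single-variable site-structured dataset for repeatability.
sim_one_variable <- function(site_sd, resid_sd = 1, n_sites = 15L,
                             n_per_site = 10L, seed = 1L) {
  cf <- sim_config(n_sites = n_sites,
                   site_altitudes = rep(700, n_sites),
                   n_fish_per_site_year = n_per_site,
                   taxa_mix = c(1, 0, 0), years = 2016L,
                   tissues = "muscle",
                   d13C_altitude_slope = 0,
                   site_effect_sd_13C = site_sd,
                   residual_sd_13C = resid_sd,
                   seed = seed)
  sim <- simulate_csia(cf)
  cal <- exact_records(sim)
  fm <- build_feature_matrix(cal, sim$meta)
  list(fm = fm, sim = sim)
}
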