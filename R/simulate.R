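# Hierarchical synthetic-data generator: a 15-site, 3-taxon, 4-tissue,
# 2-year stream-network dataset of fatty-acid delta-13C / delta-2H values,
# with an altitude gradient in 13C, site-correlated random effects, and raw
# instrument-scale peaks so the full calibration chain is exercised.

.default_taxa <- c("C. gobio", "O. mykiss", "S. trutta")
.default_tissues <- c("muscle", "brain", "liver", "eye")

# Baseline per-FA means (per-mil, free-acid scale) for a sub-alpine stream
# food web: 13C clustered around -30, 2H spread widely with the C18 PUFA
# precursors LIN (dietary, heavier) and ALA (lighter) far apart so that the
# LIN-ALA difference carries signal.
.fa_baseline <- function(panel) {
  d13C <- c("14:0" = -32, "16:0" = -30, "16:1" = -31, "18:0" = -29,
            "18:1" = -30.5, "LIN" = -31, "ALA" = -33, "ARA" = -32.5,
            "EPA" = -34, "DPA" = -33.5, "DHA" = -33)
  d2H <- c("14:0" = -220, "16:0" = -200, "16:1" = -230, "18:0" = -190,
           "18:1" = -215, "LIN" = -160, "ALA" = -240, "ARA" = -170,
           "EPA" = -250, "DPA" = -245, "DHA" = -255)
  missing <- setdiff(panel, names(d13C))
  if (length(missing) > 0L) {
    d13C[missing] <- -31; d2H[missing] <- -210
  }
  list(`13C` = d13C[panel], `2H` = d2H[panel])
}

.fa_mass_weights <- function(panel) {
  w <- c("14:0" = 0.03, "16:0" = 0.20, "16:1" = 0.06, "18:0" = 0.06,
         "18:1" = 0.18, "LIN" = 0.08, "ALA" = 0.05, "ARA" = 0.05,
         "EPA" = 0.10, "DPA" = 0.03, "DHA" = 0.16)
  missing <- setdiff(panel, names(w))
  if (length(missing) > 0L) w[missing] <- 0.02
  w <- w[panel]
  w / sum(w)
}

#' Configuration for the hierarchical synthetic CSIA dataset
#'
#' Defaults emulate the study conditions the pipeline was designed for: 15
#' sites spanning 525-1070 m a.s.l. in a ~35 km stream network, 3 fish taxa,
#' 4 tissues per fish, two sampling years, an 11-FA panel measured for both
#' isotopes. Site structure differs by isotope: delta-13C carries a negative
#' altitude gradient plus strongly inter-FA-correlated site effects, while
#' delta-2H site effects are weakly correlated across FAs and sit on a much
#' larger residual scale. See the methods vignette for the rationale behind
#' each default.
#'
#' @param n_sites Number of sampling sites.
#' @param site_altitudes Altitudes (m a.s.l.), length `n_sites`.
#' @param n_fish_per_site_year Fish per site per year.
#' @param taxa_mix Proportions over the 3 taxa (bullhead, rainbow trout,
#'   brown trout).
#' @param years Sampling years (first year = full design; second year is
#'   restricted via `year2_sites` / `year2_taxa`).
#' @param year2_sites Site indices sampled in the second year (default: the
#'   first 9, mirroring a reduced resampling campaign).
#' @param year2_taxa Taxa sampled in the second year (default: bullhead only,
#'   the sedentary taxon).
#' @param tissues Tissues dissected per fish.
#' @param panel Fatty-acid panel.
#' @param d13C_altitude_slope Per-mil change in delta-13C per km of altitude
#'   (negative: lighter with altitude).
#' @param site_effect_sd_13C,site_effect_sd_2H SD of the per-(site, FA) random
#'   effects (per-mil).
#' @param within_isotope_corr_13C,within_isotope_corr_2H Equicorrelation of
#'   site effects across FAs within an isotope (high for 13C, low for 2H).
#' @param neighbor_effect_corr Correlation of site effects within the two
#'   sub-kilometre tributary pairs (sites 4/5 and 10/11), emulating shared
#'   water sources at spatially close sites.
#' @param tissue_offsets_13C,tissue_offsets_2H Named per-tissue shifts
#'   (per-mil), applied to every FA.
#' @param taxa_offsets_13C,taxa_offsets_2H Named per-taxon shifts (per-mil).
#' @param year_drift_sd_13C,year_drift_sd_2H SD of the independent
#'   per-(site, FA) second-year shocks (per-mil).
#' @param residual_sd_13C,residual_sd_2H Residual (within-site) SDs (per-mil).
#' @param mass_fraction_concentration Dirichlet concentration governing
#'   sample-to-sample variability of FA mass fractions.
#' @param cal_slope_13C,cal_intercept_13C,cal_slope_2H,cal_intercept_2H True
#'   instrument-scale calibration used to de-calibrate emitted peaks.
#' @param methanol_d13C,methanol_d2H Methanol deltas used in the generative
#'   FAME mass balance.
#' @param std_noise_13C,std_noise_2H Measurement noise on the reference
#'   standards (per-mil).
#' @param n_std_reps Replicate measurements per standard.
#' @param seed Integer seed (mandatory; simulation refuses to run without).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 15L,
                       site_altitudes = round(seq(525, 1070, length.out = n_sites)),
                       n_fish_per_site_year = 10L,
                       taxa_mix = c(0.40, 0.23, 0.37),
                       years = c(2016L, 2018L),
                       year2_sites = seq_len(min(9L, n_sites)),
                       year2_taxa = "C. gobio",
                       tissues = .default_tissues,
                       panel = core_panel(),
                       d13C_altitude_slope = -5,
                       site_effect_sd_13C = 1.5,
                       site_effect_sd_2H = 5,
                       within_isotope_corr_13C = 0.7,
                       within_isotope_corr_2H = 0.3,
                       tissue_offsets_13C = c(muscle = 0, brain = 1.5,
                                              liver = -1, eye = 0.5),
                       tissue_offsets_2H = c(muscle = 0, brain = 30,
                                             liver = -15, eye = 10),
                       taxa_offsets_13C = c("C. gobio" = 0, "O. mykiss" = 0.5,
                                            "S. trutta" = -0.3),
                       taxa_offsets_2H = c("C. gobio" = 0, "O. mykiss" = 15,
                                           "S. trutta" = 10),
                       year_drift_sd_13C = 1.2,
                       year_drift_sd_2H = 6,
                       residual_sd_13C = 0.8,
                       residual_sd_2H = 8,
                       neighbor_effect_corr = 0.8,
                       mass_fraction_concentration = 200,
                       cal_slope_13C = 0.98, cal_intercept_13C = 1.5,
                       cal_slope_2H = 1.05, cal_intercept_2H = -8,
                       methanol_d13C = -38.5, methanol_d2H = -120,
                       std_noise_13C = 0.1, std_noise_2H = 2,
                       n_std_reps = 3L,
                       seed = NULL) {
  stopifnot(length(site_altitudes) == n_sites,
            abs(sum(taxa_mix) - 1) < 1e-8,
            site_effect_sd_13C >= 0, site_effect_sd_2H >= 0,
            residual_sd_13C >= 0, residual_sd_2H >= 0,
            within_isotope_corr_13C >= 0, within_isotope_corr_13C <= 1,
            within_isotope_corr_2H >= 0, within_isotope_corr_2H <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Correlated site effects: one shared latent draw per (site, isotope),
# blended with independent per-FA draws under an equicorrelation structure.
.site_effects <- function(n_sites, n_fa, sd, rho) {
  shared <- stats::rnorm(n_sites)
  own <- matrix(stats::rnorm(n_sites * n_fa), n_sites, n_fa)
  sd * (sqrt(rho) * shared + sqrt(1 - rho) * own)
}

#' Simulate a hierarchical compound-specific isotope dataset
#'
#' Draws, for every fish x tissue x fatty acid x isotope, a free-acid delta
#' value composed of the FA baseline, a site altitude term (13C only), a
#' site random effect shared across FAs with the configured equicorrelation,
#' tissue and taxon offsets, an independent per-(site, FA) second-year
#' shock, and residual noise. The free-acid values are then pushed through
#' the generative FAME mass balance and the inverse of the configured
#' calibration, so the emitted peak table is on the raw instrument scale and
#' the full calibration chain can be exercised downstream. Replicate
#' reference-standard measurements under the same calibration are emitted
#' alongside.
#'
#' @param config A [sim_config()] with a non-NULL `seed`.
#' @return List with `peaks` (raw-scale peak table), `meta`, `sites`,
#'   `standards` (per-isotope standard measurements), `methanol`, and
#'   `truth` (site effects, year shocks, true free-acid deltas per sample).
#' @export
simulate_csia <- function(config = sim_config(seed = 1L)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("sim_config seed is mandatory", call. = FALSE)
  cf <- config
  set.seed(cf$seed)
  n_fa <- length(cf$panel)
  baseline <- .fa_baseline(cf$panel)
  site_ids <- sprintf("S%02d", seq_len(cf$n_sites))

  # fish plan
  plan <- list()
  taxa_n <- round(cf$taxa_mix * cf$n_fish_per_site_year)
  taxa_n[1] <- cf$n_fish_per_site_year - sum(taxa_n[-1])
  for (s in seq_len(cf$n_sites)) {
    plan[[length(plan) + 1L]] <- data.frame(
      site = s, year = cf$years[1],
      taxon = rep(.default_taxa, times = taxa_n), stringsAsFactors = FALSE)
  }
  if (length(cf$years) > 1L) {
    for (s in cf$year2_sites) {
      plan[[length(plan) + 1L]] <- data.frame(
        site = s, year = cf$years[2],
        taxon = rep(cf$year2_taxa,
                    length.out = ceiling(cf$n_fish_per_site_year / 2)),
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, plan)
  if (nrow(plan) == 0L) stop("Zero fish requested", call. = FALSE)
  plan$fish_id <- sprintf("F%04d", seq_len(nrow(plan)))

  # latent structure
  site_eff <- list(
    `13C` = .site_effects(cf$n_sites, n_fa, cf$site_effect_sd_13C,
                          cf$within_isotope_corr_13C),
    `2H` = .site_effects(cf$n_sites, n_fa, cf$site_effect_sd_2H,
                         cf$within_isotope_corr_2H))
  # the two < 1 km tributary pairs share water sources, so their site
  # effects are strongly correlated (they mirror the isotopically-similar
  # close site pairs that motivate pooling)
  rho_n <- cf$neighbor_effect_corr
  for (pair in list(c(4L, 5L), c(10L, 11L))) {
    if (cf$n_sites >= pair[2]) {
      for (iso in names(site_eff)) {
        site_eff[[iso]][pair[2], ] <- rho_n * site_eff[[iso]][pair[1], ] +
          sqrt(1 - rho_n^2) * site_eff[[iso]][pair[2], ]
      }
    }
  }
  drift <- list(
    `13C` = matrix(stats::rnorm(cf$n_sites * n_fa, 0, cf$year_drift_sd_13C),
                   cf$n_sites, n_fa),
    `2H` = matrix(stats::rnorm(cf$n_sites * n_fa, 0, cf$year_drift_sd_2H),
                  cf$n_sites, n_fa))
  for (iso in names(site_eff)) {
    dimnames(site_eff[[iso]]) <- dimnames(drift[[iso]]) <-
      list(site_ids, cf$panel)
  }
  alt_km <- cf$site_altitudes / 1000
  residual_sd <- c(`13C` = cf$residual_sd_13C, `2H` = cf$residual_sd_2H)
  tissue_off <- list(`13C` = cf$tissue_offsets_13C, `2H` = cf$tissue_offsets_2H)
  taxa_off <- list(`13C` = cf$taxa_offsets_13C, `2H` = cf$taxa_offsets_2H)
  methanol <- methanol_reference(cf$methanol_d13C, cf$methanol_d2H)
  cal <- list(`13C` = c(slope = cf$cal_slope_13C, intercept = cf$cal_intercept_13C),
              `2H` = c(slope = cf$cal_slope_2H, intercept = cf$cal_intercept_2H))
  fa_structs <- lapply(cf$panel, parse_fa_name)
  names(fa_structs) <- cf$panel
  base_w <- .fa_mass_weights(cf$panel)

  n_fish <- nrow(plan)
  n_tis <- length(cf$tissues)
  n_samples <- n_fish * n_tis
  meta <- data.frame(
    sample_id = sprintf("SMP%05d", seq_len(n_samples)),
    fish_id = rep(plan$fish_id, each = n_tis),
    taxon = rep(plan$taxon, each = n_tis),
    tissue = rep(cf$tissues, times = n_fish),
    site_id = rep(site_ids[plan$site], each = n_tis),
    year = rep(plan$year, each = n_tis),
    stringsAsFactors = FALSE)

  # one block of n_fa rows per (sample, isotope); columns preallocated
  n_blocks <- 2L * n_samples
  raw_col <- numeric(n_blocks * n_fa)
  mf_col <- numeric(n_blocks * n_fa)
  true_col <- numeric(n_blocks * n_fa)
  iso_col <- character(n_blocks)
  samp_col <- character(n_blocks)
  # per-FA mass-balance weights on the free-acid -> FAME map
  mb <- lapply(c("13C", "2H"), function(iso) {
    cnt <- vapply(fa_structs, function(f)
      unlist(.mass_balance_counts(f, iso)), numeric(2))
    d_meoh <- if (iso == "13C") methanol$d13C else methanol$d2H
    list(n_fame = cnt["n_fame", ], n_me = cnt["n_me", ], d_meoh = d_meoh)
  })
  names(mb) <- c("13C", "2H")
  pidx <- 0L
  for (i in seq_len(n_samples)) {
    s <- plan$site[(i - 1L) %/% n_tis + 1L]
    second_year <- meta$year[i] != cf$years[1]
    mf <- .rdirichlet1(base_w * cf$mass_fraction_concentration)
    for (iso in c("13C", "2H")) {
      mu <- baseline[[iso]] +
        site_eff[[iso]][s, ] +
        tissue_off[[iso]][[meta$tissue[i]]] +
        taxa_off[[iso]][[meta$taxon[i]]] +
        (if (second_year) drift[[iso]][s, ] else 0) +
        (if (iso == "13C") cf$d13C_altitude_slope * alt_km[s] else 0)
      delta_fa <- mu + stats::rnorm(n_fa, 0, residual_sd[[iso]])
      w <- mb[[iso]]
      delta_fame <- ((w$n_fame - w$n_me) * delta_fa + w$n_me * w$d_meoh) /
        w$n_fame
      pidx <- pidx + 1L
      rows <- ((pidx - 1L) * n_fa + 1L):(pidx * n_fa)
      raw_col[rows] <- (delta_fame - cal[[iso]][["intercept"]]) /
        cal[[iso]][["slope"]]
      mf_col[rows] <- mf
      true_col[rows] <- delta_fa
      iso_col[pidx] <- iso
      samp_col[pidx] <- meta$sample_id[i]
    }
  }
  peaks <- data.frame(
    sample_id = rep(samp_col, each = n_fa),
    fa = rep(cf$panel, times = n_blocks),
    isotope = rep(iso_col, each = n_fa),
    delta_raw = raw_col, mass_fraction = mf_col,
    delta_cal = NA_real_, stringsAsFactors = FALSE)
  truth_delta <- data.frame(
    sample_id = peaks$sample_id, fa = peaks$fa, isotope = peaks$isotope,
    delta_fa_true = true_col, stringsAsFactors = FALSE)

  # site table: stream-like layout, distance roughly following altitude
  # order; two tributary pairs sit < 1 km apart, as happens in dense stream
  # networks, so distance-tolerant scoring is exercised
  theta <- seq(0, 2.2, length.out = cf$n_sites)
  x_km <- 17 * cos(theta) + seq(0, 6, length.out = cf$n_sites)
  y_km <- 11 * sin(theta)
  if (cf$n_sites >= 5L) {
    x_km[5] <- x_km[4] + 0.3; y_km[5] <- y_km[4] + 0.4
  }
  if (cf$n_sites >= 11L) {
    x_km[11] <- x_km[10] + 0.5; y_km[11] <- y_km[10] + 0.3
  }
  sites <- data.frame(
    site_id = site_ids,
    altitude = cf$site_altitudes,
    x_km = round(x_km, 3),
    y_km = round(y_km, 3),
    stringsAsFactors = FALSE)

  # standards measured under the same (inverse) calibration
  stds <- usgs_standards()
  std_rows <- list()
  for (iso in c("13C", "2H")) {
    acc <- if (iso == "13C") stds$d13C else stds$d2H
    noise_sd <- if (iso == "13C") cf$std_noise_13C else cf$std_noise_2H
    for (r in seq_len(cf$n_std_reps)) {
      std_rows[[length(std_rows) + 1L]] <- data.frame(
        standard = stds$name, isotope = iso, rep = r,
        delta_raw = (acc - cal[[iso]][["intercept"]]) / cal[[iso]][["slope"]] +
          stats::rnorm(nrow(stds), 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  standards <- do.call(rbind, std_rows)

  list(peaks = peaks, meta = meta, sites = sites, standards = standards,
       methanol = methanol,
       truth = list(site_effects = site_eff, year_drift = drift,
                    delta_fa = truth_delta,
                    config = cf))
}

#' Named bundled simulation fixtures
#'
#' Deterministic datasets regenerated from fixed seeds:
#' * `"tiny"` — 3 sites x 6 fish, one taxon, muscle only, single year; a
#'   seconds-scale smoke-test input.
#' * `"paper_shape"` — the full study shape: 15 sites, 3 taxa, 4 tissues,
#'   first-year n = 159 fish plus a second-year bullhead-only resampling of
#'   49 fish at 9 sites.
#'
#' @param name Fixture name.
#' @return Output of [simulate_csia()].
#' @export
make_fixture <- function(name = c("tiny", "paper_shape")) {
  if (!name[1] %in% c("tiny", "paper_shape")) {
    stop("Unknown fixture '", name[1], "'; available: tiny, paper_shape",
         call. = FALSE)
  }
  name <- match.arg(name)
  if (name == "tiny") {
    cf <- sim_config(n_sites = 3L, site_altitudes = c(550, 800, 1050),
                     n_fish_per_site_year = 6L, taxa_mix = c(1, 0, 0),
                     years = 2016L, tissues = "muscle", seed = 101L)
    return(simulate_csia(cf))
  }
  # paper_shape: 159 first-year fish over 15 sites (11 at 9 sites, 10 at 6),
  # 49 second-year bullheads over 9 sites; realised by simulating a uniform
  # 11-per-site plan and thinning deterministically to the target counts.
  cf <- sim_config(n_fish_per_site_year = 11L, seed = 2016L)
  sim <- simulate_csia(cf)
  first <- cf$years[1]
  fish1 <- unique(sim$meta$fish_id[sim$meta$year == first])
  site_of <- sim$meta$site_id[match(fish1, sim$meta$fish_id)]
  drop1 <- unlist(lapply(split(fish1, site_of)[sprintf("S%02d", 10:15)],
                         function(f) f[1]), use.names = FALSE)
  fish2 <- unique(sim$meta$fish_id[sim$meta$year != first])
  site_of2 <- sim$meta$site_id[match(fish2, sim$meta$fish_id)]
  drop2 <- unlist(lapply(split(fish2, site_of2)[sprintf("S%02d", 1:5)],
                         function(f) f[1]), use.names = FALSE)
  keep_fish <- setdiff(unique(sim$meta$fish_id), c(drop1, drop2))
  keep_samples <- sim$meta$sample_id[sim$meta$fish_id %in% keep_fish]
  sim$meta <- sim$meta[sim$meta$fish_id %in% keep_fish, , drop = FALSE]
  sim$peaks <- sim$peaks[sim$peaks$sample_id %in% keep_samples, , drop = FALSE]
  sim$truth$delta_fa <-
    sim$truth$delta_fa[sim$truth$delta_fa$sample_id %in% keep_samples, , drop = FALSE]
  rownames(sim$meta) <- rownames(sim$peaks) <- NULL
  sim
}
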