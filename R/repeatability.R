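# Site-specific repeatability: fraction of variance attributable to sampling
# site after fixed-effect adjustment for taxa, tissue and year, with a
# parametric bootstrap CI. REML via lme4; an ANOVA moment estimator serves
# as an independent cross-check.

.repeat_frame <- function(fm, variable, meta = NULL) {
  if (inherits(fm, "feature_matrix")) {
    if (!variable %in% colnames(fm$features)) {
      stop("Variable ", variable, " not in feature matrix", call. = FALSE)
    }
    data.frame(y = fm$features[, variable], fm$meta, stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(meta), length(fm) == nrow(meta))
    data.frame(y = fm, meta, stringsAsFactors = FALSE)
  }
}

.check_site_confounding <- function(df, covariates) {
  for (cv in covariates) {
    lv <- df[[cv]]
    const_within <- all(tapply(lv, df$site_id, function(v) length(unique(v)) == 1L))
    if (const_within && length(unique(lv)) == length(unique(df$site_id))) {
      stop("Covariate '", cv, "' is confounded 1:1 with site_id; ",
           "site repeatability is not identifiable", call. = FALSE)
    }
  }
}

#' Site-specific repeatability of one isotope variable
#'
#' Fits `y ~ covariates + (1 | site_id)` by REML and reports
#' `R = var_site / (var_site + var_residual)` — the adjusted repeatability:
#' the share of variance (after removing fixed-effect group means for taxa,
#' tissue and/or year) that lies between sampling sites. The confidence
#' interval is a seeded parametric bootstrap: responses are resimulated from
#' the fitted model, the model is refitted, and R recomputed, `n_boot` times;
#' the percentile interval is returned.
#'
#' @param fm A `feature_matrix`, or a numeric vector (then supply `meta`).
#' @param variable Column name in `fm$features` (e.g. `"d2H_ALA"`); ignored
#'   when `fm` is a numeric vector.
#' @param fixed_covariates Subset of `c("taxon", "tissue", "year")` entering
#'   as fixed effects; covariates with a single observed level are dropped
#'   automatically.
#' @param n_boot Number of parametric bootstrap replicates (0 skips the CI).
#' @param seed Integer seed for the bootstrap (mandatory when `n_boot > 0`).
#' @param meta Metadata data frame when `fm` is a plain vector.
#' @return An object of class `repeatability_estimate`: list with `variable`,
#'   `R`, `ci_low`, `ci_high`, `n_boot`, `var_between`, `var_within`,
#'   `n_sites`, `n_obs`, `boot_R` (replicate values).
#' @export
site_repeatability <- function(fm, variable = NULL,
                               fixed_covariates = c("taxon", "tissue", "year"),
                               n_boot = 1000L, seed = NULL, meta = NULL) {
  df <- .repeat_frame(fm, variable, meta)
  df <- df[!is.na(df$y), , drop = FALSE]
  site_n <- table(df$site_id)
  if (sum(site_n >= 2L) < 2L) {
    stop("Need >= 2 sites with >= 2 samples each", call. = FALSE)
  }
  covs <- intersect(fixed_covariates, names(df))
  covs <- covs[vapply(covs, function(cv) length(unique(df[[cv]])) > 1L, logical(1))]
  .check_site_confounding(df, covs)
  for (cv in covs) df[[cv]] <- factor(df[[cv]])
  df$site_id <- factor(df$site_id)
  fixed <- if (length(covs) > 0L) paste(covs, collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", fixed, "+ (1 | site_id)"))
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  R_of <- function(m) {
    vc <- lme4::VarCorr(m)
    vs <- as.numeric(vc$site_id[1])
    ve <- attr(vc, "sc")^2
    if (vs < 0) vs <- 0
    vs / (vs + ve)
  }
  vc <- lme4::VarCorr(fit)
  var_between <- as.numeric(vc$site_id[1])
  var_within <- attr(vc, "sc")^2
  R <- R_of(fit)
  ci <- c(NA_real_, NA_real_)
  boot_R <- numeric(0)
  if (n_boot > 0L) {
    if (is.null(seed)) stop("seed is mandatory for the bootstrap", call. = FALSE)
    set.seed(seed)
    ysim <- stats::simulate(fit, nsim = n_boot)
    boot_R <- vapply(seq_len(n_boot), function(b) {
      dfb <- df
      dfb$y <- ysim[[b]]
      R_of(suppressWarnings(suppressMessages(
        lme4::lmer(form, data = dfb, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE)))))
    }, numeric(1))
    ci <- unname(stats::quantile(boot_R, c(0.025, 0.975)))
  }
  structure(list(variable = if (is.null(variable)) "y" else variable,
                 R = R, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, var_between = var_between,
                 var_within = var_within,
                 n_sites = nlevels(df$site_id), n_obs = nrow(df),
                 covariates = covs, boot_R = boot_R),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability> %s: R = %.3f", x$variable, x$R))
  if (x$n_boot > 0L) {
    cat(sprintf(" [%.3f, %.3f] (%d bootstrap)", x$ci_low, x$ci_high, x$n_boot))
  }
  cat(sprintf("\n  var_between = %.4g, var_within = %.4g (%d sites, %d obs)\n",
              x$var_between, x$var_within, x$n_sites, x$n_obs))
  invisible(x)
}

#' ANOVA moment estimator of site repeatability (cross-check)
#'
#' Residualizes `y` on the fixed covariates with an ordinary linear model,
#' then applies the one-way ANOVA variance-component estimator on the
#' residuals: `sigma2_b = (MSB - MSW) / n0` with the unbalanced-design
#' average group size `n0 = (N - sum(n_i^2)/N) / (k - 1)`, floored at zero.
#' On balanced designs this agrees closely with the REML fit and serves as
#' its independent oracle.
#'
#' @inheritParams site_repeatability
#' @return List with `R`, `var_between`, `var_within`.
#' @export
site_repeatability_anova <- function(fm, variable = NULL,
                                     fixed_covariates = c("taxon", "tissue", "year"),
                                     meta = NULL) {
  df <- .repeat_frame(fm, variable, meta)
  df <- df[!is.na(df$y), , drop = FALSE]
  covs <- intersect(fixed_covariates, names(df))
  covs <- covs[vapply(covs, function(cv) length(unique(df[[cv]])) > 1L, logical(1))]
  .check_site_confounding(df, covs)
  y <- df$y
  if (length(covs) > 0L) {
    for (cv in covs) df[[cv]] <- factor(df[[cv]])
    y <- stats::residuals(stats::lm(stats::as.formula(
      paste("y ~", paste(covs, collapse = " + "))), data = df))
  }
  g <- factor(df$site_id)
  k <- nlevels(g)
  N <- length(y)
  ni <- tabulate(g)
  means <- tapply(y, g, mean)
  ssb <- sum(ni * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vb <- max((msb - msw) / n0, 0)
  list(R = vb / (vb + msw), var_between = vb, var_within = msw)
}

#' Repeatability table across variables and tissues
#'
#' Convenience wrapper producing a tissue-by-variable repeatability matrix
#' (one row per (variable, tissue)), mirroring the shape in which
#' site-specific repeatability of fatty-acid isotopes is usually tabulated.
#'
#' @param fm A `feature_matrix` containing all tissues.
#' @param variables Feature column names (default: all).
#' @param by_tissue Split by tissue (default TRUE; tissue is then excluded
#'   from the fixed covariates within each stratum).
#' @inheritParams site_repeatability
#' @return Data frame with `variable`, `tissue`, `R`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
repeatability_table <- function(fm, variables = colnames(fm$features),
                                by_tissue = TRUE, n_boot = 0L, seed = NULL) {
  tissues <- if (by_tissue) unique(fm$meta$tissue) else "all"
  rows <- list()
  for (tis in tissues) {
    sub <- if (by_tissue) subset_features(fm, fm$meta$tissue == tis) else fm
    for (v in variables) {
      est <- tryCatch(
        site_repeatability(sub, v,
                           fixed_covariates = c("taxon", "year"),
                           n_boot = n_boot,
                           seed = if (n_boot > 0L) seed + length(rows) else NULL),
        error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, tissue = tis, R = est$R,
        ci_low = est$ci_low, ci_high = est$ci_high, n = est$n_obs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
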