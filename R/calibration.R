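# Raw instrument deltas -> VPDB/VSMOW fatty-acid deltas:
# drift correction, three-point scale normalization, methyl mass balance.

#' Certified USGS FAME reference standards
#'
#' Accepted values of the three certified icosanoic acid methyl ester
#' (Me-C20:0) isotope standards used for three-point scale normalization:
#' USGS70 (delta-13C -30.53, delta-2H -183.9), USGS71 (-10.5, -4.9) and
#' USGS72 (-1.54, +348.3), per-mil on VPDB / VSMOW.
#'
#' @return Data frame with columns `name`, `d13C`, `d2H`.
#' @export
usgs_standards <- function() {
  data.frame(
    name = c("USGS70", "USGS71", "USGS72"),
    d13C = c(-30.53, -10.5, -1.54),
    d2H  = c(-183.9, -4.9, 348.3),
    stringsAsFactors = FALSE
  )
}

#' Methanol reference values for methylation correction
#'
#' The delta values of the methanol used during FAME derivatization. Both are
#' required: there are no defaults, because silently assuming a methanol
#' composition would bias every corrected fatty-acid value.
#'
#' @param d13C Methanol delta-13C, per-mil VPDB.
#' @param d2H Methanol delta-2H, per-mil VSMOW.
#' @return An object of class `methanol_reference`.
#' @export
methanol_reference <- function(d13C, d2H) {
  stopifnot(is.numeric(d13C), is.numeric(d2H), is.finite(d13C), is.finite(d2H))
  structure(list(d13C = d13C, d2H = d2H), class = "methanol_reference")
}

#' Fit a three-point scale normalization (with optional drift removal)
#'
#' Ordinary least squares mapping drift-corrected measured standard deltas to
#' their accepted values. If `run_index` is supplied, a linear per-run drift
#' term is first estimated (jointly with the scale map, via
#' `lm(measured ~ accepted + run_index)`) and removed from the measured
#' values before the accepted-on-measured normalization line is fitted.
#'
#' @param measured Data frame with columns `standard`, `delta_raw` and
#'   optionally `run_index`.
#' @param isotope `"13C"` or `"2H"`.
#' @param standards Registry of accepted values (default [usgs_standards()]).
#' @return An object of class `calibration_model` with `isotope`, `slope`,
#'   `intercept`, `drift_rate` (NULL if no run index), and per-standard
#'   `fit_residuals` on the accepted scale.
#' @export
fit_normalization <- function(measured, isotope = c("13C", "2H"),
                              standards = usgs_standards()) {
  isotope <- match.arg(isotope)
  .require_columns(measured, c("standard", "delta_raw"), "Standards table")
  acc_col <- if (isotope == "13C") "d13C" else "d2H"
  idx <- match(measured$standard, standards$name)
  if (anyNA(idx)) {
    stop("Unknown standard(s): ",
         paste(unique(measured$standard[is.na(idx)]), collapse = ", "),
         "; registered: ", paste(standards$name, collapse = ", "),
         call. = FALSE)
  }
  accepted <- standards[[acc_col]][idx]
  if (length(unique(measured$standard)) < 2L) {
    stop("Scale normalization needs >= 2 distinct standards", call. = FALSE)
  }
  drift_rate <- NULL
  x <- measured$delta_raw
  if ("run_index" %in% names(measured) && !all(is.na(measured$run_index)) &&
      stats::var(measured$run_index) > 0) {
    dfit <- stats::lm(x ~ accepted + run_index, data = cbind(measured, accepted = accepted))
    drift_rate <- unname(stats::coef(dfit)[["run_index"]])
    x <- x - drift_rate * measured$run_index
  }
  if (stats::var(x) < .Machine$double.eps) {
    stop("Degenerate standards: measured values are identical", call. = FALSE)
  }
  fit <- stats::lm(accepted ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("Fitted normalization slope is not positive", call. = FALSE)
  res <- stats::residuals(fit)
  names(res) <- measured$standard
  structure(list(isotope = isotope,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 drift_rate = drift_rate,
                 fit_residuals = res,
                 n_standards = length(unique(measured$standard))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: delta_cal = %.5f * delta_raw %+.5f\n",
              x$isotope, x$slope, x$intercept))
  if (!is.null(x$drift_rate)) {
    cat(sprintf("  drift removed: %+.5f per-mil per run index\n", x$drift_rate))
  }
  cat(sprintf("  residual SD over %d standards: %.4f per-mil\n",
              x$n_standards, stats::sd(x$fit_residuals)))
  invisible(x)
}

#' Apply a fitted normalization to peak records
#'
#' Sets `delta_cal = slope * (delta_raw - drift_rate * run_index) +
#' intercept`, putting the records on the VPDB (13C) or VSMOW (2H) FAME
#' scale. Re-applying to already-calibrated records is an error, as is an
#' isotope mismatch between model and records.
#'
#' @param model A `calibration_model`.
#' @param records Peak records of the model's isotope (a `run_index` column is
#'   used if the model carries a drift term).
#' @return The records with `delta_cal` populated.
#' @export
apply_normalization <- function(model, records) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(records$isotope != model$isotope)) {
    stop("Isotope mismatch: model is for ", model$isotope,
         " but records contain ",
         paste(setdiff(unique(records$isotope), model$isotope), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(records$delta_cal))) {
    stop("Records already calibrated; refusing to re-apply normalization",
         call. = FALSE)
  }
  x <- records$delta_raw
  if (!is.null(model$drift_rate)) {
    if (!"run_index" %in% names(records)) {
      stop("Model carries a drift term but records lack run_index", call. = FALSE)
    }
    x <- x - model$drift_rate * records$run_index
  }
  records$delta_cal <- model$slope * x + model$intercept
  records
}

#' Calibrate a mixed-isotope peak table with per-isotope models
#'
#' Convenience wrapper splitting the records by isotope and applying the
#' matching model to each block.
#'
#' @param records Peak records containing one or both isotopes.
#' @param model_13C,model_2H `calibration_model`s (either may be NULL if that
#'   isotope is absent).
#' @return Calibrated records in the original row order.
#' @export
calibrate_peaks <- function(records, model_13C = NULL, model_2H = NULL) {
  out <- records
  for (iso in intersect(.allowed_isotopes, unique(records$isotope))) {
    model <- if (iso == "13C") model_13C else model_2H
    if (is.null(model)) {
      stop("Records contain ", iso, " peaks but no ", iso,
           " calibration model was supplied", call. = FALSE)
    }
    sel <- out$isotope == iso
    out[sel, ] <- apply_normalization(model, out[sel, , drop = FALSE])
  }
  out
}

# Atom counts entering the methyl mass balance: the added methoxy methyl
# contributes 1 C and 3 H; n_FAME is the total atom count of the ester.
.mass_balance_counts <- function(fa, isotope) {
  if (isotope == "13C") {
    list(n_fame = fa$c_count_fame, n_me = 1L)
  } else {
    list(n_fame = fa$h_count_fame, n_me = 3L)
  }
}

#' Correct FAME deltas for the methyl group added during methylation
#'
#' Linear isotope mass balance on the delta scale:
#' `delta_FA = (n_FAME * delta_FAME - n_Me * delta_MeOH) / (n_FAME - n_Me)`,
#' where `n_FAME` is the total count of the element's atoms in the methyl
#' ester (carbons + 1 for 13C; `2*carbons - 2*double_bonds + 2` hydrogens for
#' 2H) and `n_Me` is the methyl contribution (1 C / 3 H). The approximation
#' of mixing on the delta rather than atom-fraction scale is accurate to well
#' under 0.1 per-mil over the natural-abundance range.
#'
#' @param records Calibrated peak records (FAME scale, `delta_cal` set).
#' @param methanol A [methanol_reference()].
#' @return Records with `delta_cal` moved to the free-fatty-acid scale and a
#'   logical `methyl_corrected` column set.
#' @export
methylation_correct <- function(records, methanol) {
  stopifnot(inherits(methanol, "methanol_reference"))
  if (any(is.na(records$delta_cal))) {
    stop("Records must be scale-normalized before methylation correction",
         call. = FALSE)
  }
  if (isTRUE(any(records$methyl_corrected))) {
    stop("Records already methylation-corrected", call. = FALSE)
  }
  fas <- lapply(unique(records$fa), parse_fa_name)
  names(fas) <- unique(records$fa)
  unreg <- vapply(fas, function(f) is.na(f$carbons), logical(1))
  if (any(unreg)) {
    stop("Fatty acid(s) without a registered structure (atom counts unknown): ",
         paste(names(fas)[unreg], collapse = ", "),
         if ("HTA" %in% names(fas)[unreg]) "; register HTA via register_hta()" else "",
         call. = FALSE)
  }
  d_meoh <- c("13C" = methanol$d13C, "2H" = methanol$d2H)
  out <- records
  for (i in seq_len(nrow(out))) {
    cnt <- .mass_balance_counts(fas[[out$fa[i]]], out$isotope[i])
    if (cnt$n_fame <= cnt$n_me) {
      stop("Degenerate mass balance for ", out$fa[i], " (", out$isotope[i],
           "): n_FAME <= n_Me", call. = FALSE)
    }
    out$delta_cal[i] <- (cnt$n_fame * out$delta_cal[i] -
                           cnt$n_me * d_meoh[[out$isotope[i]]]) /
      (cnt$n_fame - cnt$n_me)
  }
  out$methyl_corrected <- TRUE
  out
}

#' Recombine a corrected fatty-acid delta with the methanol pool
#'
#' Inverse of the mass balance in [methylation_correct()]: given the
#' free-acid delta, returns the FAME-scale delta. Used for mass-conservation
#' checks and by the synthetic-data generator.
#'
#' @param delta_fa Free fatty-acid delta (per-mil).
#' @param fa A `fatty_acid` (from [parse_fa_name()]).
#' @param isotope `"13C"` or `"2H"`.
#' @param methanol A [methanol_reference()].
#' @return FAME-scale delta (per-mil).
#' @export
fame_from_fa <- function(delta_fa, fa, isotope, methanol) {
  cnt <- .mass_balance_counts(fa, isotope)
  d_meoh <- if (isotope == "13C") methanol$d13C else methanol$d2H
  ((cnt$n_fame - cnt$n_me) * delta_fa + cnt$n_me * d_meoh) / cnt$n_fame
}
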