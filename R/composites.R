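# Per-sample derived quantities: mass-fraction weighted bulk composites,
# fatty-acid pair differences, per-FA correlation with the bulk value.

#' Mass-fraction-weighted bulk fatty-acid delta composites
#'
#' For each (sample, isotope), the "bulk lipid" proxy: the sum of each
#' identified peak's delta times its mass fraction, divided by the sum of the
#' mass fractions. All identified peaks of the sample contribute by default;
#' pass `panel` to restrict to a panel subset for sensitivity analysis. The
#' 13C and 2H composites are computed from each isotope's own peak set, since
#' fewer peaks are typically identified for 2H.
#'
#' @param records Calibrated peak records.
#' @param panel Optional character vector of fatty-acid codes to restrict to.
#' @return Data frame with columns `sample_id`, `isotope`, `value`,
#'   `n_peaks_used`, `mass_covered` (sum of the raw mass fractions used).
#' @export
bulk_delta <- function(records, panel = NULL) {
  if (any(is.na(records$delta_cal))) {
    stop("bulk_delta requires calibrated records", call. = FALSE)
  }
  if (!is.null(panel)) records <- records[records$fa %in% panel, , drop = FALSE]
  if (nrow(records) == 0L) stop("No peaks to composite", call. = FALSE)
  groups <- split(records, list(records$sample_id, records$isotope), drop = TRUE)
  out <- lapply(groups, function(g) {
    wsum <- sum(g$mass_fraction)
    if (wsum <= 0) {
      stop("All mass fractions are zero for sample ", g$sample_id[1],
           " (", g$isotope[1], ")", call. = FALSE)
    }
    data.frame(sample_id = g$sample_id[1],
               isotope = g$isotope[1],
               value = sum(g$mass_fraction * g$delta_cal) / wsum,
               n_peaks_used = nrow(g),
               mass_covered = wsum,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$isotope), , drop = FALSE]
}

#' Per-sample difference between two fatty acids' deltas
#'
#' `delta(fa_a) - delta(fa_b)` for one isotope, per sample. The
#' delta-2H LIN minus ALA difference is the motivating case: the two C18
#' PUFAs respond differently to site water, so their spread is a strong
#' site marker.
#'
#' @param fm A `feature_matrix`.
#' @param isotope `"13C"` or `"2H"`.
#' @param fa_a,fa_b Fatty-acid codes present in the panel.
#' @return Named numeric vector (sample ids); NA where either FA is missing.
#' @export
pair_difference <- function(fm, isotope = c("13C", "2H"), fa_a, fa_b) {
  isotope <- match.arg(isotope)
  prefix <- if (isotope == "13C") "d13C_" else "d2H_"
  cols <- paste0(prefix, c(fa_a, fa_b))
  missing <- setdiff(cols, colnames(fm$features))
  if (length(missing) > 0L) {
    stop("Feature(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- fm$features[, cols[1]] - fm$features[, cols[2]]
  names(d) <- rownames(fm$features)
  d
}

#' Pearson correlation of each fatty acid's delta with the bulk composite
#'
#' For one isotope, correlates each panel FA's delta values with the
#' sample-matched bulk composite over complete cases, and summarizes the
#' per-FA coefficients as mean +/- SD. FAs with fewer than 3 complete pairs
#' get `NA`.
#'
#' @param fm A `feature_matrix`.
#' @param composites Output of [bulk_delta()].
#' @param isotope `"13C"` or `"2H"`.
#' @return List with `per_fa` (data frame `fa`, `r`, `n`) and `summary`
#'   (`mean_r`, `sd_r` over non-missing coefficients).
#' @export
correlate_with_bulk <- function(fm, composites, isotope = c("13C", "2H")) {
  isotope <- match.arg(isotope)
  prefix <- if (isotope == "13C") "d13C_" else "d2H_"
  comp <- composites[composites$isotope == isotope, , drop = FALSE]
  bulk <- comp$value[match(rownames(fm$features), comp$sample_id)]
  rs <- vapply(fm$panel, function(fa) {
    col <- paste0(prefix, fa)
    if (!col %in% colnames(fm$features)) return(c(r = NA_real_, n = 0))
    y <- fm$features[, col]
    ok <- !is.na(y) & !is.na(bulk)
    if (sum(ok) < 3L) return(c(r = NA_real_, n = sum(ok)))
    c(r = stats::cor(y[ok], bulk[ok]), n = sum(ok))
  }, numeric(2))
  per_fa <- data.frame(fa = fm$panel, r = rs["r", ], n = as.integer(rs["n", ]),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(per_fa = per_fa,
       summary = c(mean_r = mean(per_fa$r, na.rm = TRUE),
                   sd_r = stats::sd(per_fa$r, na.rm = TRUE)))
}
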