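# Samples x (fatty acid, isotope) feature table used by all statistics.

#' Build the samples x (fatty acid, isotope) feature matrix
#'
#' Pivots calibrated peak records into one row per sample and one column per
#' (fatty acid, isotope) pair. Column order is deterministic: the full
#' delta-13C block in panel order, then the delta-2H block, named
#' `d13C_<fa>` / `d2H_<fa>`. Rows follow the metadata order restricted to
#' samples present in the records.
#'
#' @param records Calibrated peak records (non-NA `delta_cal`).
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param panel Character vector of fatty-acid codes; defaults to the 11-FA
#'   core panel (22 features).
#' @param require_complete Drop rows missing any panel feature (complete-case
#'   policy; the dropped sample ids are reported in the `dropped` attribute
#'   and via a message).
#' @return An object of class `feature_matrix`: a list with `features`
#'   (numeric matrix, rownames = sample ids), `meta` (row-aligned metadata),
#'   `panel`, and `dropped` (character vector of dropped sample ids).
#' @export
build_feature_matrix <- function(records, meta, panel = core_panel(),
                                 require_complete = TRUE) {
  if (all(is.na(records$delta_cal))) {
    stop("Records are not calibrated (delta_cal all NA); run the calibration ",
         "stage first", call. = FALSE)
  }
  records <- records[records$fa %in% panel, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop("No peaks match the requested panel (",
         paste(panel, collapse = ", "), ")", call. = FALSE)
  }
  cols <- c(paste0("d13C_", panel), paste0("d2H_", panel))
  iso_prefix <- c("13C" = "d13C_", "2H" = "d2H_")
  samples <- meta$sample_id[meta$sample_id %in% unique(records$sample_id)]
  mat <- matrix(NA_real_, nrow = length(samples), ncol = length(cols),
                dimnames = list(as.character(samples), cols))
  colkey <- paste0(iso_prefix[records$isotope], records$fa)
  keep <- records$sample_id %in% samples
  mat[cbind(as.character(records$sample_id[keep]), colkey[keep])] <-
    records$delta_cal[keep]
  dropped <- character()
  if (require_complete) {
    complete <- stats::complete.cases(mat)
    dropped <- rownames(mat)[!complete]
    if (length(dropped) > 0L) {
      message(length(dropped), " sample(s) dropped for incomplete panel: ",
              paste(utils::head(dropped, 10L), collapse = ", "))
    }
    mat <- mat[complete, , drop = FALSE]
  }
  meta_aligned <- meta[match(rownames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta_aligned) <- NULL
  structure(list(features = mat, meta = meta_aligned, panel = panel,
                 dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%d-FA panel)\n",
              nrow(x$features), ncol(x$features), length(x$panel)))
  if (length(x$dropped) > 0L) {
    cat(sprintf("  %d sample(s) dropped as incomplete\n", length(x$dropped)))
  }
  invisible(x)
}

#' Extract one isotope block from a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param isotope `"13C"` or `"2H"`.
#' @return Numeric matrix of that isotope's features, panel order preserved.
#' @export
isotope_block <- function(fm, isotope = c("13C", "2H")) {
  isotope <- match.arg(isotope)
  prefix <- if (isotope == "13C") "d13C_" else "d2H_"
  fm$features[, startsWith(colnames(fm$features), prefix), drop = FALSE]
}

#' Subset a feature matrix by a metadata predicate
#'
#' @param fm A `feature_matrix`.
#' @param keep Logical vector over rows (aligned with `fm$meta`).
#' @return The subset `feature_matrix`.
#' @export
subset_features <- function(fm, keep) {
  stopifnot(length(keep) == nrow(fm$features))
  structure(list(features = fm$features[keep, , drop = FALSE],
                 meta = fm$meta[keep, , drop = FALSE],
                 panel = fm$panel, dropped = fm$dropped),
            class = "feature_matrix")
}
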