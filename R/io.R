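# Delimited-text readers/writers for peak tables, sample metadata and sites.
# Dialect: comma- or tab-delimited, auto-detected from the header line;
# decimal point only.

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("Empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

.read_delim <- function(path) {
  sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.allowed_isotopes <- c("13C", "2H")

#' Read a GC-IRMS peak table
#'
#' Expects one row per identified FAME peak with at least the columns
#' `sample_id`, `fa`, `isotope` (one of `"13C"`, `"2H"`), `delta` (raw per-mil
#' value on the instrument scale) and `mass_fraction`. Extra columns are
#' preserved unchanged. A `delta_cal` column (NA until calibrated) is added;
#' if the file already carries one it is kept.
#'
#' @param path Path to a comma- or tab-delimited text file (auto-detected).
#' @return A `data.frame` of peak records with columns `sample_id`, `fa`,
#'   `isotope`, `delta_raw`, `delta_cal`, `mass_fraction`, plus any extras.
#' @export
read_peak_table <- function(path) {
  df <- .read_delim(path)
  .require_columns(df, c("sample_id", "fa", "isotope", "delta", "mass_fraction"),
                   "Peak table")
  names(df)[names(df) == "delta"] <- "delta_raw"
  validate_peaks(df)
}

#' Validate a peak-record data frame
#'
#' Checks isotope labels, numeric deltas, nonnegative mass fractions and
#' uniqueness of (sample_id, fa, isotope) keys.
#'
#' @param df Data frame of peak records with a `delta_raw` column.
#' @return The validated data frame (invisible changes: `delta_cal` ensured).
#' @export
validate_peaks <- function(df) {
  bad_iso <- setdiff(unique(df$isotope), .allowed_isotopes)
  if (length(bad_iso) > 0L) {
    stop("Unknown isotope label(s) ", paste(sQuote(bad_iso), collapse = ", "),
         "; allowed isotopes are ", paste(.allowed_isotopes, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$delta_raw) || anyNA(suppressWarnings(as.numeric(df$delta_raw)))) {
    stop("Non-numeric or missing delta values in peak table", call. = FALSE)
  }
  if (!is.numeric(df$mass_fraction) || any(is.na(df$mass_fraction)) ||
      any(df$mass_fraction < 0)) {
    stop("mass_fraction must be numeric and >= 0 for every peak", call. = FALSE)
  }
  key <- paste(df$sample_id, df$fa, df$isotope, sep = " / ")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    stop("Duplicate (sample_id, fa, isotope) peak(s): ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }
  if (!"delta_cal" %in% names(df)) df$delta_cal <- NA_real_
  df
}

#' Read a sample metadata table
#'
#' One row per analytical sample (a fish x tissue unit) with columns
#' `sample_id`, `fish_id`, `taxon`, `tissue`, `site_id`, `year`. Each
#' (fish_id, tissue) pair may appear at most once (up to four tissues per
#' fish).
#'
#' @param path Path to a delimited text file.
#' @return A validated `data.frame`.
#' @export
read_sample_meta <- function(path) {
  df <- .read_delim(path)
  .require_columns(df, c("sample_id", "fish_id", "taxon", "tissue",
                         "site_id", "year"), "Sample metadata")
  validate_meta(df)
}

#' @rdname read_sample_meta
#' @param df Data frame of sample metadata.
#' @export
validate_meta <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("Duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$fish_id, df$tissue)
  if (anyDuplicated(key)) {
    stop("A (fish_id, tissue) pair appears more than once: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  n_tis <- table(df$fish_id)
  if (any(n_tis > 4L)) {
    stop("Fish with more than 4 tissues: ",
         paste(names(n_tis)[n_tis > 4L], collapse = ", "), call. = FALSE)
  }
  df$year <- as.integer(df$year)
  df
}

#' Read a site table
#'
#' Columns: `site_id`, `altitude` (m a.s.l.), and either coordinate columns
#' `x_km`/`y_km` (planar kilometres, used for Euclidean distances) or nothing
#' (then a distance matrix must be supplied separately). An optional
#' `pool_label` column carries a pooled-group identifier.
#'
#' @param path Path to a delimited text file.
#' @return A validated `data.frame` of sites.
#' @export
read_site_table <- function(path) {
  df <- .read_delim(path)
  .require_columns(df, c("site_id", "altitude"), "Site table")
  if (anyDuplicated(df$site_id)) stop("Duplicate site_id", call. = FALSE)
  df
}

#' Pairwise between-site distances in kilometres
#'
#' Either derived from planar coordinates in the site table (`x_km`, `y_km`)
#' or supplied directly as a labelled square matrix (stream distances are
#' allowed, so the triangle inequality is not enforced; symmetry and a zero
#' diagonal are).
#'
#' @param sites Site data frame from [read_site_table()].
#' @param distances Optional square numeric matrix with site ids as dimnames.
#' @return Symmetric site x site distance matrix (km).
#' @export
site_distance_matrix <- function(sites, distances = NULL) {
  ids <- as.character(sites$site_id)
  if (!is.null(distances)) {
    distances <- as.matrix(distances)
    if (is.null(rownames(distances)) || is.null(colnames(distances))) {
      stop("Distance matrix must carry site ids as dimnames", call. = FALSE)
    }
    missing <- setdiff(ids, rownames(distances))
    if (length(missing) > 0L) {
      stop("Distance matrix lacks site(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    d <- distances[ids, ids, drop = FALSE]
    if (any(abs(d - t(d)) > 1e-8)) stop("Distance matrix is not symmetric",
                                        call. = FALSE)
    if (any(abs(diag(d)) > 1e-8)) stop("Distance matrix diagonal must be zero",
                                       call. = FALSE)
    return(d)
  }
  .require_columns(sites, c("x_km", "y_km"), "Site table (for distances)")
  d <- as.matrix(stats::dist(sites[, c("x_km", "y_km")]))
  dimnames(d) <- list(ids, ids)
  d
}

#' Write a result table as CSV
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param row_names Write row names (used for labelled matrices such as
#'   confusion matrices).
#' @export
write_result_table <- function(df, path, row_names = FALSE) {
  utils::write.csv(df, path, row.names = row_names)
  invisible(path)
}

#' Validate a full input bundle
#'
#' Cross-checks peaks against metadata and metadata against the site table,
#' returning a validation report. Used by the `validate` pipeline stage.
#'
#' @param peaks Peak records data frame.
#' @param meta Sample metadata data frame.
#' @param sites Site table data frame.
#' @return A list with `ok` flag and character vectors `errors`, `warnings`,
#'   plus row counts.
#' @export
validate_inputs <- function(peaks, meta, sites) {
  errors <- character()
  warnings <- character()
  orphan <- setdiff(unique(peaks$sample_id), meta$sample_id)
  if (length(orphan) > 0L) {
    errors <- c(errors, paste0("Peaks reference sample_id(s) absent from metadata: ",
                               paste(utils::head(orphan, 5L), collapse = ", ")))
  }
  no_peaks <- setdiff(meta$sample_id, unique(peaks$sample_id))
  if (length(no_peaks) > 0L) {
    warnings <- c(warnings, paste0(length(no_peaks), " sample(s) have no peaks"))
  }
  bad_site <- setdiff(unique(meta$site_id), sites$site_id)
  if (length(bad_site) > 0L) {
    errors <- c(errors, paste0("Metadata references unknown site(s): ",
                               paste(bad_site, collapse = ", ")))
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings,
       n_peaks = nrow(peaks), n_samples = nrow(meta), n_sites = nrow(sites))
}
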