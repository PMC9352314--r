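# Published reference values from the original sub-alpine field study
# (Ybbs catchment; 15 sites, 3 fish taxa, 4 tissues, 2 sampling years),
# shipped as plain CSV for worked examples: per-FA correlations with the
# bulk composite, the site-repeatability matrix, and the 9-site cross-year
# confusion matrix of bullhead assignments.

#' Published reference tables for worked examples
#'
#' Small tables of published summary values from the field study this
#' pipeline was designed around, used in worked examples and consistency
#' checks:
#' * `"bulk_correlations"` — per-FA Pearson correlation of compound-specific
#'   deltas with the bulk composite, both isotopes.
#' * `"site_repeatability"` — site-specific repeatability (R, with SE) per
#'   fatty acid, isotope and tissue.
#' * `"cross_year_confusion"` — the 9-site confusion matrix of second-year
#'   bullhead samples predicted by the first-year-trained classifier
#'   (returned as a numeric matrix, rows = true sites).
#'
#' @param name One of the table names above.
#' @return A data frame, or a numeric matrix for the confusion table.
#' @export
reference_table <- function(name = c("bulk_correlations", "site_repeatability",
                                     "cross_year_confusion")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "isocompass", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (name == "cross_year_confusion") {
    m <- as.matrix(df[, -1])
    rownames(m) <- df$true
    return(m)
  }
  df
}
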