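# One reproducible run: validate -> calibrate -> composites -> features ->
# repeatability -> multivariate -> assignment, with a YAML config and a
# run manifest.

#' Build or load a pipeline run configuration
#'
#' Either pass the fields directly or a path to a YAML file with the same
#' structure. Every stochastic stage must carry an explicit seed; the
#' configuration round-trips through [save_run_config()] / YAML.
#'
#' @param peaks,meta,sites,standards Paths to the input tables.
#' @param methanol_d13C,methanol_d2H Methanol reference deltas (required for
#'   methylation correction; no defaults).
#' @param panel Fatty-acid panel (default: the 11-FA core panel).
#' @param tissue Tissue analysed per run; per-tissue analysis is the default
#'   unit because isotope discrimination between tissues is too large to
#'   pool. `"all"` pools tissues explicitly.
#' @param pooling_map Optional named site-pooling map.
#' @param tolerance_km Distance tolerance for cross-year scoring.
#' @param n_boot_cv,n_boot_repeatability Bootstrap replicate counts.
#' @param seed Integer seed applied to every stochastic stage.
#' @param out_dir Output directory for the run.
#' @return A `run_config` list.
#' @export
run_config <- function(peaks, meta, sites, standards,
                       methanol_d13C, methanol_d2H,
                       panel = core_panel(), tissue = "muscle",
                       pooling_map = NULL, tolerance_km = 1.0,
                       n_boot_cv = 999L, n_boot_repeatability = 1000L,
                       seed, out_dir = "isocompass_run") {
  if (missing(seed)) stop("An explicit seed is required", call. = FALSE)
  structure(list(peaks = peaks, meta = meta, sites = sites,
                 standards = standards,
                 methanol_d13C = methanol_d13C, methanol_d2H = methanol_d2H,
                 panel = panel, tissue = tissue, pooling_map = pooling_map,
                 tolerance_km = tolerance_km, n_boot_cv = n_boot_cv,
                 n_boot_repeatability = n_boot_repeatability,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$pooling_map <- if (length(x$pooling_map) > 0L) unlist(x$pooling_map) else NULL
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Execute the full pipeline
#'
#' Runs validation, per-isotope calibration (scale normalization from the
#' standards table, then methylation correction), composites, the feature
#' matrix, per-variable site repeatability, canonical correlation between
#' the isotope blocks, and discriminant site assignment with bootstrap
#' cross-validation; when two years are present it also scores the frozen
#' first-year classifier on the second year. All stage outputs are written
#' as CSV into `config$out_dir` together with a JSON manifest (config hash,
#' package version, seeds, row counts, warnings). Any stage failure aborts
#' with the stage name.
#'
#' @param config A [run_config()] or path to its YAML file.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) message("[isocompass] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  note("stage: validate")
  peaks <- stage("validate", read_peak_table(config$peaks))
  meta <- stage("validate", read_sample_meta(config$meta))
  sites <- stage("validate", read_site_table(config$sites))
  report <- validate_inputs(peaks, meta, sites)
  if (!report$ok) {
    stop("Pipeline stage 'validate' failed:\n  ",
         paste(report$errors, collapse = "\n  "), call. = FALSE)
  }
  warnings_log <- c(warnings_log, report$warnings)
  if (!is.na(config$tolerance_km) &&
      !all(c("x_km", "y_km") %in% names(sites))) {
    stop("Pipeline stage 'validate' failed: tolerance scoring requested but ",
         "the site table has no coordinates for distances", call. = FALSE)
  }

  note("stage: calibrate")
  std <- stage("calibrate", .read_delim(config$standards))
  models <- list()
  for (iso in intersect(.allowed_isotopes, unique(peaks$isotope))) {
    models[[iso]] <- stage("calibrate",
      fit_normalization(std[std$isotope == iso, , drop = FALSE], iso))
  }
  calibrated <- stage("calibrate",
    calibrate_peaks(peaks, models[["13C"]], models[["2H"]]))
  calibrated <- stage("calibrate",
    methylation_correct(calibrated,
                        methanol_reference(config$methanol_d13C,
                                           config$methanol_d2H)))
  write_result_table(calibrated, file.path(out_dir, "calibrated.csv"))

  note("stage: composites")
  comp <- stage("composites", bulk_delta(calibrated))
  write_result_table(comp, file.path(out_dir, "composites.csv"))

  note("stage: features")
  use_meta <- if (identical(config$tissue, "all")) meta else
    meta[meta$tissue == config$tissue, , drop = FALSE]
  fm <- stage("features",
    build_feature_matrix(calibrated, use_meta, panel = config$panel))
  if (!is.null(config$pooling_map)) {
    fm$meta$site_id <- stage("features",
      pool_sites(fm$meta$site_id, config$pooling_map))
  }
  lin_ala <- if (all(c("LIN", "ALA") %in% config$panel)) {
    pair_difference(fm, "2H", "LIN", "ALA")
  } else NULL

  note("stage: repeatability")
  rep_tab <- stage("repeatability",
    repeatability_table(fm, by_tissue = FALSE,
                        n_boot = 0L))
  write_result_table(rep_tab, file.path(out_dir, "repeatability.csv"))

  note("stage: multivariate")
  cca <- stage("multivariate",
    canonical_correlation(isotope_block(fm, "13C"), isotope_block(fm, "2H")))
  dimtests <- tryCatch(wilks_lambda_test(cca), error = function(e) {
    warnings_log <<- c(warnings_log,
                       paste("dimension tests skipped:", conditionMessage(e)))
    data.frame(dim = integer(), lambda = numeric(), F = numeric(),
               df1 = numeric(), df2 = numeric(), p = numeric())
  })
  write_result_table(dimtests, file.path(out_dir, "cca_dimension_tests.csv"))
  write_result_table(data.frame(dim = seq_along(cca$cor), cor = cca$cor),
                     file.path(out_dir, "cca_correlations.csv"))

  note("stage: assignment")
  years <- sort(unique(fm$meta$year))
  fm_train <- if (length(years) > 1L) subset_features(fm, fm$meta$year == years[1]) else fm
  model <- stage("assignment", fit_lda(fm_train$features, fm_train$meta$site_id))
  cv <- stage("assignment",
    bootstrap_cv_accuracy(fm_train$features, fm_train$meta$site_id,
                          n_boot = config$n_boot_cv, seed = config$seed))
  scores <- lda_scores(model, fm_train$features, fm_train$meta$site_id)
  write_result_table(scores, file.path(out_dir, "lda_scores.csv"))
  accuracy <- list(cv_accuracy = cv$cv_accuracy,
                   resubstitution_accuracy = cv$resubstitution_accuracy)
  cross_year <- NULL
  if (length(years) > 1L) {
    fm_test <- subset_features(fm, fm$meta$year == years[2])
    sd_mat <- site_distance_matrix(sites)
    cross_year <- stage("assignment",
      cross_year_predict(fm_train$features, fm_train$meta$site_id,
                         fm_test$features, fm_test$meta$site_id,
                         site_dist = sd_mat,
                         tolerance_km = config$tolerance_km))
    write_result_table(as.data.frame.matrix(cross_year$confusion),
                       file.path(out_dir, "confusion.csv"), row_names = TRUE)
    write_result_table(cross_year$assignments,
                       file.path(out_dir, "assignments.csv"))
    accuracy$cross_year_exact <- cross_year$exact_accuracy
    accuracy$cross_year_tolerant <- cross_year$tolerant_accuracy
  }
  jsonlite::write_json(accuracy, file.path(out_dir, "accuracy.json"),
                       auto_unbox = TRUE, digits = NA)

  note("stage: manifest")
  cfg_path <- file.path(out_dir, "config.yaml")
  save_run_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("isocompass")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_peaks = nrow(peaks), n_samples = nrow(use_meta),
    n_features = ncol(fm$features), n_sites = length(unique(fm$meta$site_id)),
    dropped_samples = fm$dropped,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(calibrated = calibrated, composites = comp, features = fm,
                 lin_ala_diff = lin_ala, repeatability = rep_tab, cca = cca,
                 dimension_tests = dimtests, model = model, cv = cv,
                 cross_year = cross_year, manifest = manifest))
}
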