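# Site assignment: LDA/CVA fitting, bootstrap out-of-bag cross-validation,
# Mahalanobis site pooling, multi-tissue consensus, cross-year transfer with
# distance-tolerant scoring.

#' Fit a linear discriminant (canonical variate) model for site assignment
#'
#' Class centroids, pooled within-class covariance, and canonical axes (the
#' eigenvectors of `pooled_cov^{-1} B` with proportion of trace per axis).
#' When the pooled covariance is near-singular (condition number above
#' `cond_tol`), a ridge `eps * I` with `eps = ridge * tr(S)/p` is added and
#' a message is emitted; the same happens, with a warning, when `p >= n`.
#'
#' @param x Numeric feature matrix (complete cases).
#' @param labels Class labels (site ids), length `nrow(x)`.
#' @param ridge Relative ridge coefficient (default `1e-6`).
#' @param priors `"equal"` (default: sites are compared, not prevalences) or
#'   `"empirical"`.
#' @param cond_tol Condition-number threshold triggering regularization.
#' @return An object of class `iso_lda`: `classes`, `centroids` (class x
#'   feature grand means), `pooled_cov`, `priors`, `axes` (feature x axis
#'   discriminant basis), `prop_trace`, `n_per_class`, `ridge_applied`.
#' @export
fit_lda <- function(x, labels, ridge = 1e-6, priors = c("equal", "empirical"),
                    cond_tol = 1e8) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (anyNA(x)) stop("fit_lda requires complete cases", call. = FALSE)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("Need >= 2 classes", call. = FALSE)
  ncls <- table(factor(labels, levels = cls))
  if (any(ncls < 2L)) {
    stop("Class(es) with fewer than 2 samples: ",
         paste(names(ncls)[ncls < 2L], collapse = ", "), call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x); k <- length(cls)
  centroids <- matrix(NA_real_, k, p, dimnames = list(cls, colnames(x)))
  for (cl in cls) centroids[cl, ] <- colMeans(x[labels == cl, , drop = FALSE])
  Sw <- matrix(0, p, p)
  for (cl in cls) {
    xc <- scale(x[labels == cl, , drop = FALSE], center = centroids[cl, ],
                scale = FALSE)
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (n - k)
  ridge_applied <- 0
  force_ridge <- p >= n
  if (force_ridge) {
    warning("p (", p, ") >= n (", n, "): forcing ridge regularization")
  }
  kap <- tryCatch(kappa(Sw, exact = TRUE), error = function(e) Inf)
  if (force_ridge || !is.finite(kap) || kap > cond_tol) {
    ridge_applied <- ridge * sum(diag(Sw)) / p
    Sw <- Sw + diag(ridge_applied, p)
    message("Pooled covariance regularized: ridge = ", signif(ridge_applied, 3))
  }
  # Canonical axes: eigenvectors of Sw^{-1/2} B Sw^{-1/2}, mapped back.
  grand <- colMeans(centroids[rep(cls, ncls), , drop = FALSE])
  B <- matrix(0, p, p)
  for (cl in cls) {
    d <- centroids[cl, ] - grand
    B <- B + ncls[[cl]] * tcrossprod(d)
  }
  B <- B / (k - 1)
  wh <- .sym_inv_sqrt(Sw)
  M <- wh$half %*% B %*% wh$half
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  naxes <- min(p, k - 1L)
  vals <- pmax(e$values[seq_len(naxes)], 0)
  axes <- wh$half %*% e$vectors[, seq_len(naxes), drop = FALSE]
  rownames(axes) <- colnames(x)
  colnames(axes) <- paste0("LD", seq_len(naxes))
  total <- sum(pmax(e$values, 0))
  prop_trace <- if (total > 0) vals / total else rep(0, naxes)
  names(prop_trace) <- colnames(axes)
  pri <- if (priors == "equal") stats::setNames(rep(1 / k, k), cls) else
    stats::setNames(as.numeric(ncls) / n, cls)
  structure(list(classes = cls, centroids = centroids, pooled_cov = Sw,
                 priors = pri, axes = axes, prop_trace = prop_trace,
                 eigenvalues = vals,
                 n_per_class = as.integer(ncls), ridge_applied = ridge_applied),
            class = "iso_lda")
}

#' @export
print.iso_lda <- function(x, ...) {
  cat(sprintf("<iso_lda> %d classes, %d features, %d canonical axes\n",
              length(x$classes), ncol(x$centroids), ncol(x$axes)))
  cat("  proportion of trace:",
      paste(sprintf("%.1f%%", 100 * x$prop_trace[seq_len(min(3, length(x$prop_trace)))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Predict site assignments from a fitted discriminant model
#'
#' Assigns each sample to the class with the maximal Gaussian discriminant
#' score `-0.5 * Mahalanobis^2(x, centroid) + log(prior)`; with equal priors
#' this is the nearest-Mahalanobis-centroid rule. Posteriors are the softmax
#' of the scores. Exact score ties are broken lexicographically by class
#' label and flagged.
#'
#' @param object A fitted `iso_lda`.
#' @param newdata Feature matrix with the model's feature columns.
#' @param true_labels Optional true site labels; enables the `correct` flag.
#' @param ... Unused.
#' @return Data frame of class `assignment_result`: `sample_id`, `predicted`,
#'   `max_posterior`, `tie`, and (if supplied) `true_site`, `correct`; the
#'   full posterior matrix is in attribute `"posterior"`.
#' @export
predict.iso_lda <- function(object, newdata, true_labels = NULL, ...) {
  x <- as.matrix(newdata)
  Sinv <- solve(object$pooled_cov)
  scores <- vapply(object$classes, function(cl) {
    -0.5 * stats::mahalanobis(x, object$centroids[cl, ], Sinv, inverted = TRUE) +
      log(object$priors[[cl]])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(rownames(x), object$classes))
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  pred <- character(nrow(x))
  tie <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    top <- max(scores[i, ])
    winners <- object$classes[scores[i, ] >= top - 1e-12]
    tie[i] <- length(winners) > 1L
    pred[i] <- winners[1L]  # classes are sorted, so ties resolve lexicographically
  }
  out <- data.frame(
    sample_id = if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x))),
    predicted = pred,
    max_posterior = apply(post, 1, max),
    tie = tie,
    stringsAsFactors = FALSE)
  if (!is.null(true_labels)) {
    out$true_site <- as.character(true_labels)
    out$correct <- out$predicted == out$true_site
  }
  attr(out, "posterior") <- post
  class(out) <- c("assignment_result", "data.frame")
  out
}

#' Canonical-variate scores for plotting
#'
#' Projects samples onto the discriminant axes (LD1, LD2, LD3, ...), for
#' export as a flat table alongside the site label.
#'
#' @param model A fitted `iso_lda`.
#' @param x Feature matrix.
#' @param labels Optional site labels appended as a column.
#' @return Data frame of scores (one column per axis, plus `site`).
#' @export
lda_scores <- function(model, x, labels = NULL) {
  sc <- as.matrix(x) %*% model$axes
  out <- as.data.frame(sc)
  if (!is.null(labels)) out$site <- as.character(labels)
  out
}

#' Bootstrap out-of-bag cross-validated classification accuracy
#'
#' Each replicate resamples the training rows with replacement within class,
#' fits the discriminant model on the resample, and evaluates on the
#' out-of-bag rows. Accuracy is aggregated over all out-of-bag predictions;
#' a percentile interval over per-replicate accuracies and plain
#' resubstitution accuracy are also reported.
#'
#' @param x Feature matrix.
#' @param labels Class labels.
#' @param n_boot Number of bootstrap replicates (999 by convention).
#' @param seed Integer seed (mandatory).
#' @param ... Passed to [fit_lda()].
#' @return List with `cv_accuracy`, `ci`, `resubstitution_accuracy`,
#'   `per_class` (data frame), `n_boot`, `boot_accuracy`.
#' @export
bootstrap_cv_accuracy <- function(x, labels, n_boot = 999L, seed, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  idx_by_class <- split(seq_along(labels), labels)
  full <- fit_lda(x, labels, ...)
  resub <- mean(predict(full, x, true_labels = labels)$correct)
  set.seed(seed)
  correct_tot <- 0; oob_tot <- 0
  class_correct <- stats::setNames(numeric(length(cls)), cls)
  class_total <- stats::setNames(numeric(length(cls)), cls)
  empty_oob <- stats::setNames(numeric(length(cls)), cls)
  boot_acc <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    train <- unlist(lapply(idx_by_class, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
    oob <- setdiff(seq_along(labels), unique(train))
    for (cl in cls) {
      if (!any(labels[oob] == cl)) empty_oob[cl] <- empty_oob[cl] + 1
    }
    if (length(oob) == 0L) next
    fitb <- tryCatch(
      suppressMessages(suppressWarnings(
        fit_lda(x[train, , drop = FALSE], labels[train], ...))),
      error = function(e) NULL)
    if (is.null(fitb)) next
    pr <- predict(fitb, x[oob, , drop = FALSE], true_labels = labels[oob])
    correct_tot <- correct_tot + sum(pr$correct)
    oob_tot <- oob_tot + nrow(pr)
    boot_acc[b] <- mean(pr$correct)
    hits <- tapply(pr$correct, pr$true_site, sum)
    tots <- table(pr$true_site)
    class_correct[names(hits)] <- class_correct[names(hits)] + hits
    class_total[names(tots)] <- class_total[names(tots)] + as.numeric(tots)
  }
  if (any(empty_oob > n_boot / 2)) {
    warning("Class(es) with empty out-of-bag set in > 50% of replicates: ",
            paste(cls[empty_oob > n_boot / 2], collapse = ", "))
  }
  list(cv_accuracy = correct_tot / oob_tot,
       ci = unname(stats::quantile(boot_acc, c(0.025, 0.975), na.rm = TRUE)),
       resubstitution_accuracy = resub,
       per_class = data.frame(class = cls,
                              cv_accuracy = unname(class_correct / class_total),
                              stringsAsFactors = FALSE),
       n_boot = n_boot,
       boot_accuracy = boot_acc)
}

#' Leave-one-out cross-validated classification accuracy
#'
#' Deterministic alternative to the bootstrap out-of-bag estimator: each
#' sample is predicted by a model fitted on all remaining samples. Less
#' pessimistic than out-of-bag resampling when classes are small.
#'
#' @param x Feature matrix.
#' @param labels Class labels.
#' @param ... Passed to [fit_lda()].
#' @return List with `cv_accuracy` and the per-sample `correct` flags.
#' @export
loo_cv_accuracy <- function(x, labels, ...) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  correct <- vapply(seq_len(nrow(x)), function(i) {
    f <- tryCatch(
      suppressMessages(suppressWarnings(
        fit_lda(x[-i, , drop = FALSE], labels[-i], ...))),
      error = function(e) NULL)
    if (is.null(f)) return(NA)
    predict(f, x[i, , drop = FALSE])$predicted == labels[i]
  }, logical(1))
  list(cv_accuracy = mean(correct, na.rm = TRUE), correct = correct)
}

#' Pairwise Mahalanobis distance between class centroids
#'
#' Distance between site centroids under the pooled within-class covariance;
#' small distances flag candidate sites for pooling.
#'
#' @param model A fitted `iso_lda`.
#' @return Symmetric site x site distance matrix.
#' @export
mahalanobis_site_distance <- function(model) {
  cls <- model$classes
  Sinv <- solve(model$pooled_cov)
  k <- length(cls)
  d <- matrix(0, k, k, dimnames = list(cls, cls))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      diff <- model$centroids[i, ] - model$centroids[j, ]
      d[i, j] <- d[j, i] <- sqrt(drop(t(diff) %*% Sinv %*% diff))
    }
  }
  d
}

#' Suggest site pools from Mahalanobis and geographic proximity
#'
#' Proposes merging site pairs whose centroid Mahalanobis distance and
#' geographic distance both fall below thresholds. The suggestion is never
#' applied automatically; pass the returned map (possibly edited) to
#' [pool_sites()].
#'
#' @param model A fitted `iso_lda`.
#' @param geo_dist Site x site geographic distance matrix (km).
#' @param mahal_max Mahalanobis threshold.
#' @param km_max Geographic threshold (km).
#' @return Named character map `site -> pooled label` (single-linkage groups).
#' @export
suggest_site_pools <- function(model, geo_dist, mahal_max, km_max = 1) {
  md <- mahalanobis_site_distance(model)
  cls <- model$classes
  gd <- geo_dist[cls, cls]
  adj <- (md <= mahal_max) & (gd <= km_max)
  diag(adj) <- TRUE
  # single-linkage connected components
  comp <- seq_along(cls)
  repeat {
    changed <- FALSE
    for (i in seq_along(cls)) for (j in seq_along(cls)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  map <- vapply(seq_along(cls), function(i) {
    members <- cls[comp == comp[i]]
    if (length(members) == 1L) cls[i] else paste(members, collapse = "+")
  }, character(1))
  stats::setNames(map, cls)
}

#' Relabel sites according to a pooling map
#'
#' @param labels Site labels.
#' @param pooling_map Named character vector `site -> pooled label`; sites
#'   absent from the map keep their label. Unknown sites in the map are an
#'   error.
#' @return Relabelled character vector.
#' @export
pool_sites <- function(labels, pooling_map) {
  labels <- as.character(labels)
  unknown <- setdiff(names(pooling_map), unique(labels))
  if (length(unknown) > 0L) {
    stop("Pooling map references unknown site(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mapped <- unname(pooling_map[labels])
  mapped[is.na(mapped)] <- labels[is.na(mapped)]
  mapped
}

#' Multi-tissue consensus site assignment per fish
#'
#' A fish is scored site-specific when at least three of its (up to four)
#' available tissues were assigned to the correct site; with fewer than
#' three tissues available, all must be correct.
#'
#' @param assignments An `assignment_result` (or data frame) with columns
#'   `sample_id` and `correct`.
#' @param meta Sample metadata mapping `sample_id` to `fish_id`.
#' @return Data frame of class `consensus_result`: `fish_id`, `n_tissues`,
#'   `n_correct`, `site_specific`.
#' @export
consensus_assign <- function(assignments, meta) {
  if (nrow(assignments) == 0L) stop("No assignments supplied", call. = FALSE)
  if (!"correct" %in% names(assignments)) {
    stop("Assignments lack a 'correct' flag (predict with true_labels)",
         call. = FALSE)
  }
  fish <- meta$fish_id[match(assignments$sample_id, meta$sample_id)]
  if (anyNA(fish)) {
    stop("Assignment sample_id(s) missing from metadata: ",
         paste(utils::head(assignments$sample_id[is.na(fish)], 5), collapse = ", "),
         call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(assignments$correct, fish), function(v) {
    data.frame(n_tissues = length(v), n_correct = sum(v))
  }))
  out <- data.frame(fish_id = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$site_specific <- ifelse(out$n_tissues >= 3L,
                              out$n_correct >= 3L,
                              out$n_correct == out$n_tissues)
  class(out) <- c("consensus_result", "data.frame")
  out
}

#' Exact-site accuracy from a labelled confusion matrix
#'
#' `trace / total`: the fraction of samples on the diagonal. Row names are
#' true sites, column names predicted sites; rows and columns are aligned by
#' name before the trace is taken.
#'
#' @param confusion Square numeric matrix with matching dimnames.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  common <- intersect(rownames(confusion), colnames(confusion))
  sum(diag(confusion[common, common])) / sum(confusion)
}

#' Train on one year, predict another, with distance-tolerant scoring
#'
#' Freezes the year-A classifier (class centroids + pooled covariance; no
#' test-year refitting) and predicts the year-B samples. Exact accuracy is
#' the confusion-matrix trace over total; tolerant accuracy additionally
#' credits predictions whose site lies within `tolerance_km` of the true
#' site according to the supplied site distance matrix.
#'
#' @param train_x,train_labels Year-A features and site labels.
#' @param test_x,test_labels Year-B features and site labels.
#' @param site_dist Optional site x site distance matrix (km); required for
#'   tolerant accuracy.
#' @param tolerance_km Distance tolerance (default 1 km).
#' @param ... Passed to [fit_lda()].
#' @return List with `model`, `assignments`, `confusion`, `exact_accuracy`,
#'   `tolerant_accuracy` (NA without `site_dist`).
#' @export
cross_year_predict <- function(train_x, train_labels, test_x, test_labels,
                               site_dist = NULL, tolerance_km = 1.0, ...) {
  model <- fit_lda(train_x, train_labels, ...)
  pr <- predict(model, test_x, true_labels = test_labels)
  sites <- sort(union(unique(pr$true_site), model$classes))
  confusion <- table(factor(pr$true_site, levels = sites),
                     factor(pr$predicted, levels = sites))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("true", "predicted")
  exact <- accuracy_from_confusion(confusion)
  tolerant <- NA_real_
  if (!is.null(site_dist)) {
    missing <- setdiff(sites, rownames(site_dist))
    if (length(missing) > 0L) {
      stop("Site distance matrix lacks: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    within <- pr$correct |
      site_dist[cbind(pr$true_site, pr$predicted)] <= tolerance_km
    pr$within_tolerance <- within
    tolerant <- mean(within)
  }
  list(model = model, assignments = pr, confusion = confusion,
       exact_accuracy = exact, tolerant_accuracy = tolerant)
}

#' Per-site, per-tissue year shift in one variable (Welch t-test)
#'
#' Mean change between two sampling years for each (site, tissue) cell with
#' a two-sample Welch t-test; cells with one year absent are reported as NA
#' rows rather than errors.
#'
#' @param fm A `feature_matrix` spanning both years.
#' @param variable Feature column name.
#' @param years Length-2 integer vector, earlier year first.
#' @param alpha Significance threshold for the flag (default 0.05).
#' @return Data frame `site_id`, `tissue`, `delta` (later minus earlier
#'   mean), `p`, `significant`, `n_early`, `n_late`.
#' @export
year_shift_test <- function(fm, variable, years = NULL, alpha = 0.05) {
  if (!variable %in% colnames(fm$features)) {
    stop("Variable ", variable, " not in feature matrix", call. = FALSE)
  }
  meta <- fm$meta
  y <- fm$features[, variable]
  if (is.null(years)) years <- sort(unique(meta$year))
  if (length(years) != 2L) stop("Exactly two years required", call. = FALSE)
  cells <- unique(meta[, c("site_id", "tissue")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- meta$site_id == cells$site_id[i] & meta$tissue == cells$tissue[i]
    a <- y[sel & meta$year == years[1]]
    b <- y[sel & meta$year == years[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(site_id = cells$site_id[i], tissue = cells$tissue[i],
                        delta = NA_real_, p = NA_real_, significant = NA,
                        n_early = length(a), n_late = length(b)))
    }
    tt <- stats::t.test(b, a)
    data.frame(site_id = cells$site_id[i], tissue = cells$tissue[i],
               delta = mean(b) - mean(a), p = tt$p.value,
               significant = tt$p.value < alpha,
               n_early = length(a), n_late = length(b))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$site_id, res$tissue), , drop = FALSE]
}
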