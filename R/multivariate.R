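# Canonical correlation between the 13C and 2H feature blocks, Wilks' Lambda
# dimension tests (Rao's F approximation), Type II ANOVA attribution, and
# p-value adjustment utilities.

.sym_inv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  rank <- sum(keep)
  v <- e$vectors[, keep, drop = FALSE]
  list(half = v %*% diag(1 / sqrt(e$values[keep]), rank) %*% t(v),
       rank = rank)
}

#' Canonical correlation analysis of two feature blocks
#'
#' Computes canonical correlations, coefficient vectors and per-sample
#' canonical variates between two column-centered blocks (here the
#' delta-13C and delta-2H features), via singular value decomposition of the
#' whitened cross-covariance `Sxx^{-1/2} Sxy Syy^{-1/2}`. Rank-deficient
#' blocks are handled by truncating to the numerical rank (with a warning).
#'
#' @param X,Y Numeric matrices with matching rows (complete cases required).
#' @return An object of class `cca_result`: `cor` (descending canonical
#'   correlations), `xcoef`, `ycoef` (canonical coefficient matrices, one
#'   column per dimension), `xscores`, `yscores` (sample-aligned variates),
#'   `n`, `p`, `q`.
#' @export
canonical_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (anyNA(X) || anyNA(Y)) stop("Complete cases required for CCA", call. = FALSE)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= p + q) {
    warning("n (", n, ") <= p + q (", p + q,
            "); canonical correlations will be inflated")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  wx <- .sym_inv_sqrt(Sxx)
  wy <- .sym_inv_sqrt(Syy)
  if (wx$rank < p || wy$rank < q) {
    warning("Rank-deficient block(s): dimensions truncated to rank (",
            wx$rank, ", ", wy$rank, ")")
  }
  K <- wx$half %*% Sxy %*% wy$half
  sv <- svd(K)
  d <- min(wx$rank, wy$rank)
  cors <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  xcoef <- wx$half %*% sv$u[, seq_len(d), drop = FALSE]
  ycoef <- wy$half %*% sv$v[, seq_len(d), drop = FALSE]
  rownames(xcoef) <- colnames(X); rownames(ycoef) <- colnames(Y)
  colnames(xcoef) <- colnames(ycoef) <- paste0("dim", seq_len(d))
  structure(list(cor = cors, xcoef = xcoef, ycoef = ycoef,
                 xscores = Xc %*% xcoef, yscores = Yc %*% ycoef,
                 n = n, p = p, q = q),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %d x (%d, %d): canonical correlations\n",
              x$n, x$p, x$q))
  print(round(x$cor, 4))
  invisible(x)
}

#' Wilks' Lambda sequential dimension tests (Rao's F approximation)
#'
#' For each starting dimension k, tests whether canonical correlations
#' k..s are jointly zero: `Lambda_k = prod_{i >= k} (1 - r_i^2)` with Rao's
#' F approximation. For a single pair of variables this reduces exactly to
#' the ordinary correlation F test.
#'
#' @param cca A `cca_result`, or a numeric vector of canonical correlations
#'   (then `n`, `p`, `q` must be given).
#' @param n,p,q Sample size and block widths (taken from `cca` if a result
#'   object is passed).
#' @return Data frame with columns `dim`, `lambda`, `F`, `df1`, `df2`, `p`.
#' @export
wilks_lambda_test <- function(cca, n = NULL, p = NULL, q = NULL) {
  if (inherits(cca, "cca_result")) {
    r <- cca$cor; n <- cca$n; p <- cca$p; q <- cca$q
  } else {
    r <- cca
    stopifnot(!is.null(n), !is.null(p), !is.null(q))
  }
  s <- length(r)
  out <- vector("list", s)
  for (k in seq_len(s)) {
    pk <- p - k + 1L
    qk <- q - k + 1L
    lambda <- prod(1 - r[k:s]^2)
    m <- n - 3 / 2 - (pk + qk) / 2
    tt <- if (pk^2 + qk^2 - 5 > 0) {
      sqrt((pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5))
    } else 1
    df1 <- pk * qk
    df2 <- m * tt - pk * qk / 2 + 1
    if (df2 <= 0) {
      stop("Sample too small for Rao's F approximation at dimension ", k,
           " (df2 = ", round(df2, 2), ")", call. = FALSE)
    }
    lam_t <- lambda^(1 / tt)
    Fstat <- ((1 - lam_t) / lam_t) * (df2 / df1)
    out[[k]] <- data.frame(dim = k, lambda = lambda, F = Fstat,
                           df1 = df1, df2 = df2,
                           p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Type II ANOVA variance attribution
#'
#' Fits the additive linear model `y ~ factor1 + factor2 + ...` and, for
#' each term, compares the residual sum of squares of the model with all
#' other terms against the full model (the drop-one definition of Type II
#' sums of squares for additive models). Holm-adjusted p-values are
#' appended.
#'
#' @param y Numeric response.
#' @param design Data frame of factors (e.g. compound, site, tissue, taxon).
#' @param type `"II"` (default) or `"III"`; Type III uses sum-to-zero
#'   contrasts and is offered for sensitivity only.
#' @return Data frame with `term`, `ss`, `df`, `F`, `p`, `p_adj`.
#' @export
anova_type2 <- function(y, design, type = c("II", "III")) {
  type <- match.arg(type)
  design <- as.data.frame(design)
  design[] <- lapply(design, factor)
  empty <- names(design)[vapply(design, function(f) nlevels(droplevels(f)) < 2L,
                                logical(1))]
  if (length(empty) > 0L) {
    stop("Factor(s) with fewer than 2 observed levels: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  dat <- cbind(y = y, design)
  form <- stats::as.formula(paste("y ~", paste(names(design), collapse = " + ")))
  if (type == "III") {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
  }
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("Aliased factor level(s) in design: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  d1 <- stats::drop1(fit, scope = form, test = "F")
  d1 <- d1[-1, , drop = FALSE]  # drop the <none> row
  res <- data.frame(term = rownames(d1),
                    ss = d1$`Sum of Sq`,
                    df = d1$Df,
                    F = d1$`F value`,
                    p = d1$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  res$p_adj <- holm_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Holm step-down p-value adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Single-step Sidak p-value adjustment
#'
#' `1 - (1 - p)^m` for `m` simultaneous tests (default: `length(p)`).
#'
#' @param p Numeric vector of p-values.
#' @param m Number of simultaneous tests.
#' @return Adjusted p-values, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1 - (1 - p)^m, 1)
}

#' Estimated marginal means and Sidak-adjusted pairwise contrasts
#'
#' Fits the additive model, computes model-based means of the focal factor
#' on a balanced reference grid, and all pairwise differences with Sidak
#' adjustment and 95% confidence intervals.
#'
#' @param y Numeric response.
#' @param design Data frame of factors including `focal_factor`.
#' @param focal_factor Name of the factor whose levels are compared.
#' @return List with `means` (level, emmean, lower, upper) and `contrasts`
#'   (contrast, estimate, lower, upper, p_adj).
#' @export
emmeans_contrast <- function(y, design, focal_factor) {
  design <- as.data.frame(design)
  if (!focal_factor %in% names(design)) {
    stop("focal_factor '", focal_factor, "' not in design", call. = FALSE)
  }
  foc <- design[[focal_factor]]
  if (is.factor(foc) && any(table(foc) == 0L)) {
    stop("Empty level(s) in ", focal_factor, ": ",
         paste(names(which(table(foc) == 0L)), collapse = ", "),
         call. = FALSE)
  }
  design[] <- lapply(design, function(f) factor(f))
  dat <- cbind(y = y, design)
  form <- stats::as.formula(paste("y ~", paste(names(design), collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  em <- emmeans::emmeans(fit, specs = focal_factor)
  ems <- as.data.frame(em)
  means <- data.frame(level = ems[[focal_factor]],
                      emmean = ems$emmean,
                      lower = ems$lower.CL, upper = ems$upper.CL,
                      stringsAsFactors = FALSE)
  prs <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                               adjust = "sidak", infer = c(TRUE, TRUE)))
  contrasts <- data.frame(contrast = prs$contrast,
                          estimate = prs$estimate,
                          lower = prs$lower.CL, upper = prs$upper.CL,
                          p_adj = prs$p.value,
                          stringsAsFactors = FALSE)
  list(means = means, contrasts = contrasts)
}
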