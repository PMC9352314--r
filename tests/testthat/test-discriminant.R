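# LDA/CVA fitting, Mahalanobis prediction, bootstrap CV, pooling,
# consensus, cross-year transfer, year-shift tests.

two_class_1d <- function(n = 30, gap = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(c(rnorm(n), rnorm(n, gap)), ncol = 1,
              dimnames = list(NULL, "f1"))
  list(x = x, labels = rep(c("A", "B"), each = n))
}

test_that("fit_lda separates well-separated classes and degenerates gracefully", {
  d <- two_class_1d()
  m <- fit_lda(d$x, d$labels)
  pr <- predict(m, d$x, true_labels = d$labels)
  expect_equal(mean(pr$correct), 1)
  expect_equal(rowSums(attr(pr, "posterior")), rep(1, nrow(d$x)),
               tolerance = 1e-12)

  # identical class distributions: per-sample canonical eigenvalue near zero
  # (far below a separated configuration, where it scales with the squared
  # centroid gap)
  set.seed(2)
  x0 <- matrix(rnorm(400), 200, 2)
  m0 <- fit_lda(x0, rep(c("A", "B"), 100))
  expect_lt(max(m0$eigenvalues) / nrow(x0), 0.05)
  m_sep <- fit_lda(d$x, d$labels)
  expect_gt(max(m_sep$eigenvalues) / nrow(d$x),
            20 * max(m0$eigenvalues) / nrow(x0))

  expect_error(fit_lda(d$x, rep("A", nrow(d$x))), ">= 2 classes")
  expect_error(fit_lda(d$x[1:3, , drop = FALSE], c("A", "A", "B")),
               "fewer than 2")
})

test_that("canonical axes match the brute-force generalized eigen oracle", {
  set.seed(12)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, 3), n, 2),
             cbind(rnorm(n, 0), rnorm(n, 5)))
  labels <- rep(c("A", "B", "C"), each = n)
  m <- fit_lda(x, labels)
  # oracle: eigen decomposition of Sw^-1 B
  cls <- sort(unique(labels))
  cen <- t(sapply(cls, function(cl) colMeans(x[labels == cl, ])))
  Sw <- Reduce(`+`, lapply(cls, function(cl) {
    xc <- scale(x[labels == cl, ], center = TRUE, scale = FALSE)
    crossprod(xc)
  })) / (nrow(x) - 3)
  gm <- colMeans(x)
  B <- Reduce(`+`, lapply(cls, function(cl)
    sum(labels == cl) * tcrossprod(cen[cl, ] - gm))) / 2
  ev <- eigen(solve(Sw) %*% B)
  expect_equal(m$eigenvalues, Re(ev$values), tolerance = 1e-8)
  expect_equal(unname(m$prop_trace),
               unname(Re(ev$values) / sum(Re(ev$values))), tolerance = 1e-8)
  # axes equal up to sign/scale: check collinearity
  for (j in 1:2) {
    v1 <- m$axes[, j] / sqrt(sum(m$axes[, j]^2))
    v2 <- Re(ev$vectors[, j]) / sqrt(sum(Re(ev$vectors[, j])^2))
    expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-8)
  }
})

test_that("proportion of trace is invariant under invertible affine transforms", {
  set.seed(18)
  x <- rbind(matrix(rnorm(80), 40, 2), matrix(rnorm(80, 2), 40, 2))
  labels <- rep(c("A", "B"), each = 40)
  m1 <- fit_lda(x, labels)
  A <- matrix(c(1.5, 0.3, -0.2, 2), 2, 2)
  m2 <- fit_lda(x %*% A + 3, labels)
  expect_equal(m1$prop_trace, m2$prop_trace, tolerance = 1e-8)
})

test_that("prediction is the nearest-Mahalanobis-centroid rule with lexicographic ties", {
  d <- two_class_1d()
  m <- fit_lda(d$x, d$labels)
  expect_equal(predict(m, m$centroids)$predicted, m$classes)

  # equidistant sample under equal priors: tie broken to first label, flagged
  midpoint <- matrix(mean(m$centroids[, 1]), 1, 1,
                     dimnames = list(NULL, "f1"))
  pr_mid <- predict(m, midpoint)
  expect_true(pr_mid$tie)
  expect_equal(pr_mid$predicted, "A")

  # oracle equivalence on random seeded instances
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:5, 1); p <- sample(2:4, 1)
    x <- matrix(rnorm(20 * k * p), 20 * k, p)
    labels <- rep(paste0("C", 1:k), each = 20)
    x <- x + 2 * as.integer(factor(labels))
    model <- fit_lda(x, labels)
    newx <- matrix(rnorm(15 * p, 1.5), 15, p)
    got <- predict(model, newx)$predicted
    Sinv <- solve(model$pooled_cov)
    oracle <- apply(newx, 1, function(row) {
      d2 <- apply(model$centroids, 1, function(mu)
        t(row - mu) %*% Sinv %*% (row - mu))
      model$classes[which.min(d2)]
    })
    expect_identical(got, unname(oracle))
  }
})

test_that("predictions agree with MASS::lda as an independent cross-check", {
  skip_if_not_installed("MASS")
  set.seed(77)
  x <- rbind(matrix(rnorm(120), 40, 3), matrix(rnorm(120, 1.2), 40, 3),
             matrix(rnorm(120, -1), 40, 3))
  colnames(x) <- paste0("f", 1:3)
  labels <- rep(c("A", "B", "C"), each = 40)
  m <- fit_lda(x, labels)
  mm <- MASS::lda(x, grouping = labels,
                  prior = rep(1 / 3, 3))
  newx <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, colnames(x)))
  expect_identical(predict(m, newx)$predicted,
                   as.character(predict(mm, newx)$class))
  expect_equal(unname(m$prop_trace),
               unname(mm$svd^2 / sum(mm$svd^2)), tolerance = 1e-6)
})

test_that("bootstrap CV accuracy hits the separable and chance benchmarks", {
  d <- two_class_1d(n = 25, gap = 12)
  cv <- bootstrap_cv_accuracy(d$x, d$labels, n_boot = 60, seed = 1)
  expect_gt(cv$cv_accuracy, 0.99)
  expect_equal(cv$resubstitution_accuracy, 1)

  set.seed(10)
  x <- matrix(rnorm(240), 120, 2)
  labels <- sample(rep(paste0("C", 1:4), 30))
  cv2 <- bootstrap_cv_accuracy(x, labels, n_boot = 100, seed = 2)
  expect_lt(abs(cv2$cv_accuracy - 0.25), 0.08)  # chance level for k = 4

  # reproducible under the same seed
  cv3 <- bootstrap_cv_accuracy(x, labels, n_boot = 100, seed = 2)
  expect_identical(cv2$boot_accuracy, cv3$boot_accuracy)
})

test_that("CV accuracy does not beat resubstitution on average (optimism)", {
  deficit <- vapply(1:6, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(160), 80, 2)
    labels <- rep(c("A", "B"), 40)
    x[labels == "B", ] <- x[labels == "B", ] + 0.8
    cv <- bootstrap_cv_accuracy(x, labels, n_boot = 40, seed = seed)
    cv$resubstitution_accuracy - cv$cv_accuracy
  }, numeric(1))
  expect_gte(mean(deficit), 0)
})

test_that("Mahalanobis centroid distances follow the closed form", {
  # 1-D: centroids 0 and 3, pooled variance 9 -> distance |0-3|/3 = 1
  m <- list(classes = c("A", "B"),
            centroids = matrix(c(0, 3), 2, 1, dimnames = list(c("A", "B"), "f")),
            pooled_cov = matrix(9, 1, 1))
  class(m) <- "iso_lda"
  d <- mahalanobis_site_distance(m)
  expect_equal(d["A", "B"], 1)
  expect_equal(d["B", "A"], 1)
  expect_equal(unname(diag(d)), c(0, 0))

  m$centroids[2, ] <- 0
  expect_true(all(mahalanobis_site_distance(m) == 0))
})

test_that("pool_sites relabels per map and validates site ids", {
  labels <- c("S1", "S2", "S3", "S2")
  expect_identical(pool_sites(labels, c(S1 = "S1", S2 = "S2", S3 = "S3")),
                   labels)
  pooled <- pool_sites(labels, c(S2 = "S23", S3 = "S23"))
  expect_identical(pooled, c("S1", "S23", "S23", "S23"))
  expect_equal(length(unique(pooled)), length(unique(labels)) - 1L)
  expect_error(pool_sites(labels, c(S9 = "X")), "unknown site")
})

test_that("suggested pools require both isotopic and geographic proximity", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 0.1), 30, 2),
             matrix(rnorm(60, 8), 30, 2))
  labels <- rep(c("S1", "S2", "S3"), each = 30)
  m <- fit_lda(x, labels)
  geo <- matrix(c(0, 0.4, 5, 0.4, 0, 5, 5, 5, 0), 3, 3,
                dimnames = list(c("S1", "S2", "S3"), c("S1", "S2", "S3")))
  map <- suggest_site_pools(m, geo, mahal_max = 1, km_max = 1)
  expect_equal(unname(map["S1"]), unname(map["S2"]))
  expect_equal(unname(map["S3"]), "S3")
})

test_that("consensus assignment applies the 3-of-4 rule with small-n fallback", {
  meta <- data.frame(sample_id = paste0("smp", 1:10),
                     fish_id = c(rep("F1", 4), rep("F2", 4), rep("F3", 2)),
                     taxon = "C. gobio",
                     tissue = c(rep(c("muscle", "brain", "liver", "eye"), 2),
                                "muscle", "brain"),
                     site_id = "S1", year = 2016)
  asg <- data.frame(sample_id = meta$sample_id,
                    correct = c(TRUE, TRUE, TRUE, FALSE,   # F1: 3/4 -> TRUE
                                TRUE, TRUE, FALSE, FALSE,  # F2: 2/4 -> FALSE
                                TRUE, FALSE))              # F3: 1/2 -> FALSE
  res <- consensus_assign(asg, meta)
  expect_identical(res$site_specific[match(c("F1", "F2", "F3"), res$fish_id)],
                   c(TRUE, FALSE, FALSE))
  expect_error(consensus_assign(asg[0, ], meta), "No assignments")
})

test_that("cross-year transfer freezes the training model and scores tolerance", {
  set.seed(30)
  x <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             matrix(rnorm(100, 4, 0.5), 50, 2),
             cbind(rnorm(50, 4, 0.5), rnorm(50, 0, 0.5)))
  labels <- rep(c("S1", "S2", "S3"), each = 50)
  dist_km <- matrix(c(0, 0.5, 9, 0.5, 0, 9, 9, 9, 0), 3, 3,
                    dimnames = list(c("S1", "S2", "S3"), c("S1", "S2", "S3")))

  # test = train: perfect diagonal, both accuracies 1, tolerant >= exact
  res <- cross_year_predict(x, labels, x, labels, site_dist = dist_km)
  expect_equal(res$exact_accuracy, 1)
  expect_equal(res$tolerant_accuracy, 1)
  expect_true(all(res$confusion[upper.tri(res$confusion)] == 0))

  # a shifted test year degrades exact accuracy; S1<->S2 errors count as
  # tolerant because those sites are 0.5 km apart
  x_shift <- x + matrix(rnorm(300, 0, 2), 150, 2)
  res2 <- cross_year_predict(x, labels, x_shift, labels, site_dist = dist_km)
  expect_lt(res2$exact_accuracy, 1)
  expect_gte(res2$tolerant_accuracy, res2$exact_accuracy)
  expect_equal(sum(res2$confusion), 150)
  expect_equal(unname(rowSums(res2$confusion)), rep(50, 3))
  expect_equal(accuracy_from_confusion(res2$confusion), res2$exact_accuracy)
})

test_that("year shifts are detected per (site, tissue) cell and missing cells are NA", {
  set.seed(41)
  n <- 20
  meta <- data.frame(
    sample_id = paste0("s", 1:(4 * n)),
    fish_id = paste0("f", 1:(4 * n)),
    taxon = "C. gobio", tissue = "muscle",
    site_id = rep(c("S1", "S1", "S2", "S2"), each = n),
    year = rep(c(2016, 2018, 2016, 2018), each = n))
  y <- rnorm(4 * n, sd = 1)
  y[meta$site_id == "S1" & meta$year == 2018] <-
    y[meta$site_id == "S1" & meta$year == 2018] + 5
  fm <- structure(list(
    features = matrix(y, ncol = 1, dimnames = list(meta$sample_id, "d2H_LIN")),
    meta = meta, panel = "LIN", dropped = character()),
    class = "feature_matrix")
  res <- year_shift_test(fm, "d2H_LIN")
  s1 <- res[res$site_id == "S1", ]
  s2 <- res[res$site_id == "S2", ]
  expect_equal(s1$delta, 5, tolerance = 1)
  expect_true(s1$significant)
  expect_gt(s2$p, 0.05)

  # a site observed in only one year yields an NA row, not an error
  meta2 <- meta; meta2$year[meta2$site_id == "S2"] <- 2016
  fm2 <- fm; fm2$meta <- meta2
  res2 <- year_shift_test(fm2, "d2H_LIN")
  expect_true(is.na(res2$delta[res2$site_id == "S2"]))
})
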