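# CCA with whitened cross-covariance, Wilks/Rao dimension tests, Type II
# attribution, p adjustments, marginal means.

test_that("canonical correlations are exact in degenerate and independent cases", {
  set.seed(14)
  X <- matrix(rnorm(120), 40, 3)
  r_ident <- canonical_correlation(X, X)
  expect_equal(r_ident$cor, rep(1, 3), tolerance = 1e-8)

  Xn <- matrix(rnorm(2000), 1000, 2)
  Yn <- matrix(rnorm(2000), 1000, 2)
  expect_lt(canonical_correlation(Xn, Yn)$cor[1], 0.15)
})

test_that("canonical correlations match the generalized-eigenvalue oracle and cancor", {
  # oracle: eigenvalues of Sxx^-1 Sxy Syy^-1 Syx are the squared correlations
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30; p <- 5; q <- 3
    X <- matrix(rnorm(n * p), n, p)
    Y <- 0.5 * X[, 1:q] + matrix(rnorm(n * q), n, q)
    res <- canonical_correlation(X, Y)
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
    Sxy <- crossprod(Xc, Yc) / (n - 1)
    ev <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy))$values
    oracle <- sqrt(sort(Re(ev[seq_len(q)]), decreasing = TRUE))
    expect_equal(res$cor, oracle, tolerance = 1e-8)
    expect_equal(res$cor, stats::cancor(X, Y)$cor, tolerance = 1e-8)
  }
})

test_that("canonical correlations are invariant under affine transforms of a block", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  Y <- X[, 1:2] + matrix(rnorm(100), 50, 2)
  base <- canonical_correlation(X, Y)$cor
  A <- matrix(c(2, 0.5, -1, 3), 2, 2)
  Yt <- Y %*% A + matrix(rep(c(5, -2), each = 50), 50, 2)
  expect_equal(canonical_correlation(X, Yt)$cor, base, tolerance = 1e-8)
})

test_that("rank-deficient blocks are truncated with a warning", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  X3 <- cbind(X, X[, 1] + X[, 2])
  Y <- matrix(rnorm(60), 30, 2)
  expect_warning(res <- canonical_correlation(X3, Y), "Rank-deficient")
  expect_equal(length(res$cor), 2L)
})

test_that("Wilks' Lambda tests reduce to the correlation F-test when p = q = 1", {
  set.seed(6)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  r <- cor(x, y)
  wt <- wilks_lambda_test(abs(r), n = 40, p = 1, q = 1)
  ct <- cor.test(x, y)
  expect_equal(wt$F, unname(ct$statistic)^2, tolerance = 1e-10)
  expect_equal(wt$p, ct$p.value, tolerance = 1e-10)

  # all r = 0 -> Lambda 1, F 0, p 1
  null <- wilks_lambda_test(c(0, 0), n = 50, p = 2, q = 2)
  expect_equal(null$lambda, c(1, 1))
  expect_equal(null$F, c(0, 0), tolerance = 1e-12)
  expect_equal(null$p, c(1, 1))

  # Lambda strictly decreasing in any r_i
  a <- wilks_lambda_test(c(0.6, 0.3), n = 50, p = 2, q = 2)
  b <- wilks_lambda_test(c(0.7, 0.3), n = 50, p = 2, q = 2)
  expect_lt(b$lambda[1], a$lambda[1])

  expect_error(wilks_lambda_test(0.5, n = 3, p = 4, q = 4), "too small")
})

test_that("Type II attribution isolates the generating factor", {
  set.seed(13)
  n <- 120
  design <- data.frame(site = sample(paste0("S", 1:5), n, TRUE),
                       tissue = sample(c("muscle", "brain"), n, TRUE),
                       taxon = sample(c("a", "b", "c"), n, TRUE))
  y <- as.integer(factor(design$site)) * 2 + rnorm(n)
  res <- anova_type2(y, design)
  site_row <- res[res$term == "site", ]
  expect_lt(site_row$p, 1e-10)
  expect_gt(site_row$F, 10 * max(res$F[res$term != "site"]))
})

test_that("Type II equals sequential SS on balanced designs and matches car::Anova", {
  set.seed(2)
  design <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                        rep = 1:10)[, 1:2]
  y <- rnorm(40) + 2 * (design$a == "a2") - 1.5 * (design$b == "b2")
  res <- anova_type2(y, design)
  seq_tab <- anova(lm(y ~ a + b, data = cbind(y = y, design)))
  expect_equal(res$ss[res$term == "a"], seq_tab["a", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$ss[res$term == "b"], seq_tab["b", "Sum Sq"], tolerance = 1e-10)

  skip_if_not_installed("car")
  set.seed(15)
  design2 <- data.frame(a = sample(c("a1", "a2", "a3"), 50, TRUE),
                        b = sample(c("b1", "b2"), 50, TRUE))
  y2 <- rnorm(50) + (design2$a == "a2")
  res2 <- anova_type2(y2, design2)
  ca <- car::Anova(lm(y2 ~ a + b, data = cbind(y2 = y2, design2)), type = 2)
  expect_equal(res2$ss, ca[c("a", "b"), "Sum Sq"], tolerance = 1e-10)
  expect_equal(res2$F, ca[c("a", "b"), "F value"], tolerance = 1e-10)
})

test_that("Type II SS for the last term equals its Type I SS in unbalanced data", {
  set.seed(31)
  design <- data.frame(a = sample(c("x", "y"), 45, TRUE, prob = c(0.7, 0.3)),
                       b = sample(c("u", "v", "w"), 45, TRUE))
  y <- rnorm(45) + (design$a == "y") * 0.8
  res <- anova_type2(y, design)
  seq_tab <- anova(lm(y ~ a + b, data = cbind(y = y, design)))
  expect_equal(res$ss[res$term == "b"], seq_tab["b", "Sum Sq"], tolerance = 1e-10)
})

test_that("permuting the response destroys all attribution", {
  set.seed(44)
  n <- 80
  design <- data.frame(site = rep(paste0("S", 1:4), each = 20),
                       tissue = rep(c("m", "b"), 40))
  y <- as.integer(factor(design$site)) * 3 + rnorm(n)
  ps <- replicate(40, {
    res <- anova_type2(sample(y), design)
    res$p[res$term == "site"]
  })
  expect_lt(mean(ps < 0.05), 0.2)   # near-nominal false positives
  expect_gt(mean(ps), 0.25)         # roughly uniform p under the null
})

test_that("Holm and Sidak adjustments behave as stepwise/simultaneous corrections", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.02, m = 3), 1 - (1 - 0.02)^3)
  set.seed(1)
  p <- runif(20)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  expect_true(all(h <= pmin(length(p) * p, 1)))  # never above Bonferroni
  expect_true(all(diff(h[order(p)]) >= -1e-15))  # monotone in rank
})

test_that("marginal means equal raw means when balanced and recover true contrasts", {
  set.seed(19)
  design <- expand.grid(g = c("g1", "g2"), t = c("t1", "t2"), rep = 1:15)[, 1:2]
  y <- rnorm(60, sd = 0.8) + 5 * (design$g == "g2")
  res <- emmeans_contrast(y, design, "g")
  raw <- tapply(y, design$g, mean)
  expect_equal(res$means$emmean, as.numeric(raw[res$means$level]),
               tolerance = 1e-9)
  est <- res$contrasts$estimate[1]
  expect_equal(abs(est), 5, tolerance = 0.8)
  expect_true(res$contrasts$lower[1] <= est && est <= res$contrasts$upper[1])
  expect_lt(res$contrasts$p_adj[1], 1e-6)

  design2 <- design; design2$g <- factor(design2$g, levels = c("g1", "g2", "g3"))
  expect_error(emmeans_contrast(y, design2, "g"), "Empty level")
})
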