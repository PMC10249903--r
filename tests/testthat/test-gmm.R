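# Gaussian-mixture density layer: fitting, evaluation, conditionals.

test_that("single-component fit is the maximum-likelihood Gaussian", {
  g <- fit_gmm_1d(c(0, 0, 2, 2), max_components = 1, seed = 1, min_samples = 4)
  expect_equal(g$weights, 1)
  expect_equal(g$means, 1)
  expect_equal(g$variances, 1)  # ML variance: mean squared deviation
})

test_that("fitting rejects degenerate and insufficient data", {
  expect_error(fit_gmm_1d(rep(3, 50)), class = "aodesrs_degenerate_data")
  expect_error(fit_gmm_1d(c(1, 2, 3)), class = "aodesrs_training_data")
  expect_error(fit_gmm_2d(cbind(1:2, 3:4)), class = "aodesrs_training_data")
  expect_error(fit_gmm_2d(cbind(1:20, rep(1, 20)), min_samples = 10),
               class = "aodesrs_degenerate_data")
})

test_that("1-D fit recovers the generating Gaussian", {
  x <- withr::with_seed(42, rnorm(5000, -1, 0.2))
  g <- fit_gmm_1d(x, max_components = 5, seed = 42)
  # mixture moments (all components pooled)
  mu <- sum(g$weights * g$means)
  v <- sum(g$weights * (g$variances + g$means^2)) - mu^2
  expect_lt(abs(mu - (-1)), 0.02)
  expect_lt(abs(sqrt(v) - 0.2), 0.02)
})

test_that("2-D fit: symmetric four-point design and correlation recovery", {
  pts <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2))
  g <- fit_gmm_2d(pts, max_components = 1, min_samples = 4)
  expect_equal(g$means[1, ], c(1, 1))
  expect_equal(g$covariances[, , 1], diag(2), tolerance = 1e-5)  # + ridge

  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  X <- withr::with_seed(7, matrix(rnorm(10000), ncol = 2) %*% chol(S))
  g2 <- fit_gmm_2d(X, max_components = 5, seed = 7)
  # pooled mixture covariance
  mu <- colSums(g2$weights * g2$means)
  C <- matrix(0, 2, 2)
  for (i in seq_len(g2$n_components)) {
    d <- g2$means[i, ] - mu
    C <- C + g2$weights[i] * (g2$covariances[, , i] + outer(d, d))
  }
  rho <- C[1, 2] / sqrt(C[1, 1] * C[2, 2])
  expect_lt(abs(rho - 0.9), 0.03)
})

test_that("BIC model selection is deterministic given data and seed", {
  x <- withr::with_seed(3, c(rnorm(300, -2, 0.5), rnorm(300, 2, 0.5)))
  g1 <- fit_gmm_1d(x, seed = 11)
  g2 <- fit_gmm_1d(x, seed = 11)
  expect_identical(g1, g2)
  expect_gt(g1$n_components, 1)  # clearly bimodal input
})

test_that("log10 1-D density matches the closed-form Gaussian pdf", {
  g <- gmm1d(1, -1, 0.04)
  expect_equal(log10_density_1d(g, -1), log10(dnorm(-1, -1, 0.2)),
               tolerance = 1e-12)
  expect_equal(log10_density_1d(g, -1), 0.29988, tolerance = 1e-4)
  expect_equal(log10_density_1d(g, 0), log10(dnorm(0, -1, 0.2)),
               tolerance = 1e-12)
  expect_equal(log10_density_1d(g, 0), -5.1288, tolerance = 1e-4)
  # two identical components collapse to the single-component density
  g2 <- gmm1d(c(0.5, 0.5), c(-1, -1), c(0.04, 0.04))
  xs <- seq(-3, 3, length.out = 41)
  expect_equal(log10_density_1d(g2, xs), log10_density_1d(g, xs),
               tolerance = 1e-12)
  expect_error(log10_density_1d(g, NA_real_), class = "aodesrs_input")
})

test_that("log-space evaluation stays finite 30 sd into the tail", {
  g <- gmm1d(1, 0, 1)
  expect_true(is.finite(log10_density_1d(g, 30)))
  expect_equal(log10_density_1d(g, 30), log10(exp(1)) * (-450) - log10(sqrt(2 * pi)),
               tolerance = 1e-9)
})

test_that("log10 2-D density matches the closed-form bivariate pdf", {
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  g <- gmm2d(1, matrix(c(0, 0), 1), array(S, c(2, 2, 1)))
  bvn <- function(x, y) {
    q <- (x^2 - 2 * 0.9 * x * y + y^2) / (1 - 0.81)
    exp(-q / 2) / (2 * pi * sqrt(1 - 0.81))
  }
  expect_equal(log10_density_2d(g, 1, 1), log10(bvn(1, 1)), tolerance = 1e-12)
  expect_equal(log10_density_2d(g, 1, 1), -0.6661, tolerance = 1e-4)
  expect_equal(log10_density_2d(g, 1, -1), log10(bvn(1, -1)), tolerance = 1e-12)
  expect_equal(log10_density_2d(g, 1, -1), -4.7805, tolerance = 1e-4)
})

test_that("independent joint factorizes into its marginals", {
  g <- gmm2d(1, matrix(c(0.3, -0.2), 1), array(diag(c(1.2, 0.7)), c(2, 2, 1)))
  m1 <- gmm1d(1, 0.3, 1.2)
  m2 <- gmm1d(1, -0.2, 0.7)
  pts <- withr::with_seed(5, matrix(rnorm(40), ncol = 2))
  expect_equal(log10_density_2d(g, pts[, 1], pts[, 2]),
               log10_density_1d(m1, pts[, 1]) + log10_density_1d(m2, pts[, 2]),
               tolerance = 1e-9)
  # conditional reduces to the joint's own marginal under independence
  expect_equal(log10_conditional_density(g, pts[, 1], pts[, 2]),
               log10_density_1d(m1, pts[, 1]), tolerance = 1e-9)
})

test_that("conditional density matches the closed-form conditional Gaussian", {
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  g <- gmm2d(1, matrix(c(0, 0), 1), array(S, c(2, 2, 1)))
  # X | Y = 1 is N(0.9, 0.19)
  expect_equal(log10_conditional_density(g, 0.9, 1),
               log10(dnorm(0.9, 0.9, sqrt(0.19))), tolerance = 1e-12)
  expect_lt(abs(log10_conditional_density(g, 0.9, 1) - (-0.03848)), 1e-4)
})

test_that("conditional-consistency: conditional x marginal = joint", {
  g <- gmm2d(c(0.4, 0.6), rbind(c(-1, 0.5), c(2, -1)),
             array(c(1, 0.3, 0.3, 0.8, 0.5, -0.2, -0.2, 1.5), c(2, 2, 2)))
  pts <- withr::with_seed(9, matrix(rnorm(60, sd = 2), ncol = 2))
  lhs <- log10_conditional_density(g, pts[, 1], pts[, 2]) +
    log10_marginal_2d(g, pts[, 2], margin = 2)
  expect_equal(lhs, log10_density_2d(g, pts[, 1], pts[, 2]), tolerance = 1e-9)
})

test_that("densities integrate to one (quadrature oracle)", {
  x <- withr::with_seed(21, c(rnorm(400, -2, 0.6), rnorm(200, 1.5, 0.4)))
  g <- fit_gmm_1d(x, seed = 21)
  dens <- function(t) 10^log10_density_1d(g, t)
  expect_equal(integrate(dens, -15, 15, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # conditional of a 2-component joint integrates to 1 over the target
  g2 <- gmm2d(c(0.7, 0.3), rbind(c(0, 0), c(2, 1)),
              array(c(1, 0.5, 0.5, 1, 0.6, -0.3, -0.3, 0.9), c(2, 2, 2)))
  cdens <- function(t) 10^log10_conditional_density(g2, t, x_j = 0.7)
  expect_equal(integrate(cdens, -10, 10, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
})

test_that("mixture containers validate their invariants", {
  expect_error(gmm1d(c(0.6, 0.5), c(0, 1), c(1, 1)), class = "aodesrs_validation")
  expect_error(gmm1d(1, 0, 0), class = "aodesrs_validation")
  expect_error(gmm2d(1, matrix(c(0, 0), 1),
                     array(matrix(c(1, 2, 2, 1), 2), c(2, 2, 1))),
               class = "aodesrs_validation")  # not positive definite
})
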