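#' One-dimensional Gaussian mixture density
#'
#' Container for a univariate Gaussian mixture: the per-class marginal
#' attribute density f(X = x | class) used by the AODE likelihood. Weights
#' must be strictly positive and sum to one; variances are kept above a
#' strictly positive floor so the density can never degenerate to a spike.
#'
#' @param weights Numeric vector of component weights (positive, sum to 1).
#' @param means Numeric vector of component means (attribute units).
#' @param variances Numeric vector of component variances (> 0).
#' @return An object of class `gmm1d` with fields `weights`, `means`,
#'   `variances`, `n_components`.
#' @seealso [fit_gmm_1d()], [log10_density_1d()]
#' @export
gmm1d <- function(weights, means, variances) {
  weights <- as.numeric(weights)
  means <- as.numeric(means)
  variances <- as.numeric(variances)
  k <- length(weights)
  if (k < 1L || length(means) != k || length(variances) != k)
    aode_stop("validation", "weights, means and variances must have equal positive length")
  if (any(!is.finite(weights)) || any(weights <= 0))
    aode_stop("validation", "mixture weights must be finite and strictly positive")
  if (abs(sum(weights) - 1) > 1e-9)
    aode_stop("validation", "mixture weights must sum to 1 (got ", sum(weights), ")")
  if (any(!is.finite(means)) || any(!is.finite(variances)) || any(variances <= 0))
    aode_stop("validation", "component means must be finite and variances strictly positive")
  structure(
    list(weights = weights / sum(weights), means = means,
         variances = variances, n_components = k),
    class = "gmm1d")
}

#' Two-dimensional Gaussian mixture density
#'
#' Container for a bivariate Gaussian mixture: the per-class joint density
#' f(Xa = xa, Xb = xb | class) for one attribute pair, from which conditional
#' densities are derived. Every covariance matrix must be symmetric positive
#' definite.
#'
#' @param weights Numeric vector of component weights (positive, sum to 1).
#' @param means Matrix with one row per component and two columns.
#' @param covariances 2 x 2 x k array of component covariance matrices.
#' @param attribute_pair Character vector of length 2 naming the coordinates.
#' @return An object of class `gmm2d`.
#' @seealso [fit_gmm_2d()], [log10_density_2d()], [log10_conditional_density()]
#' @export
gmm2d <- function(weights, means, covariances, attribute_pair = c("x1", "x2")) {
  weights <- as.numeric(weights)
  k <- length(weights)
  means <- matrix(as.numeric(means), nrow = k, ncol = 2L)
  covariances <- array(as.numeric(covariances), dim = c(2L, 2L, k))
  if (k < 1L) aode_stop("validation", "at least one component required")
  if (any(!is.finite(weights)) || any(weights <= 0))
    aode_stop("validation", "mixture weights must be finite and strictly positive")
  if (abs(sum(weights) - 1) > 1e-9)
    aode_stop("validation", "mixture weights must sum to 1 (got ", sum(weights), ")")
  if (any(!is.finite(means))) aode_stop("validation", "component means must be finite")
  for (i in seq_len(k)) {
    S <- covariances[, , i]
    if (any(!is.finite(S)) || abs(S[1L, 2L] - S[2L, 1L]) > 1e-12 * max(1, abs(S[1L, 2L])))
      aode_stop("validation", "covariance matrices must be finite and symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      aode_stop("validation", "covariance matrix of component ", i,
                " is not positive definite (min eigenvalue ", min(ev), ")")
  }
  structure(
    list(weights = weights / sum(weights), means = means,
         covariances = covariances, n_components = k,
         attribute_pair = as.character(attribute_pair)),
    class = "gmm2d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("Gaussian mixture (1-D),", x$n_components, "component(s)\n")
  print(data.frame(weight = x$weights, mean = x$means, sd = sqrt(x$variances)))
  invisible(x)
}

#' @export
print.gmm2d <- function(x, ...) {
  cat("Gaussian mixture (2-D),", x$n_components, "component(s), pair (",
      paste(x$attribute_pair, collapse = ", "), ")\n")
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  component %d: weight %.4g, mean (%.4g, %.4g), cov [%.4g %.4g; %.4g %.4g]\n",
                i, x$weights[i], x$means[i, 1L], x$means[i, 2L],
                x$covariances[1L, 1L, i], x$covariances[1L, 2L, i],
                x$covariances[2L, 1L, i], x$covariances[2L, 2L, i]))
  }
  invisible(x)
}

# Default variance floor: a small fraction of the squared data range, so a
# fitted component can never collapse onto a repeated value.
variance_floor_for <- function(values, floor = NULL) {
  if (!is.null(floor)) return(floor)
  r <- diff(range(values))
  max(1e-8 * r^2, .Machine$double.xmin)
}

#' Fit a one-dimensional Gaussian mixture by EM with BIC model selection
#'
#' Fits mixtures with 1..`max_components` components (unequal variances) and
#' returns the fit minimizing BIC. Fitting is delegated to
#' \code{mclust::Mclust}, whose model-based hierarchical initialization makes
#' the result deterministic for a given data vector; the seed is still set for
#' reproducibility of any stochastic fallback. Component variances are clipped
#' below at `variance_floor` (default `1e-8 * range(values)^2`).
#'
#' @param values Numeric vector of finite attribute values.
#' @param max_components Maximum number of mixture components (>= 1).
#' @param seed Integer seed.
#' @param min_samples Minimum number of values required (default 10).
#' @param variance_floor Optional variance floor override.
#' @return A [gmm1d()] object.
#' @examples
#' fit_gmm_1d(c(0, 0, 2, 2), max_components = 1, seed = 1, min_samples = 4)
#' @export
fit_gmm_1d <- function(values, max_components = 5L, seed = 1L,
                       min_samples = 10L, variance_floor = NULL) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (any(!is.finite(values))) aode_stop("input", "attribute values must be finite")
  if (max_components < 1L) aode_stop("validation", "max_components must be >= 1")
  if (length(values) < min_samples)
    aode_stop("training_data", "need at least ", min_samples,
              " values to fit a marginal density, got ", length(values))
  if (stats::sd(values) == 0)
    aode_stop("degenerate_data", "attribute has zero variance (all values equal ",
              values[1L], "); cannot fit a density")
  floor <- variance_floor_for(values, variance_floor)
  if (max_components == 1L) {
    v <- mean((values - mean(values))^2)  # ML variance
    return(gmm1d(1, mean(values), max(v, floor)))
  }
  fit <- with_seed(seed, suppressWarnings(
    mclust::Mclust(values, G = seq_len(max_components), modelNames = "V",
                   verbose = FALSE)))
  if (is.null(fit)) {  # EM failed for every G: fall back to the 1-component ML fit
    v <- mean((values - mean(values))^2)
    return(gmm1d(1, mean(values), max(v, floor)))
  }
  p <- fit$parameters
  sig2 <- p$variance$sigmasq
  if (length(sig2) == 1L) sig2 <- rep(sig2, fit$G)
  gmm1d(p$pro, p$mean, pmax(sig2, floor))
}

# Regularize a 2x2 covariance: symmetrize, ridge the diagonal, and lift the
# smallest eigenvalue to `floor` if needed.
regularize_cov2 <- function(S, floor, ridge = 1e-6) {
  S <- (S + t(S)) / 2
  S <- S + diag(ridge, 2L)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor) {
    vals <- pmax(e$values, floor)
    S <- e$vectors %*% diag(vals) %*% t(e$vectors)
    S <- (S + t(S)) / 2
  }
  S
}

#' Fit a two-dimensional Gaussian mixture by EM with BIC model selection
#'
#' Rows containing a missing value are excluded before fitting
#' (pairwise-complete). Full covariance matrices are fitted per component and
#' regularized (1e-6 ridge on the diagonal plus an eigenvalue floor).
#'
#' @param pairs Two-column numeric matrix (or data.frame) of value pairs.
#' @param max_components Maximum number of mixture components.
#' @param seed Integer seed.
#' @param min_samples Minimum number of complete pairs required (default 10).
#' @param variance_floor Optional eigenvalue floor override.
#' @param attribute_pair Names of the two coordinates.
#' @return A [gmm2d()] object.
#' @export
fit_gmm_2d <- function(pairs, max_components = 5L, seed = 1L,
                       min_samples = 10L, variance_floor = NULL,
                       attribute_pair = c("x1", "x2")) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) aode_stop("validation", "pairs must have exactly two columns")
  storage.mode(pairs) <- "double"
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (any(!is.finite(pairs))) aode_stop("input", "attribute values must be finite")
  if (max_components < 1L) aode_stop("validation", "max_components must be >= 1")
  if (nrow(pairs) < min_samples)
    aode_stop("training_data", "need at least ", min_samples,
              " complete pairs to fit a joint density, got ", nrow(pairs))
  if (stats::sd(pairs[, 1L]) == 0 || stats::sd(pairs[, 2L]) == 0)
    aode_stop("degenerate_data", "one coordinate of the pair has zero variance")
  floor <- max(variance_floor_for(pairs[, 1L], variance_floor),
               variance_floor_for(pairs[, 2L], variance_floor))
  ml_single <- function() {
    mu <- colMeans(pairs)
    S <- crossprod(sweep(pairs, 2L, mu)) / nrow(pairs)
    gmm2d(1, matrix(mu, 1L), array(regularize_cov2(S, floor), c(2L, 2L, 1L)),
          attribute_pair)
  }
  if (max_components == 1L) return(ml_single())
  fit <- with_seed(seed, suppressWarnings(
    mclust::Mclust(pairs, G = seq_len(max_components), modelNames = "VVV",
                   verbose = FALSE)))
  if (is.null(fit)) return(ml_single())
  p <- fit$parameters
  k <- fit$G
  covs <- array(0, c(2L, 2L, k))
  for (i in seq_len(k)) covs[, , i] <- regularize_cov2(p$variance$sigma[, , i], floor)
  gmm2d(p$pro, t(p$mean), covs, attribute_pair)
}

#' Evaluate a 1-D Gaussian mixture density on the log10 scale
#'
#' Computed in log space (log-sum-exp over components), so the result is
#' finite for any representable x, however far into the tail.
#'
#' @param model A [gmm1d()] object.
#' @param x Numeric vector of evaluation points (finite).
#' @return log10 density at each `x`.
#' @export
log10_density_1d <- function(model, x) {
  stopifnot(inherits(model, "gmm1d"))
  if (any(!is.finite(x))) aode_stop("input", "evaluation points must be finite")
  k <- model$n_components
  L <- matrix(NA_real_, length(x), k)
  for (i in seq_len(k)) {
    L[, i] <- log(model$weights[i]) +
      stats::dnorm(x, model$means[i], sqrt(model$variances[i]), log = TRUE)
  }
  row_logsumexp(L) / LN10
}

# Per-component bivariate normal log density (natural log), vectorized in x, y.
bvn_log_density <- function(x, y, mu, S) {
  dx <- x - mu[1L]; dy <- y - mu[2L]
  det <- S[1L, 1L] * S[2L, 2L] - S[1L, 2L]^2
  q <- (S[2L, 2L] * dx^2 - 2 * S[1L, 2L] * dx * dy + S[1L, 1L] * dy^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Evaluate a 2-D Gaussian mixture density on the log10 scale
#'
#' @param model A [gmm2d()] object.
#' @param x,y Numeric vectors of coordinates (finite, recycled to a common
#'   length), in the order of `model$attribute_pair`.
#' @return log10 joint density at each (x, y).
#' @export
log10_density_2d <- function(model, x, y) {
  stopifnot(inherits(model, "gmm2d"))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    aode_stop("input", "evaluation points must be finite")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  L <- matrix(NA_real_, n, model$n_components)
  for (i in seq_len(model$n_components)) {
    L[, i] <- log(model$weights[i]) +
      bvn_log_density(x, y, model$means[i, ], model$covariances[, , i])
  }
  row_logsumexp(L) / LN10
}

#' Marginal of a 2-D Gaussian mixture in one coordinate, on the log10 scale
#'
#' The marginal implied by the joint model itself: the mixture of its
#' components' univariate projections. This is the denominator used when
#' deriving conditional densities from the joint.
#'
#' @param model A [gmm2d()] object.
#' @param x Numeric vector of evaluation points.
#' @param margin Which coordinate (1 or 2) to marginalize onto.
#' @return log10 marginal density at each `x`.
#' @export
log10_marginal_2d <- function(model, x, margin = 2L) {
  stopifnot(inherits(model, "gmm2d"), margin %in% c(1L, 2L))
  if (any(!is.finite(x))) aode_stop("input", "evaluation points must be finite")
  L <- matrix(NA_real_, length(x), model$n_components)
  for (i in seq_len(model$n_components)) {
    L[, i] <- log(model$weights[i]) +
      stats::dnorm(x, model$means[i, margin],
                   sqrt(model$covariances[margin, margin, i]), log = TRUE)
  }
  row_logsumexp(L) / LN10
}

# Conditional log10 density of one coordinate given the other, derived from
# the joint mixture: equals log10 f(x, y) - log10 f_margin(conditioning
# value). Written as a mixture of component conditionals, which is the same
# quantity in one numerically stable pass. `given` is the conditioning
# coordinate index (the value `x_given` belongs to).
cond_log10_density <- function(model, x_target, x_given, given = 2L) {
  target <- if (given == 2L) 1L else 2L
  n <- max(length(x_target), length(x_given))
  x_target <- rep_len(x_target, n); x_given <- rep_len(x_given, n)
  k <- model$n_components
  LW <- matrix(NA_real_, n, k)   # log responsibilities (unnormalized)
  LC <- matrix(NA_real_, n, k)   # component conditional log densities
  for (i in seq_len(k)) {
    S <- model$covariances[, , i]
    sgg <- S[given, given]
    stg <- S[target, given]
    LW[, i] <- log(model$weights[i]) +
      stats::dnorm(x_given, model$means[i, given], sqrt(sgg), log = TRUE)
    cmean <- model$means[i, target] + (stg / sgg) * (x_given - model$means[i, given])
    cvar <- S[target, target] - stg^2 / sgg
    LC[, i] <- stats::dnorm(x_target, cmean, sqrt(cvar), log = TRUE)
  }
  (row_logsumexp(LW + LC) - row_logsumexp(LW)) / LN10
}

#' Conditional density derived from a joint 2-D Gaussian mixture
#'
#' Returns log10 f(x_i | x_j) where the joint mixture holds coordinates
#' (i, j) in that order. The denominator is the joint model's own implied
#' marginal in the conditioning coordinate, so the conditional integrates to
#' one over x_i by construction.
#'
#' @param joint A [gmm2d()] object over coordinates (i, j).
#' @param x_i Value(s) of the target coordinate.
#' @param x_j Value(s) of the conditioning coordinate.
#' @return log10 conditional density.
#' @export
log10_conditional_density <- function(joint, x_i, x_j) {
  stopifnot(inherits(joint, "gmm2d"))
  if (any(!is.finite(x_i)) || any(!is.finite(x_j)))
    aode_stop("input", "evaluation points must be finite")
  cond_log10_density(joint, x_i, x_j, given = 2L)
}
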