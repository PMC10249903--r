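# Seeded generators for the scenarios the diagnostics are designed around:
# a 1-D two-class problem, bivariate two-class problems with contrasting
# correlation structure, a 3-class correlated-morphology table with one class
# intermediate between the others, cohort mean-shift / class-separation-shrink
# scenarios, and informative-vs-noise attribute tables for missingness
# experiments. Every generator is a pure function of (parameters, seed).

mvn_draw <- function(n, mean, Sigma) {
  p <- length(mean)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% L, 2L, mean, "+")
}

#' Two well-separated classes on a single attribute
#'
#' Class 1 is drawn from N(means[1], sd^2) and class 2 from N(means[2],
#' sd^2); the defaults (means -1 and +1, sd 0.2, 1000 instances per class)
#' give two narrow, clearly separated classes, so the region between them is
#' poorly supported by either and the reliability score dips there even
#' though the posterior sweeps confidently from one class to the other.
#'
#' @param n_per_class Instances per class (default 1000).
#' @param means Length-2 vector of class means (default c(-1, 1)).
#' @param sd Common standard deviation (> 0, default 0.2).
#' @param seed Integer seed.
#' @return A labeled [attribute_table()] with one attribute `x` and classes
#'   `class1`, `class2`.
#' @export
gen_1d_two_class <- function(n_per_class = 1000L, means = c(-1, 1), sd = 0.2,
                             seed = 1L) {
  if (n_per_class < 1L) aode_stop("validation", "n_per_class must be >= 1")
  if (!is_number(sd) || sd <= 0) aode_stop("validation", "sd must be > 0")
  if (length(means) != 2L || any(!is.finite(means)))
    aode_stop("validation", "means must be two finite values")
  with_seed(seed, {
    x <- c(stats::rnorm(n_per_class, means[1L], sd),
           stats::rnorm(n_per_class, means[2L], sd))
    attribute_table(data.frame(
      x = x, class = rep(c("class1", "class2"), each = n_per_class)),
      class_column = "class")
  })
}

#' Preset bivariate two-class scenarios
#'
#' Three presets exercising distinct correlation structure:
#' \describe{
#'   \item{"X-like"}{two separated independent blobs — instances between the
#'     classes get intermediate posteriors with a low reliability score;}
#'   \item{"Y-like"}{two broad overlapping blobs — intermediate posteriors
#'     with a high reliability score (genuine ambiguity);}
#'   \item{"Z-like"}{both classes centered at the origin with opposite strong
#'     correlations (+0.9 vs -0.9) — classification is carried entirely by
#'     the joint structure, and instances off both correlation ridges are
#'     jointly atypical despite typical marginal values.}
#' }
#' A custom `spec` may be supplied instead: a named list of classes, each
#' with `weights`, `means` (k x 2), `covariances` (2 x 2 x k) and optionally
#' `n`.
#'
#' @param preset One of "X-like", "Y-like", "Z-like" (ignored when `spec`
#'   given).
#' @param n_per_class Instances per class (default 1000).
#' @param seed Integer seed.
#' @param spec Optional explicit scenario specification.
#' @return A labeled [attribute_table()] with attributes `x1`, `x2`.
#' @export
gen_2d_classes <- function(preset = c("X-like", "Y-like", "Z-like"),
                           n_per_class = 1000L, seed = 1L, spec = NULL) {
  if (is.null(spec)) {
    preset <- match.arg(preset)
    cov_rho <- function(v, rho) matrix(c(v, rho * v, rho * v, v), 2L)
    spec <- switch(preset,
      "X-like" = list(
        class1 = list(weights = 1, means = c(-1, -1), covariances = cov_rho(0.09, 0)),
        class2 = list(weights = 1, means = c(1, 1), covariances = cov_rho(0.09, 0))),
      "Y-like" = list(
        class1 = list(weights = 1, means = c(-0.4, -0.4), covariances = cov_rho(0.36, 0)),
        class2 = list(weights = 1, means = c(0.4, 0.4), covariances = cov_rho(0.36, 0))),
      "Z-like" = list(
        class1 = list(weights = 1, means = c(0, 0), covariances = cov_rho(0.25, 0.9)),
        class2 = list(weights = 1, means = c(0, 0), covariances = cov_rho(0.25, -0.9))))
  }
  if (is.null(names(spec))) aode_stop("validation", "spec must be a named list of classes")
  with_seed(seed, {
    blocks <- lapply(names(spec), function(lb) {
      cs <- spec[[lb]]
      n <- as.integer(cs$n %||% n_per_class)
      if (n < 1L) aode_stop("validation", "class '", lb, "': n must be >= 1")
      w <- as.numeric(cs$weights)
      if (abs(sum(w) - 1) > 1e-9)
        aode_stop("validation", "class '", lb, "': weights must sum to 1")
      k <- length(w)
      means <- matrix(as.numeric(cs$means), nrow = k, ncol = 2L)
      covs <- array(as.numeric(cs$covariances), dim = c(2L, 2L, k))
      for (i in seq_len(k)) {
        ev <- eigen((covs[, , i] + t(covs[, , i])) / 2, symmetric = TRUE,
                    only.values = TRUE)$values
        if (min(ev) <= 0)
          aode_stop("validation", "class '", lb, "': covariance ", i,
                    " is not positive definite")
      }
      comp <- sample.int(k, n, replace = TRUE, prob = w)
      X <- matrix(0, n, 2L)
      for (i in seq_len(k)) {
        idx <- which(comp == i)
        if (length(idx)) X[idx, ] <- mvn_draw(length(idx), means[i, ], covs[, , i])
      }
      data.frame(x1 = X[, 1L], x2 = X[, 2L], class = lb)
    })
    attribute_table(do.call(rbind, blocks), class_column = "class")
  })
}

#' Uniform draws over a rectangle
#'
#' Test-point generator for mapping posterior probability and reliability
#' score over the attribute plane; defaults match a (-2, 2) x (-2, 2) box
#' with 2000 points.
#'
#' @param bounds Named list of c(lower, upper) per attribute (default
#'   `list(x1 = c(-2, 2), x2 = c(-2, 2))`).
#' @param n Number of points (default 2000).
#' @param seed Integer seed.
#' @return An unlabeled [attribute_table()].
#' @export
uniform_grid_sample <- function(bounds = list(x1 = c(-2, 2), x2 = c(-2, 2)),
                                n = 2000L, seed = 1L) {
  if (n < 1L) aode_stop("validation", "n must be >= 1")
  for (b in bounds) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L])
      aode_stop("validation", "each bound must be a finite interval (lower < upper)")
  }
  with_seed(seed, {
    cols <- lapply(bounds, function(b) stats::runif(n, b[1L], b[2L]))
    attribute_table(as.data.frame(cols, check.names = FALSE))
  })
}

#' Three correlated-attribute classes with one class intermediate
#'
#' Emulates a seed-morphology table: attributes load on a single latent size
#' factor (loadings ramp from 0.4 to 0.8) plus independent residual noise
#' (sd 0.3), so pairwise correlations are strong. Class centers sit at
#' factor positions -4 (class2), 0 (class1) and +4 (class3): class 1 is
#' componentwise intermediate between the other two, the hard case for
#' unknown-class detection since none of its attribute values is extreme.
#'
#' @param n_per_class Instances per class (default 70, >= 10).
#' @param n_attributes Number of attributes (default 7, >= 2).
#' @param seed Integer seed.
#' @return A labeled [attribute_table()] with classes `class1`..`class3` and
#'   attributes `a1`..`a<n>`.
#' @export
gen_multiclass_unknown <- function(n_per_class = 70L, n_attributes = 7L,
                                   seed = 1L) {
  if (n_per_class < 10L) aode_stop("validation", "n_per_class must be >= 10")
  if (n_attributes < 2L) aode_stop("validation", "n_attributes must be >= 2")
  lambda <- seq(0.4, 0.8, length.out = n_attributes)
  centers <- c(class1 = 0, class2 = -4, class3 = 4)
  noise_sd <- 0.3
  with_seed(seed, {
    blocks <- lapply(names(centers), function(lb) {
      f <- stats::rnorm(n_per_class, centers[[lb]], 1)
      X <- outer(f, lambda) +
        matrix(stats::rnorm(n_per_class * n_attributes, 0, noise_sd),
               n_per_class, n_attributes)
      df <- as.data.frame(X)
      names(df) <- paste0("a", seq_len(n_attributes))
      df$class <- lb
      df
    })
    attribute_table(do.call(rbind, blocks), class_column = "class")
  })
}

#' Training / matched / mismatched binary-class cohorts
#'
#' Generates three cohorts of a two-class problem over `n_attributes`
#' correlated attributes (unit variances; a fixed random correlation matrix
#' drawn once per seed). The class effect adds 0.8 to the first 8 attributes
#' of the "elevated" class. The training and matched cohorts share one
#' distribution; the mismatched cohort is translated by `shift` (a systematic
#' mean shift, as when a model trained on one sex is applied to the other)
#' and its between-class mean gap is multiplied by `separation_scale`
#' (`< 1` shrinks the class difference, as when the class-defining contrast
#' is weaker in a different ancestry cohort).
#'
#' @param n_per_cohort Rows per cohort (default 800, >= 10; split evenly
#'   between the two classes).
#' @param shift Mean shift of the mismatched cohort: a single number applied
#'   to every attribute or a vector of length `n_attributes` (default 0.4,
#'   the scale of typical between-sex differences across blood biomarkers).
#' @param separation_scale Multiplier on the mismatched cohort's class gap
#'   (default 1).
#' @param n_attributes Number of attributes (default 22).
#' @param seed Integer seed.
#' @return A list of labeled [attribute_table()]s: `train`, `matched`,
#'   `mismatched`.
#' @export
gen_cohort_shift <- function(n_per_cohort = 800L, shift = 0.4,
                             separation_scale = 1, n_attributes = 22L,
                             seed = 1L) {
  if (n_per_cohort < 10L) aode_stop("validation", "n_per_cohort must be >= 10")
  if (!is_number(separation_scale) || separation_scale < 0)
    aode_stop("validation", "separation_scale must be a non-negative number")
  if (length(shift) == 1L) shift <- rep(shift, n_attributes)
  if (length(shift) != n_attributes || any(!is.finite(shift)))
    aode_stop("validation", "shift must be finite, length 1 or n_attributes")
  beta <- c(rep(0.8, min(8L, n_attributes)),
            rep(0, max(0L, n_attributes - 8L)))  # class effect: elevated - normal
  n_el <- n_per_cohort %/% 2L
  n_no <- n_per_cohort - n_el
  with_seed(seed, {
    A <- matrix(stats::rnorm(n_attributes * 2L * n_attributes),
                2L * n_attributes, n_attributes)
    Sigma <- stats::cov2cor(crossprod(A) / (2L * n_attributes) +
                              diag(0.1, n_attributes))
    draw_cohort <- function(mu0, gap) {
      X <- rbind(mvn_draw(n_el, mu0 + gap, Sigma), mvn_draw(n_no, mu0, Sigma))
      df <- as.data.frame(X)
      names(df) <- paste0("a", seq_len(n_attributes))
      df$class <- rep(c("elevated", "normal"), c(n_el, n_no))
      attribute_table(df, class_column = "class")
    }
    list(train = draw_cohort(rep(0, n_attributes), beta),
         matched = draw_cohort(rep(0, n_attributes), beta),
         mismatched = draw_cohort(shift, beta * separation_scale))
  })
}

#' Two classes with informative and pure-noise attributes
#'
#' Informative attributes separate the classes (means 0 vs 1.5, sd 0.5:
#' narrow, peaked distributions, like standardized summary statistics);
#' noise attributes are N(0, 1) identically in both classes and carry no
#' class information. The contrast in how much each attribute type
#' contributes to the likelihood is what the missingness-profiling workflow
#' detects.
#'
#' @param n_per_class Instances per class (default 500).
#' @param n_informative Number of informative attributes (default 5).
#' @param n_noise Number of noise attributes (default 3).
#' @param seed Integer seed.
#' @return A labeled [attribute_table()] with attributes `inf1..`/`noise1..`
#'   and classes `case`/`control`.
#' @export
gen_informative_noise <- function(n_per_class = 500L, n_informative = 5L,
                                  n_noise = 3L, seed = 1L) {
  if (n_per_class < 1L || n_informative < 1L || n_noise < 1L)
    aode_stop("validation", "all counts must be >= 1")
  with_seed(seed, {
    n <- 2L * n_per_class
    cls <- rep(c("case", "control"), each = n_per_class)
    inf_mu <- ifelse(cls == "case", 1.5, 0)
    Xi <- matrix(stats::rnorm(n * n_informative, inf_mu, 0.5), n, n_informative)
    Xn <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    df <- as.data.frame(cbind(Xi, Xn))
    names(df) <- c(paste0("inf", seq_len(n_informative)),
                   paste0("noise", seq_len(n_noise)))
    df$class <- cls
    attribute_table(df, class_column = "class")
  })
}

#' Inject missingness into an attribute table
#'
#' Three removal protocols, all deterministic given the seed:
#' \describe{
#'   \item{exact set}{`attributes` given — those cells become missing in
#'     every row;}
#'   \item{random subset}{`n_remove` and `from` given — each row loses
#'     `n_remove` attributes drawn (per row) from the candidate set `from`;}
#'   \item{random rate}{`rate` given — each cell is independently missing
#'     with that probability.}
#' }
#' A removal that would leave any row with zero present attributes is
#' rejected.
#'
#' @param table An [attribute_table()].
#' @param attributes Character vector: remove exactly these in every row.
#' @param n_remove,from Remove `n_remove` random attributes per row from the
#'   candidate set `from` (character vector).
#' @param rate Per-cell missingness probability in (0, 1).
#' @param seed Integer seed (used by the random protocols).
#' @return The table with additional missing cells.
#' @export
inject_missingness <- function(table, attributes = NULL, n_remove = NULL,
                               from = NULL, rate = NULL, seed = 1L) {
  stopifnot(inherits(table, "attribute_table"))
  X <- table$values
  p <- ncol(X)
  modes <- sum(!is.null(attributes), !is.null(n_remove), !is.null(rate))
  if (modes != 1L)
    aode_stop("validation",
              "specify exactly one of: attributes, n_remove (with from), rate")
  if (!is.null(attributes)) {
    bad <- setdiff(attributes, table$attribute_names)
    if (length(bad)) aode_stop("validation", "unknown attribute(s): ",
                               paste(bad, collapse = ", "))
    X[, attributes] <- NA_real_
  } else if (!is.null(n_remove)) {
    from <- from %||% table$attribute_names
    bad <- setdiff(from, table$attribute_names)
    if (length(bad)) aode_stop("validation", "unknown attribute(s): ",
                               paste(bad, collapse = ", "))
    if (n_remove > length(from))
      aode_stop("validation", "n_remove exceeds the candidate set size")
    cols <- match(from, table$attribute_names)
    X <- with_seed(seed, {
      for (r in seq_len(nrow(X)))
        X[r, sample(cols, n_remove)] <- NA_real_
      X
    })
  } else {
    if (!is_number(rate) || rate < 0 || rate >= 1)
      aode_stop("validation", "rate must be in [0, 1)")
    X <- with_seed(seed, {
      drop_mask <- matrix(stats::runif(length(X)) < rate, nrow(X), p)
      X[drop_mask] <- NA_real_
      X
    })
  }
  if (any(rowSums(!is.na(X)) == 0L))
    aode_stop("validation", "removal would leave at least one row with no present attributes")
  out <- table
  out$values <- X
  out
}
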