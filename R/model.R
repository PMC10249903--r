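MODEL_FORMAT_VERSION <- "aodesrs-model/1"

#' Training configuration
#'
#' @param max_components Maximum mixture components per density (BIC selects
#'   1..max_components); default 5.
#' @param min_samples Minimum training rows per class (and complete pairs per
#'   joint fit); default 10.
#' @param seed Integer seed recorded in the model.
#' @param standardize Standardize each attribute (training mean 0, sd 1,
#'   computed over present values) before fitting; the parameters are stored
#'   in the model and applied identically to application data. Off by
#'   default.
#' @param variance_floor Optional variance floor override (default
#'   `1e-8 * range^2` per attribute).
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_components = 5L, min_samples = 10L, seed = 1L,
                            standardize = FALSE, variance_floor = NULL) {
  if (max_components < 1L || min_samples < 1L)
    aode_stop("validation", "max_components and min_samples must be >= 1")
  structure(list(max_components = as.integer(max_components),
                 min_samples = as.integer(min_samples),
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 variance_floor = variance_floor),
            class = "training_config")
}

validate_priors <- function(priors, class_labels) {
  if (is.null(priors)) {
    priors <- rep(1 / length(class_labels), length(class_labels))
    names(priors) <- class_labels
    return(priors)
  }
  if (is.null(names(priors))) {
    if (length(priors) != length(class_labels))
      aode_stop("validation", "priors must be named or match the number of classes")
    names(priors) <- class_labels
  }
  if (!setequal(names(priors), class_labels))
    aode_stop("validation", "prior names must match class labels: ",
              paste(class_labels, collapse = ", "))
  priors <- priors[class_labels]
  if (any(!is.finite(priors)) || any(priors < 0))
    aode_stop("validation", "priors must be finite and non-negative")
  if (abs(sum(priors) - 1) > 1e-9)
    aode_stop("validation", "priors must sum to 1 (got ", sum(priors), ")")
  priors
}

new_aode_model <- function(attribute_names, classes, priors, standardization,
                           config) {
  m <- structure(
    list(format = MODEL_FORMAT_VERSION,
         attribute_names = attribute_names,
         classes = classes,
         priors = priors,
         standardization = standardization,
         config = config),
    class = "aode_model")
  m$fingerprint <- model_fingerprint(m)
  m
}

#' Train an AODE generative model
#'
#' Learns, for every class, a one-dimensional Gaussian-mixture marginal for
#' each attribute and a two-dimensional Gaussian-mixture joint for each
#' unordered attribute pair. Marginals use the present values of the
#' attribute within the class; joints use rows where both pair members are
#' present (no imputation). Component counts are selected by BIC up to
#' `config$max_components`.
#'
#' @param table A labeled [attribute_table()].
#' @param config A [training_config()].
#' @param priors Optional named class priors (default uniform); classification
#'   can override them per call.
#' @return An object of class `aode_model`.
#' @export
train_model <- function(table, config = training_config(), priors = NULL) {
  stopifnot(inherits(table, "attribute_table"), inherits(config, "training_config"))
  if (is.null(table$labels))
    aode_stop("training_data", "training table must carry class labels")
  attrs <- table$attribute_names
  labels <- sort(unique(table$labels))
  counts <- table(table$labels)
  low <- names(counts)[counts < config$min_samples]
  if (length(low))
    aode_stop("training_data", "class '", low[1L], "' has ", counts[low[1L]],
              " rows; at least ", config$min_samples, " required")
  X <- table$values
  std <- NULL
  if (config$standardize) {
    mu <- colMeans(X, na.rm = TRUE)
    sd_ <- apply(X, 2L, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sd_)) || any(sd_ == 0))
      aode_stop("degenerate_data", "cannot standardize an attribute with zero variance")
    std <- list(mean = mu, sd = sd_)
    X <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  }
  pairs <- attribute_pairs(length(attrs))
  classes <- lapply(labels, function(lb) {
    rows <- which(table$labels == lb)
    marginals <- lapply(seq_along(attrs), function(a) {
      v <- X[rows, a]
      v <- v[!is.na(v)]
      if (!length(v))
        aode_stop("training_data", "attribute '", attrs[a],
                  "' is entirely missing for class '", lb, "'")
      tryCatch(
        fit_gmm_1d(v, config$max_components, config$seed,
                   config$min_samples, config$variance_floor),
        aodesrs_training_data = function(e)
          aode_stop("training_data", "class '", lb, "', attribute '", attrs[a],
                    "': ", conditionMessage(e)))
    })
    names(marginals) <- attrs
    joints <- lapply(pairs, function(ab) {
      pr <- X[rows, ab, drop = FALSE]
      tryCatch(
        fit_gmm_2d(pr, config$max_components, config$seed,
                   config$min_samples, config$variance_floor,
                   attribute_pair = attrs[ab]),
        aodesrs_training_data = function(e)
          aode_stop("training_data", "class '", lb, "', pair (",
                    paste(attrs[ab], collapse = ", "), "): ", conditionMessage(e)))
    })
    names(joints) <- vapply(pairs, function(ab)
      paste(attrs[ab], collapse = ":"), character(1L))
    list(class_label = lb, marginals = marginals, joints = joints)
  })
  names(classes) <- labels
  new_aode_model(attrs, classes, validate_priors(priors, labels), std, config)
}

#' Build an exact AODE model from explicit Gaussian-mixture parameters
#'
#' Constructs a model whose densities equal stated closed forms, without any
#' fitting: each class is an n-dimensional Gaussian mixture, and the stored
#' marginals and pairwise joints are its (exact) univariate and bivariate
#' projections. Useful as an oracle for testing and for scoring under known
#' generative parameters.
#'
#' @param classes Named list (one entry per class label), each a list with
#'   `weights` (length k), `means` (k x p matrix, or vector for k = 1), and
#'   `covariances` (p x p x k array, or a single p x p matrix for k = 1; for
#'   p = 1 a vector of variances).
#' @param attribute_names Character vector of the p attribute names.
#' @param priors Optional named class priors (default uniform).
#' @return An object of class `aode_model`.
#' @examples
#' m <- build_model_from_parameters(
#'   classes = list(
#'     class1 = list(weights = 1, means = -1, covariances = 0.04),
#'     class2 = list(weights = 1, means = 1, covariances = 0.04)),
#'   attribute_names = "x")
#' @export
build_model_from_parameters <- function(classes, attribute_names,
                                        priors = NULL) {
  p <- length(attribute_names)
  if (is.null(names(classes)) || any(names(classes) == ""))
    aode_stop("validation", "classes must be a named list of class specs")
  labels <- names(classes)
  pairs <- attribute_pairs(p)
  built <- lapply(labels, function(lb) {
    spec <- classes[[lb]]
    w <- as.numeric(spec$weights)
    k <- length(w)
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-9)
      aode_stop("validation", "class '", lb,
                "': weights must be positive and sum to 1")
    means <- matrix(as.numeric(spec$means), nrow = k, ncol = p)
    covs <- array(as.numeric(spec$covariances), dim = c(p, p, k))
    for (i in seq_len(k)) {
      S <- covs[, , i]
      if (any(abs(S - t(S)) > 1e-12 * pmax(1, abs(S))))
        aode_stop("validation", "class '", lb, "': covariance ", i, " not symmetric")
      ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0)
        aode_stop("validation", "class '", lb, "': covariance ", i,
                  " not positive definite")
    }
    marginals <- lapply(seq_len(p), function(a)
      gmm1d(w, means[, a], covs[a, a, ]))
    names(marginals) <- attribute_names
    joints <- lapply(pairs, function(ab)
      gmm2d(w, means[, ab, drop = FALSE], covs[ab, ab, , drop = FALSE],
            attribute_pair = attribute_names[ab]))
    names(joints) <- vapply(pairs, function(ab)
      paste(attribute_names[ab], collapse = ":"), character(1L))
    list(class_label = lb, marginals = marginals, joints = joints)
  })
  names(built) <- labels
  new_aode_model(attribute_names, built, validate_priors(priors, labels),
                 NULL, training_config())
}

#' @export
print.aode_model <- function(x, ...) {
  p <- length(x$attribute_names)
  cat("AODE generative model:", length(x$classes), "class(es),", p,
      "attribute(s),", p * (p - 1L) / 2L, "joint(s) per class\n")
  cat("  classes:", paste(names(x$classes), collapse = ", "), "\n")
  cat("  priors:", paste(sprintf("%s=%.4g", names(x$priors), x$priors),
                         collapse = ", "), "\n")
  cat("  standardized:", !is.null(x$standardization), "\n")
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

# Canonical plain-list payload: the single source of truth for both the
# fingerprint and JSON serialization, so a save/load round trip preserves the
# fingerprint exactly.
model_payload <- function(model) {
  list(
    format = MODEL_FORMAT_VERSION,
    attribute_names = as.character(model$attribute_names),
    priors = as.numeric(model$priors),
    class_labels = as.character(names(model$classes)),
    standardization = if (!is.null(model$standardization)) list(
      mean = as.numeric(model$standardization$mean),
      sd = as.numeric(model$standardization$sd)),
    config = list(max_components = as.integer(model$config$max_components),
                  min_samples = as.integer(model$config$min_samples),
                  seed = as.integer(model$config$seed),
                  standardize = isTRUE(model$config$standardize)),
    classes = lapply(unname(model$classes), function(cm) list(
      class_label = cm$class_label,
      marginals = lapply(unname(cm$marginals), function(g) list(
        weights = as.numeric(g$weights), means = as.numeric(g$means),
        variances = as.numeric(g$variances))),
      joints = lapply(unname(cm$joints), function(g) list(
        attribute_pair = as.character(g$attribute_pair),
        weights = as.numeric(g$weights),
        means = lapply(seq_len(nrow(g$means)), function(i) as.numeric(g$means[i, ])),
        covariances = lapply(seq_len(g$n_components), function(i)
          lapply(1:2, function(r) as.numeric(g$covariances[r, , i]))))))))
}

#' Model fingerprint
#'
#' A hash of the model's full parameter payload. Result files embed it, and
#' diagnostic comparisons refuse to mix reliability scores produced under
#' different fingerprints: scores are only comparable within a single trained
#' model.
#'
#' @param model An `aode_model`.
#' @return Character hash.
#' @export
model_fingerprint <- function(model) {
  rlang::hash(model_payload(model))
}

#' Save / load an AODE model
#'
#' Models persist as a single versioned JSON document (UTF-8) with numbers at
#' full double precision; the round trip is lossless (identical densities and
#' fingerprint).
#'
#' @param model An `aode_model`.
#' @param path File path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aode_model"))
  # digits = I(17): 17 significant digits, the minimum guaranteeing an exact
  # double round trip
  jsonlite::write_json(model_payload(model), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) aode_stop("input", "model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) aode_stop("format", "malformed model file: ",
                                                conditionMessage(e)))
  if (!identical(doc$format, MODEL_FORMAT_VERSION))
    aode_stop("format", "unsupported model format version: ",
              doc$format %||% "<missing>")
  attrs <- as.character(unlist(doc$attribute_names))
  labels <- as.character(unlist(doc$class_labels))
  classes <- lapply(seq_along(labels), function(ci) {
    cd <- doc$classes[[ci]]
    marginals <- lapply(cd$marginals, function(g)
      gmm1d(unlist(g$weights), unlist(g$means), unlist(g$variances)))
    names(marginals) <- attrs
    joints <- lapply(cd$joints, function(g) {
      k <- length(g$weights)
      means <- do.call(rbind, lapply(g$means, unlist))
      covs <- array(0, c(2L, 2L, k))
      for (i in seq_len(k)) covs[, , i] <- do.call(rbind, lapply(g$covariances[[i]], unlist))
      gmm2d(unlist(g$weights), means, covs,
            attribute_pair = as.character(unlist(g$attribute_pair)))
    })
    if (length(joints)) names(joints) <- vapply(joints, function(j)
      paste(j$attribute_pair, collapse = ""), character(1L))
    list(class_label = cd$class_label, marginals = marginals, joints = joints)
  })
  names(classes) <- labels
  priors <- as.numeric(unlist(doc$priors))
  names(priors) <- labels
  std <- if (!is.null(doc$standardization)) {
    s <- list(mean = as.numeric(unlist(doc$standardization$mean)),
              sd = as.numeric(unlist(doc$standardization$sd)))
    names(s$mean) <- attrs; names(s$sd) <- attrs
    s
  }
  cfg <- training_config(max_components = doc$config$max_components,
                         min_samples = doc$config$min_samples,
                         seed = doc$config$seed,
                         standardize = isTRUE(doc$config$standardize))
  new_aode_model(attrs, classes, priors, std, cfg)
}
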