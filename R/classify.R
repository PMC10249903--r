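# Core likelihood evaluation. For each class the AODE estimator is
#
#   L(class | x) = sum over present attributes j of
#                  f(x_j | class) * prod over present i != j of f(x_i | x_j, class)
#
# evaluated entirely in log space. Missing attributes restrict both the outer
# sum and the inner products to the present set. With a single present
# attribute the product is empty and the term is the marginal density alone.

apply_standardization <- function(model, X) {
  if (is.null(model$standardization)) return(X)
  sweep(sweep(X, 2L, model$standardization$mean), 2L,
        model$standardization$sd, "/")
}

# log10 AODE likelihood of every row of X (n x p matrix, NA = missing) under
# one class model. Returns a vector; rows with zero present attributes get NA.
class_loglik_matrix <- function(class_model, X, attrs) {
  n <- nrow(X); p <- ncol(X)
  present <- !is.na(X)
  # M[r, j] = log10 f(x_j | class); NA where missing
  M <- matrix(NA_real_, n, p)
  for (a in seq_len(p)) {
    idx <- which(present[, a])
    if (length(idx))
      M[idx, a] <- log10_density_1d(class_model$marginals[[attrs[a]]], X[idx, a])
  }
  # A[r, j] = sum over present i != j of log10 f(x_i | x_j, class)
  A <- matrix(0, n, p)
  if (p >= 2L) {
    for (jt in class_model$joints) {
      a <- match(jt$attribute_pair[1L], attrs)
      b <- match(jt$attribute_pair[2L], attrs)
      idx <- which(present[, a] & present[, b])
      if (!length(idx)) next
      A[idx, b] <- A[idx, b] + cond_log10_density(jt, X[idx, a], X[idx, b], given = 2L)
      A[idx, a] <- A[idx, a] + cond_log10_density(jt, X[idx, b], X[idx, a], given = 1L)
    }
  }
  S <- (M + A) * LN10            # per-j terms in natural log
  ll <- row_logsumexp(S) / LN10  # log10 sum over present j
  ll[rowSums(present) == 0L] <- NA_real_
  ll
}

# n x n_classes matrix of log10 likelihoods for a whole table.
loglik_all_classes <- function(model, X) {
  X <- apply_standardization(model, X)
  cols <- lapply(model$classes, function(cm)
    class_loglik_matrix(cm, X, model$attribute_names))
  matrix(unlist(cols, use.names = FALSE), nrow = nrow(X),
         dimnames = list(NULL, names(model$classes)))
}

instance_to_matrix <- function(model, instance) {
  p <- length(model$attribute_names)
  if (!is.null(names(instance))) {
    if (!all(model$attribute_names %in% names(instance)))
      aode_stop("schema", "instance is missing attribute(s): ",
                paste(setdiff(model$attribute_names, names(instance)), collapse = ", "))
    instance <- instance[model$attribute_names]
  } else if (length(instance) != p) {
    aode_stop("schema", "instance has ", length(instance), " values; model expects ", p)
  }
  instance <- as.numeric(instance)
  if (any(!is.na(instance) & !is.finite(instance)))
    aode_stop("input", "present attribute values must be finite")
  matrix(instance, nrow = 1L)
}

#' log10 AODE likelihood of one instance under one class
#'
#' Sums, over the present attributes j, the product of j's marginal density
#' and the conditional densities of every other present attribute given j,
#' all under the named class; computed by log-sum-exp. Missing attributes are
#' simply left out of both the sum and the products.
#'
#' @param model An `aode_model`.
#' @param instance Numeric vector of attribute values (NA = missing), named
#'   or ordered as in `model$attribute_names`.
#' @param class_label Which class to evaluate.
#' @return log10 likelihood (a single number).
#' @export
class_log10_likelihood <- function(model, instance, class_label) {
  stopifnot(inherits(model, "aode_model"))
  if (!class_label %in% names(model$classes))
    aode_stop("lookup", "unknown class label '", class_label, "'")
  X <- instance_to_matrix(model, instance)
  if (all(is.na(X)))
    aode_stop("missing_data", "no attributes present; cannot evaluate the likelihood")
  Xs <- apply_standardization(model, X)
  class_loglik_matrix(model$classes[[class_label]], Xs, model$attribute_names)
}

posterior_from_loglik <- function(L10, priors) {
  # L10: n x C matrix of log10 likelihoods; priors: named, summing to 1.
  lp <- sweep(L10 * LN10, 2L, ifelse(priors > 0, log(priors), -Inf), "+")
  m <- suppressWarnings(apply(lp, 1L, max, na.rm = TRUE))
  w <- exp(lp - m)
  w[is.na(w)] <- 0
  sw <- rowSums(w)
  out <- w / sw
  out[!is.finite(m) | sw == 0, ] <- NA_real_
  out
}

#' Posterior class probabilities for one instance
#'
#' Prior-weighted AODE likelihoods normalized across classes, computed in log
#' space so extreme likelihood ratios remain stable. For two classes this is
#' the classic generative posterior; for more classes the same normalization
#' applies.
#'
#' @inheritParams class_log10_likelihood
#' @param priors Optional named prior per class (positive, sum to 1);
#'   defaults to the priors stored in the model.
#' @return Named probability vector summing to 1.
#' @export
posterior_probabilities <- function(model, instance, priors = NULL) {
  stopifnot(inherits(model, "aode_model"))
  priors <- validate_priors(priors %||% model$priors, names(model$classes))
  X <- instance_to_matrix(model, instance)
  if (all(is.na(X)))
    aode_stop("missing_data", "no attributes present; cannot classify")
  L10 <- loglik_all_classes(model, X)
  drop(posterior_from_loglik(L10, priors))
}

#' Reliability score (SRS) of an instance
#'
#' The log10 of the maximum AODE likelihood across classes: how well the
#' instance matches the best-fitting trained class, ignoring priors entirely.
#' Low values flag instances unlike anything seen in training — regardless of
#' how confident the posterior looks. With a single attribute the score
#' reduces to the maximum of the per-class log10 marginal densities. Scores
#' are comparable only among instances scored under the same trained model.
#'
#' @inheritParams class_log10_likelihood
#' @return log10 reliability score (a single number).
#' @export
srs <- function(model, instance) {
  stopifnot(inherits(model, "aode_model"))
  X <- instance_to_matrix(model, instance)
  if (all(is.na(X)))
    aode_stop("missing_data", "no attributes present; cannot compute a reliability score")
  max(loglik_all_classes(model, X), na.rm = TRUE)
}

#' Classify a table and score every instance
#'
#' Produces one record per row, in input order: the posterior probability of
#' each class, the reliability score (SRS), the number of present attributes,
#' and an abstention flag. Rows with zero present attributes abstain and get
#' no posteriors; when `srs_threshold` is given, rows scoring below it are
#' additionally flagged as abstained (their posteriors are still reported).
#'
#' @param model An `aode_model`.
#' @param table An [attribute_table()] whose attributes match the model's.
#' @param priors Optional named class priors (default: model priors).
#' @param srs_threshold Optional abstention threshold on the reliability
#'   score (may be -Inf/+Inf).
#' @return A data.frame of class `classification_records` with columns
#'   `prob_<class>`, `srs`, `n_present`, `abstained` (plus any table id
#'   columns), carrying the model fingerprint as an attribute.
#' @export
classify_table <- function(model, table, priors = NULL, srs_threshold = NULL) {
  stopifnot(inherits(model, "aode_model"), inherits(table, "attribute_table"))
  if (!setequal(table$attribute_names, model$attribute_names))
    aode_stop("schema", "table attributes do not match model attributes; expected: ",
              paste(model$attribute_names, collapse = ", "))
  X <- table$values[, model$attribute_names, drop = FALSE]
  priors <- validate_priors(priors %||% model$priors, names(model$classes))
  if (!is.null(srs_threshold) && !(is.numeric(srs_threshold) &&
                                   length(srs_threshold) == 1L && !is.na(srs_threshold)))
    aode_stop("validation", "srs_threshold must be a single numeric value")
  L10 <- loglik_all_classes(model, X)
  post <- posterior_from_loglik(L10, priors)
  srs_v <- suppressWarnings(apply(L10, 1L, max, na.rm = TRUE))
  n_present <- rowSums(!is.na(X))
  abstained <- n_present == 0L | !is.finite(srs_v)
  srs_v[n_present == 0L] <- NA_real_
  if (!is.null(srs_threshold))
    abstained <- abstained | (!is.na(srs_v) & srs_v < srs_threshold)
  post[n_present == 0L, ] <- NA_real_
  rec <- as.data.frame(post)
  names(rec) <- paste0("prob_", names(model$classes))
  rec$srs <- srs_v
  rec$n_present <- as.integer(n_present)
  rec$abstained <- abstained
  if (!is.null(table$ids)) rec <- cbind(table$ids, rec)
  structure(rec,
            class = c("classification_records", "data.frame"),
            fingerprint = model$fingerprint,
            class_labels = names(model$classes))
}

#' @export
print.classification_records <- function(x, ...) {
  cat("classification_records:", nrow(x), "instances,",
      sum(x$abstained), "abstained; model", attr(x, "fingerprint"), "\n")
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Write classification records as TSV
#'
#' Pass-through id columns first, then one posterior column per class, `srs`,
#' `n_present`, `abstained`. The model fingerprint is embedded as a
#' `#model=` comment line so downstream comparisons can verify that two
#' result files came from the same trained model. Missing values (abstained
#' rows) are written as `NA`; numbers carry 17 significant digits.
#'
#' @param records A `classification_records` data.frame.
#' @param path Output path.
#' @param timestamp Write a `#date=` comment line (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path, timestamp = TRUE) {
  stopifnot(inherits(records, "classification_records"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#model=", attr(records, "fingerprint")), con)
  if (timestamp) writeLines(paste0("#date=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  for (cn in names(df)[num]) df[[cn]] <- fmt_num(df[[cn]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read classification records written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return A `classification_records` data.frame with the embedded model
#'   fingerprint attached.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) aode_stop("input", "results file not found: ", path)
  hdr <- readLines(path, n = 5L)
  fp_line <- grep("^#model=", hdr, value = TRUE)
  fingerprint <- if (length(fp_line)) sub("^#model=", "", fp_line[1L]) else NA_character_
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("srs", "n_present", "abstained") %in% names(df)))
    aode_stop("format", "not a results file (missing srs/n_present/abstained columns): ",
              path)
  df$abstained <- as.logical(df$abstained)
  cls <- sub("^prob_", "", grep("^prob_", names(df), value = TRUE))
  structure(df, class = c("classification_records", "data.frame"),
            fingerprint = fingerprint, class_labels = cls)
}
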