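# Two-sample diagnostics on reliability scores, ROC against unknown-class
# scores, and missingness profiling.

new_shift_report <- function(method, statistic, p_value, group_sizes,
                             mean_srs, direction, extra = list()) {
  structure(c(list(method = method, statistic = statistic, p_value = p_value,
                   group_sizes = group_sizes, mean_srs = mean_srs,
                   direction = direction), extra),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat("Two-sample shift report (", x$method, ")\n", sep = "")
  cat(sprintf("  n = (%d, %d), mean = (%.6g, %.6g)\n",
              x$group_sizes[1L], x$group_sizes[2L], x$mean_srs[1L], x$mean_srs[2L]))
  cat(sprintf("  statistic = %.6g, two-sided p = %.6g\n", x$statistic, x$p_value))
  cat("  lower group:", x$direction, "\n")
  invisible(x)
}

# Exact permutation distribution of the midrank sum of sample A over all
# C(N, n) relabelings, by a subset-sum dynamic program over the pooled
# doubled midranks (doubling makes them integers under ties). Returns the
# exact two-sided p-value for the observed U (ties contribute 0.5 per pair).
exact_mw_p <- function(ranks2, n, U_obs) {
  maxS <- sum(ranks2)
  # f[k + 1, s + 1] = number of size-k subsets with doubled-midrank sum s
  f <- matrix(0, nrow = n + 1L, ncol = maxS + 1L)
  f[1L, 1L] <- 1
  for (w in ranks2) {
    for (k in seq(n, 1L)) {
      f[k + 1L, (w + 1L):(maxS + 1L)] <-
        f[k + 1L, (w + 1L):(maxS + 1L)] + f[k, 1L:(maxS + 1L - w)]
    }
  }
  counts <- f[n + 1L, ]
  U_all <- (seq_along(counts) - 1L) / 2 - n * (n + 1L) / 2
  total <- sum(counts)
  p_le <- sum(counts[U_all <= U_obs + 1e-9]) / total
  p_ge <- sum(counts[U_all >= U_obs - 1e-9]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs where a value of `sample_a` exceeds one of `sample_b`, with
#' 0.5 per tied pair. The p-value is exact (full enumeration of the
#' permutation distribution via a rank-sum recursion, ties included) when
#' `n * m <= 200`, otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param sample_a,sample_b Numeric vectors (each of length >= 2).
#' @return A `shift_report` with the U statistic, two-sided p-value, group
#'   sizes, group means and which group is lower.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    aode_stop("input", "each sample must contain at least 2 values")
  if (any(!is.finite(sample_a)) || any(!is.finite(sample_b)))
    aode_stop("input", "samples must be finite")
  n <- length(sample_a); m <- length(sample_b); N <- n + m
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                        # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1L) / 2
  if (n * m <= 200L) {
    p <- exact_mw_p(as.integer(round(2 * r)), n, U)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1L))
    sigma2 <- n * m / 12 * ((N + 1L) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- U - n * m / 2
      z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  dir <- if (mean(sample_a) < mean(sample_b)) "a" else
    if (mean(sample_b) < mean(sample_a)) "b" else "none"
  new_shift_report("mann_whitney", U, p, c(n, m),
                   c(mean(sample_a), mean(sample_b)), dir)
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors (each of length >= 2; at least
#'   one must have nonzero variance).
#' @return A `shift_report` (with a `df` field).
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    aode_stop("input", "each sample must contain at least 2 values")
  if (any(!is.finite(sample_a)) || any(!is.finite(sample_b)))
    aode_stop("input", "samples must be finite")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    aode_stop("degenerate_data", "both samples have zero variance")
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  dir <- if (mean(sample_a) < mean(sample_b)) "a" else
    if (mean(sample_b) < mean(sample_a)) "b" else "none"
  new_shift_report("welch_t", unname(tt$statistic), tt$p.value,
                   c(length(sample_a), length(sample_b)),
                   c(mean(sample_a), mean(sample_b)), dir,
                   extra = list(df = unname(tt$parameter)))
}

records_srs <- function(records) {
  stopifnot(inherits(records, "classification_records"))
  records$srs[!is.na(records$srs) & is.finite(records$srs)]
}

#' Test for a reliability-score shift between two scored cohorts
#'
#' Applies a two-sample test to the reliability scores of two record sets —
#' the "failing loudly" check for a systemic mismatch between the data a
#' model was trained on and the data it is applied to. Both record sets must
#' have been scored under the same trained model (fingerprints are compared);
#' scores from different models are not comparable.
#'
#' @param records_a,records_b `classification_records` scored under the same
#'   model.
#' @param method "welch_t" (default) or "mann_whitney".
#' @return A `shift_report`; `direction` names the lower cohort ("a"/"b").
#' @export
srs_shift_test <- function(records_a, records_b,
                           method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  fa <- attr(records_a, "fingerprint"); fb <- attr(records_b, "fingerprint")
  if (is.null(fa) || is.null(fb) || is.na(fa) || is.na(fb) || !identical(fa, fb))
    aode_stop("comparability",
              "records were scored under different models (fingerprints ",
              fa %||% "<none>", " vs ", fb %||% "<none>",
              "); reliability scores are only comparable within one trained model")
  a <- records_srs(records_a); b <- records_srs(records_b)
  if (identical(a, b)) {
    # a cohort against itself: no shift by definition
    return(new_shift_report(method, if (method == "welch_t") 0 else
      length(a)^2 / 2, 1, c(length(a), length(b)),
      c(mean(a), mean(b)), "none"))
  }
  if (method == "welch_t") welch_t(a, b) else mann_whitney_u(a, b)
}

#' ROC of reliability scores for separating known from unknown instances
#'
#' Sweeps a threshold over all distinct scores; the true-positive rate is the
#' fraction of known-class instances at or above the threshold and the
#' false-positive rate is the fraction of unknown-class instances at or
#' above it. The area under the curve (trapezoid rule) equals the
#' Mann-Whitney probability that a known instance outscores an unknown one
#' (ties counting one half); that identity is asserted internally.
#'
#' @param srs_known Scores of instances from classes present in training.
#' @param srs_unknown Scores of instances from the withheld/unknown class.
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
srs_roc_auc <- function(srs_known, srs_unknown) {
  srs_known <- as.numeric(srs_known); srs_unknown <- as.numeric(srs_unknown)
  if (!length(srs_known) || !length(srs_unknown))
    aode_stop("input", "both score sets must be nonempty")
  if (any(!is.finite(srs_known)) || any(!is.finite(srs_unknown)))
    aode_stop("input", "scores must be finite")
  th <- sort(unique(c(srs_known, srs_unknown)), decreasing = TRUE)
  th <- c(Inf, th, -Inf)
  tpr <- vapply(th, function(t) mean(srs_known >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(srs_unknown >= t), numeric(1L))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  # AUC / Mann-Whitney identity: auc == 1 - U(unknown vs known) / (n * m)
  n <- length(srs_unknown); m <- length(srs_known)
  r <- rank(c(srs_unknown, srs_known))
  U_unknown <- sum(r[seq_len(n)]) - n * (n + 1L) / 2
  stopifnot(abs(auc - (1 - U_unknown / (n * m))) < 1e-9)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds; AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Profile reliability scores by missing-attribute pattern
#'
#' Groups rows by their exact set of missing attributes and summarizes the
#' reliability score within each group, plus a per-attribute comparison of
#' mean score when the attribute is absent versus present. Instances missing
#' informative attributes score systematically lower than instances missing
#' uninformative ones, which makes this a principled basis for missingness
#' filters (rather than a blanket cap on the number of missing cells).
#' Group comparisons are most meaningful between groups with equal numbers of
#' missing attributes, since the score is a sum over present attributes.
#'
#' @param table The [attribute_table()] that was classified.
#' @param records The matching `classification_records` (same rows, same
#'   order).
#' @return An object of class `missingness_report`: `$patterns` (one row per
#'   distinct missing set: pattern, n_missing, count, mean_srs, sd_srs,
#'   ordered by mean_srs ascending) and `$attributes` (per attribute: counts
#'   and mean score when absent vs present).
#' @export
missingness_profile <- function(table, records) {
  stopifnot(inherits(table, "attribute_table"),
            inherits(records, "classification_records"))
  if (nrow(table$values) != nrow(records))
    aode_stop("input", "table (", nrow(table$values), " rows) and records (",
              nrow(records), " rows) are not aligned")
  miss <- is.na(table$values)
  pat <- apply(miss, 1L, function(r)
    if (!any(r)) "<none>" else paste(table$attribute_names[r], collapse = ","))
  s <- records$srs
  groups <- split(seq_along(pat), pat)
  patterns <- data.frame(
    pattern = names(groups),
    n_missing = vapply(groups, function(i) sum(miss[i[1L], ]), integer(1L)),
    count = lengths(groups),
    mean_srs = vapply(groups, function(i) mean(s[i], na.rm = TRUE), numeric(1L)),
    sd_srs = vapply(groups, function(i) stats::sd(s[i], na.rm = TRUE), numeric(1L)),
    row.names = NULL)
  patterns <- patterns[order(patterns$mean_srs), , drop = FALSE]
  rownames(patterns) <- NULL
  attributes <- data.frame(
    attribute = table$attribute_names,
    n_absent = colSums(miss),
    n_present = colSums(!miss),
    mean_srs_absent = vapply(seq_len(ncol(miss)), function(a)
      if (any(miss[, a])) mean(s[miss[, a]], na.rm = TRUE) else NA_real_, numeric(1L)),
    mean_srs_present = vapply(seq_len(ncol(miss)), function(a)
      if (any(!miss[, a])) mean(s[!miss[, a]], na.rm = TRUE) else NA_real_, numeric(1L)),
    row.names = NULL)
  stopifnot(sum(patterns$count) == nrow(records))
  structure(list(patterns = patterns, attributes = attributes),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("Missingness profile:", nrow(x$patterns), "distinct missing-attribute set(s)\n")
  print(utils::head(x$patterns, 12L))
  cat("Per-attribute mean reliability score (absent vs present):\n")
  print(x$attributes)
  invisible(x)
}

#' Flag low-reliability instances as abstained
#'
#' Marks a record abstained if its reliability score falls below the given
#' threshold (or if it was already abstained). There is no default
#' threshold: an appropriate cutoff depends on the application and must be
#' chosen with domain knowledge, e.g. from the score distribution of held-out
#' training-like data.
#'
#' @param records A `classification_records` data.frame.
#' @param srs_threshold Numeric threshold (-Inf and +Inf allowed).
#' @return The records with updated `abstained` flags; the number of newly
#'   abstained rows is attached as attribute `n_newly_abstained`.
#' @export
apply_abstention <- function(records, srs_threshold) {
  stopifnot(inherits(records, "classification_records"))
  if (!is.numeric(srs_threshold) || length(srs_threshold) != 1L || is.na(srs_threshold))
    aode_stop("validation", "srs_threshold must be a single numeric value")
  before <- records$abstained
  low <- !is.na(records$srs) & records$srs < srs_threshold
  records$abstained <- before | low
  attr(records, "n_newly_abstained") <- sum(records$abstained & !before)
  records
}
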