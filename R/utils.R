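# Internal helpers: classed errors, numerically stable log-sum-exp, seeding.

LN10 <- log(10)

# Classed condition so callers/tests can distinguish failure modes:
# classes used across the package: training_data, degenerate_data, input,
# validation, schema, format, lookup, missing_data, comparability, usage.
aode_stop <- function(class, ..., call. = FALSE) {
  msg <- paste0(...)
  stop(errorCondition(msg, class = c(paste0("aodesrs_", class), "aodesrs_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# log(sum(exp(x))) over a vector, -Inf-safe.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log(sum(exp())) over a matrix with possible NAs (missing entries
# are excluded); rows with no finite entry give -Inf.
row_logsumexp <- function(X) {
  m <- suppressWarnings(apply(X, 1L, max, na.rm = TRUE))
  m[!is.finite(m)] <- NA_real_
  s <- rowSums(exp(X - m), na.rm = TRUE)
  out <- m + log(s)
  out[is.na(m)] <- -Inf
  out
}

# Evaluate code under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  if (!is_number(seed)) aode_stop("validation", "seed must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unordered attribute index pairs as a list of length-2 vectors (empty for
# p < 2).
attribute_pairs <- function(p) {
  if (p < 2L) return(list())
  idx <- utils::combn(p, 2L)
  lapply(seq_len(ncol(idx)), function(i) idx[, i])
}
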