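# Shared fixtures: exact models built from known parameters, and the
# leave-one-class-out workflow used by the unknown-class tests.

# Two narrow single-Gaussian classes at -1 and +1 (sd 0.2) on one attribute.
exact_two_class_1d <- function() {
  build_model_from_parameters(
    classes = list(
      class1 = list(weights = 1, means = -1, covariances = 0.04),
      class2 = list(weights = 1, means = 1, covariances = 0.04)),
    attribute_names = "x")
}

# Single class, two independent standard-normal attributes.
exact_indep_2d <- function() {
  build_model_from_parameters(
    classes = list(A = list(weights = 1, means = c(0, 0), covariances = diag(2))),
    attribute_names = c("u", "v"))
}

# Single class, standard bivariate normal with correlation rho.
exact_corr_2d <- function(rho = 0.9) {
  S <- matrix(c(1, rho, rho, 1), 2L)
  build_model_from_parameters(
    classes = list(A = list(weights = 1, means = c(0, 0), covariances = S)),
    attribute_names = c("u", "v"))
}

# Two-class, three-attribute model with zero off-diagonal covariance, for the
# naive-Bayes-reduction checks.
exact_diag_3d <- function() {
  build_model_from_parameters(
    classes = list(
      A = list(weights = 1, means = c(0, 0, 0),
               covariances = diag(c(1, 2, 0.5))),
      B = list(weights = 1, means = c(1, -1, 0.5),
               covariances = diag(c(0.5, 1, 2)))),
    attribute_names = c("p", "q", "r"))
}

# Split a labeled table into per-class train/test halves (n_train rows of
# each class train, the rest test), train on all classes except `held_out`,
# classify the full test set; returns the test labels and records.
leave_one_class_out <- function(table, held_out, n_train = 35L, seed = 1L,
                                max_components = 2L) {
  d <- as.data.frame(table)
  idx <- split(seq_len(nrow(d)), table$labels)
  train_rows <- unlist(lapply(idx, function(i) i[seq_len(n_train)]))
  test_rows <- setdiff(seq_len(nrow(d)), train_rows)
  train <- attribute_table(d[setdiff(train_rows, idx[[held_out]]), ],
                           class_column = "class")
  test <- attribute_table(d[test_rows, ], class_column = "class")
  model <- train_model(train, training_config(max_components = max_components,
                                              seed = seed))
  list(records = classify_table(model, test), labels = test$labels,
       model = model)
}

# log10 SRS values split into known-class and held-out-class groups.
split_srs <- function(loco, held_out) {
  list(known = loco$records$srs[loco$labels != held_out],
       unknown = loco$records$srs[loco$labels == held_out])
}
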