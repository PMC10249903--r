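# Shift tests, ROC/AUC, missingness profiling, abstention.

# Brute-force two-sided Mann-Whitney p by enumerating every C(n+m, n)
# relabeling of the pooled sample (the independent oracle for the DP).
enumerate_mw_p <- function(a, b) {
  n <- length(a); pooled <- c(a, b); N <- length(pooled)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(N, n)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(U_all <= U_obs + 1e-9)
  p_ge <- mean(U_all >= U_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

test_that("Mann-Whitney: frozen small-sample cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2 * 1/20 over all C(6,3) labelings
  expect_identical(r$direction, "a")

  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  rt <- mann_whitney_u(c(1, 1), c(1, 1))
  expect_equal(rt$statistic, 2)  # four tied pairs at 0.5 each
  expect_equal(rt$p_value, 1)

  expect_error(mann_whitney_u(1, c(1, 2)), class = "aodesrs_input")
})

test_that("exact Mann-Whitney p agrees with full enumeration, ties included", {
  cases <- withr::with_seed(17, replicate(12, {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    list(a = sample(1:4, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE),
         b = sample(1:4, m, replace = TRUE))
  }, simplify = FALSE))
  for (cs in cases) {
    expect_equal(mann_whitney_u(cs$a, cs$b)$p_value, enumerate_mw_p(cs$a, cs$b),
                 tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney matches wilcox.test on tie-free samples", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      a <- rnorm(8); b <- rnorm(11, 0.5)
      ours <- mann_whitney_u(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("approximate Mann-Whitney matches the tie-corrected normal reference", {
  withr::with_seed(29, {
    a <- round(rnorm(40), 1); b <- round(rnorm(35, 0.4), 1)  # many ties
    ours <- mann_whitney_u(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("Welch t-test: identity, degeneracy, power", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(welch_t(rep(0, 4), rep(1, 4)), class = "aodesrs_degenerate_data")
  withr::with_seed(41, {
    r2 <- welch_t(rnorm(1000), rnorm(1000, 1))
    expect_lt(r2$p_value, 1e-10)
    expect_identical(r2$direction, "a")
  })
})

test_that("shift test enforces model comparability and detects shifts", {
  cohorts <- gen_cohort_shift(n_per_cohort = 200, shift = 1, seed = 13)
  m <- train_model(cohorts$train, training_config(max_components = 1, seed = 13))
  ra <- classify_table(m, cohorts$matched)
  rb <- classify_table(m, cohorts$mismatched)
  rep <- srs_shift_test(ra, rb, method = "welch_t")
  expect_identical(rep$direction, "b")  # mismatched cohort scores lower
  expect_lt(rep$p_value, 1e-3)

  # a cohort against itself is a null comparison by definition
  expect_equal(srs_shift_test(ra, ra)$p_value, 1)

  # records from different trained models must be refused
  m2 <- train_model(cohorts$matched, training_config(max_components = 1, seed = 13))
  rc <- classify_table(m2, cohorts$mismatched)
  expect_error(srs_shift_test(ra, rc), class = "aodesrs_comparability")
})

test_that("null cohorts give approximately uniform shift p-values", {
  ps <- vapply(1:60, function(seed) {
    cohorts <- gen_cohort_shift(n_per_cohort = 100, shift = 0,
                                separation_scale = 1, n_attributes = 5,
                                seed = 1000 + seed)
    m <- train_model(cohorts$train, training_config(max_components = 1, seed = seed))
    srs_shift_test(classify_table(m, cohorts$matched),
                   classify_table(m, cohorts$mismatched))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ROC: frozen cases and the Mann-Whitney/AUC identity", {
  expect_equal(srs_roc_auc(c(0.9, 0.8, 0.7), c(0.1, 0.2))$auc, 1)
  expect_equal(srs_roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  roc <- srs_roc_auc(c(3, 2), c(1, 2.5))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1 & roc$fpr >= 0 & roc$fpr <= 1))
  withr::with_seed(37, {
    for (rep in 1:8) {
      known <- round(rnorm(25), 1)  # rounding forces ties
      unknown <- round(rnorm(15, -0.5), 1)
      auc <- srs_roc_auc(known, unknown)$auc
      n <- length(unknown); m <- length(known)
      r <- rank(c(unknown, known))
      U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
      expect_equal(auc, 1 - U / (n * m), tolerance = 1e-9)
    }
  })
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    known <- rnorm(40, 1); unknown <- rnorm(30)
    auc <- srs_roc_auc(known, unknown)$auc
    ref <- pROC::auc(pROC::roc(
      response = rep(c(1, 0), c(40, 30)), predictor = c(known, unknown),
      quiet = TRUE, direction = "<"))
    expect_equal(auc, as.numeric(ref), tolerance = 1e-9)
  })
})

test_that("missingness profile partitions rows and ranks patterns", {
  tab <- gen_informative_noise(n_per_class = 50, seed = 19)
  m <- train_model(tab, training_config(max_components = 1, seed = 19))
  rec <- classify_table(m, tab)
  prof <- missingness_profile(tab, rec)
  expect_equal(nrow(prof$patterns), 1)
  expect_identical(prof$patterns$pattern, "<none>")
  expect_equal(prof$patterns$count, 100)

  # two disjoint patterns of sizes 40/60
  d <- as.data.frame(tab)
  d[1:40, "noise1"] <- NA
  d[41:100, "inf1"] <- NA
  tab2 <- attribute_table(d, class_column = "class")
  prof2 <- missingness_profile(tab2, classify_table(m, tab2))
  expect_setequal(prof2$patterns$count, c(40, 60))
  expect_equal(sum(prof2$patterns$count), 100)
  # group means ordered ascending
  expect_true(!is.unsorted(prof2$patterns$mean_srs))

  expect_error(missingness_profile(tab, rec[1:10, ]), class = "aodesrs_input")
})

test_that("missing informative attributes depress the score more than noise", {
  tab <- gen_informative_noise(n_per_class = 250, seed = 47)
  m <- train_model(tab, training_config(max_components = 1, seed = 47))
  test <- gen_informative_noise(n_per_class = 250, seed = 48)
  noise_rm <- inject_missingness(test, attributes = paste0("noise", 1:3))
  inf_rm <- inject_missingness(test, n_remove = 3, from = paste0("inf", 1:5),
                               seed = 49)
  r_noise <- classify_table(m, noise_rm)
  r_inf <- classify_table(m, inf_rm)
  expect_lt(mean(r_inf$srs), mean(r_noise$srs))
  expect_lt(welch_t(r_inf$srs, r_noise$srs)$p_value, 1e-3)
})

test_that("abstention thresholds behave as order statistics", {
  tab <- gen_1d_two_class(n_per_class = 20, seed = 3)
  m <- train_model(tab, training_config(seed = 3))
  rec <- classify_table(m, tab)
  expect_equal(attr(apply_abstention(rec, -Inf), "n_newly_abstained"), 0)
  all_out <- apply_abstention(rec, Inf)
  expect_true(all(all_out$abstained))
  ten <- rec[1:10, ]
  stopifnot(!anyDuplicated(ten$srs))
  thr <- median(ten$srs)
  expect_equal(sum(apply_abstention(ten, thr)$abstained), 5)
})
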