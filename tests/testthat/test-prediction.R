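rf_only <- function(seed = 1) {
  cv_config(families = "random_forest",
            grids = list(random_forest = data.frame(num_trees = 100, max_depth = 3)),
            seed = seed)
}

test_that("baseline closed forms: limits, errors, and large-sample convergence", {
  expect_error(baseline_performance(0), "strictly between")
  expect_error(baseline_performance(1), "strictly between")
  expect_error(baseline_performance(0.5, 0), "q must be")
  # r -> 1 limit: always-positive baseline F1 -> 100%
  expect_gt(baseline_table(1, 9999)$f1[2], 99.9)

  # law-of-large-numbers check: empirical metrics of simulated baseline
  # predictions converge to the closed forms
  set.seed(31)
  for (i in 1:25) {
    r <- runif(1, 0.1, 0.9); q <- runif(1, 0.2, 1)
    n <- 40000
    y <- rbinom(n, 1, r)
    b <- baseline_performance(r, q)
    pred1 <- rbinom(n, 1, q)                 # chance-level predictor
    prec1 <- sum(pred1 & y) / sum(pred1)
    rec1 <- sum(pred1 & y) / sum(y)
    expect_lt(abs(prec1 - b$precision[1]), 0.03)
    expect_lt(abs(rec1 - b$recall[1]), 0.03)
    expect_lt(abs(2 * prec1 * rec1 / (prec1 + rec1) - b$f1[1]), 0.03)
    prec2 <- sum(y) / n                      # always-positive predictor
    expect_lt(abs(prec2 - b$precision[2]), 0.03)
    expect_lt(abs(2 * prec2 / (prec2 + 1) - b$f1[2]), 0.03)
  }
})

test_that("rank AUC equals the Mann-Whitney statistic", {
  set.seed(32)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    pos <- round(rnorm(n1, 0.3), 2); neg <- round(rnorm(n0), 2)  # with ties
    y <- factor(c(rep("neg", n0), rep("pos", n1)), levels = c("neg", "pos"))
    w <- suppressWarnings(wilcox.test(pos, neg))$statistic
    expect_equal(compute_auc(c(neg, pos), y), unname(w) / (n0 * n1),
                 tolerance = 1e-12)
  }
  expect_true(is.na(compute_auc(1:5, factor(rep("pos", 5), levels = c("neg", "pos")))))
})

test_that("inverse-frequency weights balance the classes", {
  y <- factor(c(rep("neg", 30), rep("pos", 10)), levels = c("neg", "pos"))
  w <- seizREN:::inverse_class_weights(y)
  expect_equal(sum(w[y == "neg"]), sum(w[y == "pos"]))
  expect_equal(sum(w), length(y))
})

test_that("perfectly separable features give perfect fold metrics", {
  fl <- separable_features(n_pos = 30, n_neg = 30)
  rep <- run_task(fl, "next_seizure", rf_only())
  expect_true(all(rep$per_fold$auc == 1))
  expect_true(all(rep$per_fold$f1 == 1))
  expect_equal(rep$across_patients$auc_mean, 1)
})

test_that("evaluation is reproducible and seed-sensitive", {
  fl <- separable_features(n_pos = 25, n_neg = 25, sd = 3)  # overlapping classes
  r1 <- run_task(fl, "next_seizure", rf_only(seed = 7))
  r2 <- run_task(fl, "next_seizure", rf_only(seed = 7))
  expect_identical(r1$per_fold, r2$per_fold)
  r3 <- run_task(fl, "next_seizure", rf_only(seed = 8))
  expect_false(identical(r1$per_fold$auc, r3$per_fold$auc))
})

test_that("pure-noise features yield chance-level AUC (no optimistic leakage)", {
  set.seed(33)
  fl <- separable_features(n_pos = 100, n_neg = 100)
  for (col in feature_columns()) fl[[col]] <- rnorm(200)  # erase all signal
  rep <- run_task(fl, "next_seizure", rf_only(seed = 2))
  expect_lt(abs(rep$across_patients$auc_mean - 0.5), 0.12)
})

test_that("ineligible patients are skipped with a reason", {
  fl <- separable_features(n_pos = 4, n_neg = 30)
  expect_error(run_task(fl, "next_seizure", rf_only()), "no eligible patient")
  fl2 <- rbind(separable_features(n_pos = 20, n_neg = 20),
               separable_features(n_pos = 4, n_neg = 30, patient = "py", seed = 6))
  rep <- run_task(fl2, "next_seizure", rf_only())
  expect_equal(rep$excluded$patient_id, "py")
  expect_match(rep$excluded$reason, "below minimum")
  expect_equal(unique(rep$per_fold$patient_id), "px")
})

test_that("every model family runs through nested selection on a small table", {
  fl <- separable_features(n_pos = 20, n_neg = 20, sd = 1.5)
  small_grids <- list(
    logistic_regression = data.frame(lambda = c(0.001, 0.1)),
    svm_linear = data.frame(cost = c(0.1, 1)),
    knn = data.frame(k = c(3, 7)),
    decision_tree = data.frame(maxdepth = c(2, 5)),
    random_forest = data.frame(num_trees = 50, max_depth = c(3, 0)))
  cfg <- cv_config(families = names(small_grids), grids = small_grids, seed = 3)
  rep <- run_task(fl, "next_seizure", cfg)
  expect_setequal(unique(rep$per_fold$family), names(small_grids))
  ok <- is.finite(rep$per_fold$auc)
  expect_true(all(rep$per_fold$auc[ok] >= 0 & rep$per_fold$auc[ok] <= 1))
  # strong signal: every family beats chance comfortably
  expect_true(all(rep$across_patients$auc_mean > 0.8))
})

test_that("sample-size sweep: counts honored, full pool deterministic, caps warned", {
  fl <- separable_features(n_pos = 60, n_neg = 60, sd = 2)
  cfg <- cv_config(seed = 4)
  sw <- sample_size_sweep(fl, "next_seizure", cfg, sizes = 16,
                          size_type = "count", family = "decision_tree")
  expect_true(all(sw$per_rep$n_train == 16))

  sw_full <- sample_size_sweep(fl, "next_seizure", cfg, sizes = 1,
                               size_type = "fraction", family = "decision_tree")
  expect_equal(sw_full$summary$auc_sd, 0)  # single unique subset

  expect_warning(sample_size_sweep(fl, "next_seizure", cfg, sizes = 10000,
                                   size_type = "count", family = "decision_tree"),
                 "capped")
})

test_that("characteristic associations behave on degenerate and perfect inputs", {
  perf <- data.frame(patient_id = paste0("p", 1:8), auc = seq(0.5, 0.85, by = 0.05))
  chars <- data.frame(patient_id = paste0("p", 1:8),
                      age = 20:27,
                      sex = rep(c("m", "f"), 4),
                      zone = rep("temporal", 8))
  res <- characteristic_association(perf, chars)
  expect_equal(abs(res$estimate[res$variable == "age"]), 1)   # perfect ordering
  expect_false(res$testable[res$variable == "zone"])          # single level
  # identical AUC distribution in both groups: p = 1
  perf2 <- data.frame(patient_id = paste0("p", 1:8),
                      auc = rep(c(0.6, 0.7, 0.8, 0.9), 2))
  chars2 <- data.frame(patient_id = paste0("p", 1:8),
                       sex = rep(c("m", "f"), each = 4))
  res2 <- characteristic_association(perf2, chars2)
  expect_equal(res2$p[res2$variable == "sex"], 1)
})
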