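#' Cross-validation configuration for individualized prediction
#'
#' Individualized classifiers are evaluated with outer 5-fold stratified
#' cross-validation (80/20 train-test). Hyperparameters are selected per
#' outer fold by inner 5-fold stratified cross-validation on the training
#' portion only, maximizing mean validation AUC. Training samples are
#' weighted inversely proportional to class size.
#'
#' Default hyperparameter grids: logistic regression, ridge penalty over a
#' log grid; linear-kernel SVM, cost over a log grid; k-NN, k in
#' \{3, 5, 7, 11, 15\}; decision tree, max depth in \{2, 3, 5, 8, 30\};
#' random forest, trees in \{100, 300\} x max depth in \{3, 8, unlimited\}.
#'
#' @param outer_folds,inner_folds fold counts (>= 2).
#' @param families model families to evaluate.
#' @param grids named list of hyperparameter data.frames (one row per
#'   candidate); defaults above.
#' @param min_per_class patient eligibility threshold (10 per class).
#' @param seed integer seed controlling fold assignment and model fitting.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 5L,
                      families = c("logistic_regression", "svm_linear", "knn",
                                   "decision_tree", "random_forest"),
                      grids = default_grids(), min_per_class = 10L, seed = 1L) {
  outer_folds <- as.integer(outer_folds)
  inner_folds <- as.integer(inner_folds)
  if (outer_folds < 2L || inner_folds < 2L) stop("fold counts must be >= 2")
  families <- match.arg(families, several.ok = TRUE)
  if (!all(families %in% names(grids)) ||
      any(vapply(grids[families], nrow, integer(1)) == 0L))
    stop("grids must contain a nonempty data.frame for every family")
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 families = families, grids = grids,
                 min_per_class = as.integer(min_per_class),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Default hyperparameter grids
#' @return named list of data.frames, one per model family.
#' @export
default_grids <- function() {
  list(
    logistic_regression = data.frame(lambda = 10^seq(-4, 1, length.out = 6)),
    svm_linear = data.frame(cost = 10^(-2:2)),
    knn = data.frame(k = c(3, 5, 7, 11, 15)),
    decision_tree = data.frame(maxdepth = c(2, 3, 5, 8, 30)),
    random_forest = expand.grid(num_trees = c(100, 300), max_depth = c(3, 8, 0))
  )
}

default_params <- function(family) {
  switch(family,
         logistic_regression = list(lambda = 0.01),
         svm_linear = list(cost = 1),
         knn = list(k = 7),
         decision_tree = list(maxdepth = 8),
         random_forest = list(num_trees = 300, max_depth = 0),
         stop("unknown family: ", family))
}

# stratified k-fold assignment; returns list of test-index vectors
stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

inverse_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab[as.character(y)]))
  as.numeric(w)
}

#' Rank-based AUC of a score vector
#'
#' Area under the ROC curve via the Mann-Whitney rank statistic (tied scores
#' receive average ranks).
#'
#' @param scores numeric scores, larger = more positive.
#' @param y factor with levels `neg`, `pos`.
#' @return AUC in `[0, 1]`, or NA if either class is absent.
#' @export
compute_auc <- function(scores, y) {
  pos <- y == "pos"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

classification_metrics <- function(scores, y, threshold = 0.5) {
  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & y == "pos")
  fp <- sum(pred_pos & y == "neg")
  fn <- sum(!pred_pos & y == "pos")
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1,
    auc = compute_auc(scores, y))
}

# ---- model registry ---------------------------------------------------------

fit_model <- function(family, params, x, y, w, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # small weighted training folds provoke benign convergence/size warnings
  fit <- suppressWarnings(switch(
    family,
    logistic_regression = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0, lambda = params$lambda, weights = w),
    svm_linear = {
      cw <- table(y); cw <- length(y) / (length(cw) * cw)
      e1071::svm(x, y, kernel = "linear", cost = params$cost, scale = FALSE,
                 class.weights = cw)
    },
    knn = list(x = x, y = y, w = w, k = min(params$k, nrow(x))),
    decision_tree = {
      df <- data.frame(y = y, x)
      rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                   control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                  cp = 0.001, minsplit = 5L,
                                                  xval = 0L))
    },
    random_forest = ranger::ranger(
      x = x, y = y, probability = TRUE, num.trees = params$num_trees,
      max.depth = params$max_depth, case.weights = w, seed = seed,
      num.threads = 1L),
    stop("unknown family: ", family)
  ))
  list(family = family, fit = fit, params = params)
}

# positive-class score in [0, 1]; for the linear SVM the decision value is
# mapped through a logistic link so that score >= 0.5 coincides with the
# predicted class (deterministic, no internal Platt cross-validation)
predict_prob <- function(model, x) {
  fit <- model$fit
  switch(
    model$family,
    logistic_regression =
      as.numeric(predict(fit, newx = x, s = model$params$lambda, type = "response")),
    svm_linear = {
      dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
      sgn <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
      stats::plogis(sgn * as.numeric(dv[, 1]))
    },
    knn = {
      apply(x, 1L, function(row) {
        d <- sqrt(colSums((t(fit$x) - row)^2))
        nn <- order(d)[seq_len(fit$k)]
        sum(fit$w[nn] * (fit$y[nn] == "pos")) / sum(fit$w[nn])
      })
    },
    decision_tree = {
      pr <- predict(fit, newdata = data.frame(x), type = "prob")
      if ("pos" %in% colnames(pr)) pr[, "pos"] else rep(0, nrow(x))
    },
    random_forest = {
      pr <- predict(fit, data = x, num.threads = 1L)$predictions
      if ("pos" %in% colnames(pr)) pr[, "pos"] else rep(0, nrow(x))
    },
    stop("unknown family: ", model$family)
  )
}

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(apply = function(z) sweep(sweep(z, 2L, ctr), 2L, scl, "/"))
}

# inner-CV grid search: returns the grid row with highest mean validation AUC
select_params <- function(family, grid, x, y, cfg, seed) {
  folds <- stratified_folds(y, cfg$inner_folds, seed)
  mean_auc <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      if (length(val) == 0L || length(unique(y[val])) < 2L ||
          length(unique(y[-val])) < 2L) next
      std <- standardizer(x[-val, , drop = FALSE])
      xtr <- std$apply(x[-val, , drop = FALSE])
      xva <- std$apply(x[val, , drop = FALSE])
      w <- inverse_class_weights(y[-val])
      m <- fit_model(family, as.list(grid[g, , drop = FALSE]), xtr, y[-val], w,
                     derive_seed(seed, g, f))
      aucs <- c(aucs, compute_auc(predict_prob(m, xva), y[val]))
    }
    mean_auc[g] <- if (length(aucs)) mean(aucs, na.rm = TRUE) else NA_real_
  }
  if (all(is.na(mean_auc))) return(as.list(grid[1L, , drop = FALSE]))
  as.list(grid[which.max(mean_auc), , drop = FALSE])
}

#' Run an individualized prediction task
#'
#' Nested stratified cross-validation per patient: the outer 5 folds provide
#' the 80/20 train-test splits; hyperparameters are chosen per outer fold by
#' inner 5-fold cross-validation on the training portion (mean validation
#' AUC); the final per-fold model is fit with inverse-class-frequency sample
#' weights and evaluated on the held-out fold. Features are standardized with
#' statistics of the outer training portion. Patients with fewer than
#' `cfg$min_per_class` seizures in either class are skipped with a reason;
#' rows with any missing feature are dropped.
#'
#' @param features labeled feature table (10 REN features plus `category`,
#'   `is_cluster_first`).
#' @param task `"next_seizure"` or `"cluster_onset"`.
#' @param cfg a [cv_config()].
#' @param bands band table used to locate the feature columns.
#' @return object of class `eval_report`: list with `task`, `per_fold`
#'   (metrics per patient x family x fold, plus chosen hyperparameters),
#'   `per_patient` (cross-fold mean and SD), `across_patients` (unweighted
#'   mean over patients), and `excluded` (patients skipped, with reasons).
#' @export
run_task <- function(features, task = c("next_seizure", "cluster_onset"),
                     cfg = cv_config(), bands = band_specs()) {
  task <- match.arg(task)
  stopifnot(inherits(cfg, "cv_config"))
  feat_cols <- feature_columns(bands)
  if (!all(feat_cols %in% names(features)))
    stop("features must contain the 10 grand-average REN columns")
  per_fold <- list()
  excluded <- list()
  pids <- unique(features$patient_id)
  for (pi in seq_along(pids)) {
    pid <- pids[pi]
    fp <- features[features$patient_id == pid, , drop = FALSE]
    complete <- stats::complete.cases(fp[feat_cols])
    if (any(!complete))
      message(sprintf("run_task: patient %s: dropped %d row(s) with missing features",
                      pid, sum(!complete)))
    fp <- fp[complete, , drop = FALSE]
    tc <- task_classes(fp, task)
    tc <- tc[tc$included, , drop = FALSE]
    elig <- patient_eligible(fp, task, cfg$min_per_class)
    if (!elig$eligible) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(patient_id = pid, reason = elig$reason, stringsAsFactors = FALSE)
      next
    }
    x <- as.matrix(tc[feat_cols])
    y <- tc$class
    folds <- stratified_folds(y, cfg$outer_folds, derive_seed(cfg$seed, 11L, pi))
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      if (length(test) == 0L) next
      single_class_test <- length(unique(y[test])) < 2L
      std <- standardizer(x[-test, , drop = FALSE])
      xtr <- std$apply(x[-test, , drop = FALSE])
      xte <- std$apply(x[test, , drop = FALSE])
      w <- inverse_class_weights(y[-test])
      for (family in cfg$families) {
        params <- select_params(family, cfg$grids[[family]],
                                x[-test, , drop = FALSE], y[-test], cfg,
                                derive_seed(cfg$seed, 13L, pi, f))
        m <- fit_model(family, params, xtr, y[-test], w,
                       derive_seed(cfg$seed, 17L, pi, f))
        met <- classification_metrics(predict_prob(m, xte), y[test])
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          patient_id = pid, family = family, fold = f,
          precision = met["precision"], recall = met["recall"],
          f1 = met["f1"], auc = met["auc"],
          single_class_test = single_class_test,
          params = paste(names(params), unlist(params), sep = "=", collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  per_fold <- if (length(per_fold)) do.call(rbind, per_fold) else
    stop("no eligible patient for task ", task)
  rownames(per_fold) <- NULL
  metrics <- c("precision", "recall", "f1", "auc")
  per_patient <- do.call(rbind, lapply(split(per_fold, per_fold[c("patient_id", "family")], drop = TRUE),
    function(d) {
      out <- data.frame(patient_id = d$patient_id[1], family = d$family[1],
                        stringsAsFactors = FALSE)
      for (mname in metrics) {
        out[[paste0(mname, "_mean")]] <- mean(d[[mname]], na.rm = TRUE)
        out[[paste0(mname, "_sd")]] <- sd(d[[mname]], na.rm = TRUE)
      }
      out
    }))
  rownames(per_patient) <- NULL
  across <- do.call(rbind, lapply(split(per_patient, per_patient$family), function(d) {
    out <- data.frame(family = d$family[1], n_patients = nrow(d),
                      stringsAsFactors = FALSE)
    for (mname in metrics) {
      out[[paste0(mname, "_mean")]] <- mean(d[[paste0(mname, "_mean")]], na.rm = TRUE)
      out[[paste0(mname, "_sd")]] <- mean(d[[paste0(mname, "_sd")]], na.rm = TRUE)
    }
    out
  }))
  rownames(across) <- NULL
  structure(list(task = task, per_fold = per_fold, per_patient = per_patient,
                 across_patients = across,
                 excluded = if (length(excluded)) do.call(rbind, excluded) else
                   data.frame(patient_id = character(0), reason = character(0))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> task: %s (%d patient(s), %d excluded)\n",
              x$task, length(unique(x$per_patient$patient_id)), nrow(x$excluded)))
  print(x$across_patients, digits = 3)
  invisible(x)
}

# ---- analytic baselines -----------------------------------------------------

#' Closed-form baseline classifier performance
#'
#' Two analytic baselines for a binary task with positive-class prevalence
#' `r`: baseline 1 predicts the positive class with probability `q` (chance
#' level), baseline 2 always predicts positive. Both have precision `r`;
#' recall is `q` and 1 respectively; F1 is `2rq/(r+q)` and `2r/(r+1)`; AUC is
#' 0.5 for baseline 1 and undefined for baseline 2.
#'
#' @param r true positive-class prevalence, strictly between 0 and 1.
#' @param q baseline-1 prediction probability in (0, 1]; 0.5 by default.
#' @return data.frame with rows `baseline_1` and `baseline_2` and columns
#'   `precision`, `recall`, `f1`, `auc` (proportions in `[0, 1]`).
#' @examples
#' baseline_performance(648 / 676)  # baseline-2 F1 = 0.979
#' @export
baseline_performance <- function(r, q = 0.5) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 || r >= 1)
    stop("r must be strictly between 0 and 1 (degenerate class otherwise)")
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 1)
    stop("q must be in (0, 1]")
  data.frame(
    baseline = c("baseline_1", "baseline_2"),
    precision = c(r, r),
    recall = c(q, 1),
    f1 = c(2 * r * q / (r + q), 2 * r / (r + 1)),
    auc = c(0.5, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Baseline table from class sizes
#'
#' Convenience wrapper producing table-style percentages (rounded to one
#' decimal) from observed class sizes.
#'
#' @param n_neg,n_pos class sizes (negative, positive).
#' @param q baseline-1 prediction probability.
#' @return data.frame as [baseline_performance()] but in percent, rounded to
#'   one decimal, with the class sizes and prevalence attached.
#' @export
baseline_table <- function(n_neg, n_pos, q = 0.5) {
  r <- n_pos / (n_neg + n_pos)
  b <- baseline_performance(r, q)
  for (col in c("precision", "recall", "f1", "auc"))
    b[[col]] <- round(100 * b[[col]], 1)
  b$n_neg <- n_neg
  b$n_pos <- n_pos
  b$r <- r
  b
}

# ---- sample-size experiments ------------------------------------------------

#' Effect of training-set size on prediction performance
#'
#' Splits one patient's data into a fixed stratified 20% test set and an 80%
#' training pool, then trains on stratified subsamples of the pool —
#' either fractions of it (20...100%) or fixed counts (powers of two) — with
#' five repetitions per size, evaluating AUC on the same test set each time.
#'
#' @param features labeled feature table of a single patient.
#' @param task prediction task.
#' @param cfg a [cv_config()] (its seed controls the split and sampling).
#' @param sizes numeric vector: fractions in (0, 1] when
#'   `size_type = "fraction"`, sample counts when `size_type = "count"`
#'   (counts above the pool size are capped, with a warning).
#' @param size_type `"fraction"` or `"count"`.
#' @param family model family to train (default random forest with its
#'   default hyperparameters; no inner selection, so repetition scatter
#'   reflects sampling alone).
#' @param n_reps repetitions per size (5).
#' @param bands band table used to locate the feature columns.
#' @return list with `per_rep` (size, n_train, rep, auc) and `summary`
#'   (mean and SD AUC per size).
#' @export
sample_size_sweep <- function(features, task = c("next_seizure", "cluster_onset"),
                              cfg = cv_config(),
                              sizes = c(0.2, 0.4, 0.6, 0.8, 1.0),
                              size_type = c("fraction", "count"),
                              family = "random_forest", n_reps = 5L,
                              bands = band_specs()) {
  task <- match.arg(task)
  size_type <- match.arg(size_type)
  feat_cols <- feature_columns(bands)
  fp <- features[stats::complete.cases(features[feat_cols]), , drop = FALSE]
  tc <- task_classes(fp, task)
  tc <- tc[tc$included, , drop = FALSE]
  x <- as.matrix(tc[feat_cols])
  y <- tc$class
  # fixed stratified 20% test split
  folds <- stratified_folds(y, 5L, derive_seed(cfg$seed, 23L))
  test <- folds[[1L]]
  pool <- setdiff(seq_along(y), test)
  params <- default_params(family)
  rows <- list()
  for (si in seq_along(sizes)) {
    n_target <- if (size_type == "fraction") {
      if (sizes[si] <= 0 || sizes[si] > 1) stop("fractions must be in (0, 1]")
      round(sizes[si] * length(pool))
    } else {
      if (sizes[si] > length(pool)) {
        warning(sprintf("requested %d training samples but pool has %d; capped",
                        sizes[si], length(pool)))
        length(pool)
      } else as.integer(sizes[si])
    }
    for (rep_i in seq_len(n_reps)) {
      old <- .Random.seed_save()
      set.seed(derive_seed(cfg$seed, 29L, si, rep_i))
      if (n_target >= length(pool)) {
        tr <- pool
      } else {
        # stratified subsample, at least one per class
        tr <- unlist(lapply(levels(y), function(cl) {
          idx <- pool[y[pool] == cl]
          n_cl <- max(1L, round(n_target * length(idx) / length(pool)))
          sample(idx, min(n_cl, length(idx)))
        }))
      }
      .Random.seed_restore(old)
      if (length(unique(y[tr])) < 2L) next
      std <- standardizer(x[tr, , drop = FALSE])
      m <- fit_model(family, params, std$apply(x[tr, , drop = FALSE]), y[tr],
                     inverse_class_weights(y[tr]),
                     derive_seed(cfg$seed, 31L, si, rep_i))
      auc <- compute_auc(predict_prob(m, std$apply(x[test, , drop = FALSE])), y[test])
      rows[[length(rows) + 1L]] <- data.frame(
        size = sizes[si], n_train = length(tr), rep = rep_i, auc = auc)
    }
  }
  per_rep <- do.call(rbind, rows)
  rownames(per_rep) <- NULL
  summary <- do.call(rbind, lapply(split(per_rep, per_rep$size), function(d)
    data.frame(size = d$size[1], n_train = max(d$n_train),
               auc_mean = mean(d$auc, na.rm = TRUE),
               auc_sd = sd(d$auc, na.rm = TRUE))))
  summary <- summary[order(summary$size), , drop = FALSE]
  rownames(summary) <- NULL
  list(per_rep = per_rep, summary = summary)
}

#' Association between patient characteristics and prediction performance
#'
#' Compares per-patient AUC across groups defined by categorical
#' characteristics (Wilcoxon rank-sum for two groups, Kruskal-Wallis for
#' more) and rank-correlates AUC with continuous characteristics (Spearman).
#'
#' @param perf data.frame with `patient_id` and `auc`.
#' @param characteristics data.frame with `patient_id` and one column per
#'   characteristic.
#' @return data.frame with `variable`, `type`, `estimate` (rank correlation
#'   for continuous variables), `p`, and `testable`.
#' @export
characteristic_association <- function(perf, characteristics) {
  stopifnot(all(c("patient_id", "auc") %in% names(perf)))
  d <- merge(perf, characteristics, by = "patient_id")
  vars <- setdiff(names(characteristics), "patient_id")
  rows <- lapply(vars, function(v) {
    val <- d[[v]]
    if (is.numeric(val)) {
      if (length(unique(val)) < 2L)
        return(data.frame(variable = v, type = "continuous", estimate = NA_real_,
                          p = NA_real_, testable = FALSE))
      ct <- suppressWarnings(cor.test(d$auc, val, method = "spearman"))
      data.frame(variable = v, type = "continuous",
                 estimate = unname(ct$estimate), p = ct$p.value, testable = TRUE)
    } else {
      g <- factor(val)
      counts <- table(g)
      if (length(counts) < 2L || sum(counts >= 2L) < 2L)
        return(data.frame(variable = v, type = "categorical", estimate = NA_real_,
                          p = NA_real_, testable = FALSE))
      p <- if (length(counts) == 2L)
        suppressWarnings(wilcox.test(d$auc ~ g)$p.value)
      else kruskal.test(d$auc ~ g)$p.value
      data.frame(variable = v, type = "categorical", estimate = NA_real_,
                 p = p, testable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
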