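#' Classifier comparison under record-wise and patient-wise splits
#'
#' The same window dataset is evaluated under two train/test strategies:
#' record-wise (windows assigned to sides independently, stratified by label)
#' and patient-wise (whole patients assigned to one side, so no patient
#' leaks across the boundary). Cross-validation on the training side is
#' stratified K-fold for record-wise splits and group K-fold (folds grouped
#' by patient) for patient-wise splits. Metrics: accuracy, ROC-AUC from
#' predicted probabilities, recall, precision and F1 for the positive
#' (claudication) class at a 0.5 threshold.
#'
#' @name classify
NULL

#' Fixed-hyperparameter model registry
#'
#' Tree-ensemble classifiers with fixed, documented hyperparameters (no
#' automatic tuning): `xgboost` (depth-6 histogram gradient boosting),
#' `gbdt` (classic shallow stagewise gradient boosting, exact splits),
#' `random_forest` (500 trees), `extra_trees` (extremely randomized trees).
#'
#' @return named list of model definitions; each has `fit(X, y, seed)` and
#'   `predict_prob(fit, X)`.
#' @export
model_registry <- function() {
  xgb_def <- function(max_depth, eta, nrounds, tree_method) list(
    fit = function(X, y, seed) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, tree_method = tree_method, nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds,
        verbose = 0)
    },
    predict_prob = function(fit, X) stats::predict(fit, xgboost::xgb.DMatrix(X))
  )
  list(
    xgboost = xgb_def(max_depth = 6, eta = 0.1, nrounds = 200,
                      tree_method = "hist"),
    gbdt = xgb_def(max_depth = 3, eta = 0.05, nrounds = 300,
                   tree_method = "exact"),
    random_forest = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                   ntree = 500)
      },
      predict_prob = function(fit, X) stats::predict(fit, X, type = "prob")[, "1"]
    ),
    extra_trees = list(
      fit = function(X, y, seed) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
        ranger::ranger(y ~ ., data = df, num.trees = 500,
                       splitrule = "extratrees", probability = TRUE,
                       num.threads = 1, seed = seed)
      },
      predict_prob = function(fit, X) {
        stats::predict(fit, data.frame(X, check.names = FALSE),
                num.threads = 1)$predictions[, "1"]
      }
    )
  )
}

#' Record-wise train/test split
#'
#' Uniform random row split, stratified by label.
#'
#' @param ds a `window_dataset`.
#' @param test_frac test fraction.
#' @param seed RNG seed.
#' @return a `split_plan`: list with `strategy`, `train_indices`,
#'   `test_indices`, `seed`.
#' @export
split_records <- function(ds, test_frac = 0.2, seed = 1) {
  n <- nrow(ds$features)
  if (n < 10) stop("need at least 10 rows")
  if (length(unique(ds$labels)) < 2) stop("dataset has a single class")
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(ds$labels)) {
    idx <- which(ds$labels == cl)
    test <- c(test, sample(idx, round(test_frac * length(idx))))
  }
  test <- sort(test)
  structure(list(strategy = "record-wise",
                 train_indices = setdiff(seq_len(n), test),
                 test_indices = test, seed = seed),
            class = "split_plan")
}

#' Patient-wise train/test split
#'
#' Patients are assigned wholesale: patients are shuffled and accumulated
#' into the test side while doing so brings the realized test fraction
#' closer to `test_frac`.
#'
#' @inheritParams split_records
#' @export
split_patients <- function(ds, test_frac = 0.2, seed = 1) {
  n <- nrow(ds$features)
  pts <- unique(ds$patient_ids)
  if (length(pts) < 5) stop("need at least 5 patients")
  set.seed(seed)
  pts <- sample(pts)
  sizes <- vapply(pts, function(p) sum(ds$patient_ids == p), integer(1))
  test_pts <- character(0); cur <- 0
  for (i in seq_along(pts)) {
    if (abs((cur + sizes[i]) / n - test_frac) < abs(cur / n - test_frac)) {
      test_pts <- c(test_pts, pts[i]); cur <- cur + sizes[i]
    }
  }
  test <- which(ds$patient_ids %in% test_pts)
  structure(list(strategy = "patient-wise",
                 train_indices = setdiff(seq_len(n), test),
                 test_indices = test, seed = seed,
                 test_patients = test_pts),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n <- length(x$train_indices) + length(x$test_indices)
  cat(sprintf("<split_plan> %s: %d train / %d test (test fraction %.3f)\n",
              x$strategy, length(x$train_indices), length(x$test_indices),
              length(x$test_indices) / n))
  invisible(x)
}

#' Classification metrics from labels and probabilities
#'
#' @param y true 0/1 labels.
#' @param prob predicted positive-class probabilities.
#' @param threshold probability threshold for label metrics.
#' @return named numeric: accuracy, auc, recall, precision, f1. AUC is `NA`
#'   on a single-class set.
#' @export
classification_metrics <- function(y, prob, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auc <- if (length(unique(y)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  c(accuracy = mean(pred == y), auc = auc, recall = recall,
    precision = precision, f1 = f1)
}

# Stratified K-fold assignment (fold id per row).
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Group K-fold: whole groups to folds, balancing fold sizes greedily.
group_folds <- function(groups, k, seed) {
  set.seed(seed)
  gs <- sample(unique(groups))
  sizes <- vapply(gs, function(g) sum(groups == g), integer(1))
  ord <- order(sizes, decreasing = TRUE)
  load <- numeric(k)
  gfold <- integer(length(gs))
  for (i in ord) {
    f <- which.min(load)
    gfold[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  gfold[match(groups, gs)]
}

#' Cross-validated training of one registry model
#'
#' Stratified K-fold for record-wise plans, patient-grouped K-fold for
#' patient-wise plans. The model is refit per fold with the registry's fixed
#' hyperparameters.
#'
#' @param model_name a name from [model_registry()].
#' @param X feature matrix (training side).
#' @param y 0/1 labels.
#' @param groups patient ids (used for grouped folds), or `NULL`.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param grouped use patient-grouped folds?
#' @return list with `per_fold` (metric matrix) and `mean` (named vector).
#' @export
crossval_train <- function(model_name, X, y, groups = NULL, k = 10, seed = 1,
                           grouped = !is.null(groups)) {
  reg <- model_registry()
  if (!model_name %in% names(reg))
    stop("unknown model '", model_name, "'; registry: ",
         paste(names(reg), collapse = ", "))
  if (k > min(table(y))) stop("k exceeds the minority-class count")
  mdl <- reg[[model_name]]
  fold <- if (grouped) group_folds(groups, k, seed)
  else stratified_folds(y, k, seed)
  per_fold <- t(vapply(seq_len(k), function(f) {
    tr <- fold != f; va <- fold == f
    if (!any(va) || length(unique(y[tr])) < 2)
      return(rep(NA_real_, 5))
    fit <- mdl$fit(X[tr, , drop = FALSE], y[tr], seed = seed + f)
    classification_metrics(y[va], mdl$predict_prob(fit, X[va, , drop = FALSE]))
  }, numeric(5)))
  colnames(per_fold) <- c("accuracy", "auc", "recall", "precision", "f1")
  list(per_fold = per_fold, mean = colMeans(per_fold, na.rm = TRUE))
}

#' Fit on the training side and evaluate on the held-out side
#'
#' @param model_name a name from [model_registry()].
#' @param ds a `window_dataset`.
#' @param plan a `split_plan`.
#' @param seed RNG seed.
#' @return named metric vector on the test side.
#' @export
evaluate_model <- function(model_name, ds, plan, seed = 1) {
  reg <- model_registry()
  mdl <- reg[[model_name]]
  tr <- plan$train_indices; te <- plan$test_indices
  fit <- mdl$fit(ds$features[tr, , drop = FALSE], ds$labels[tr], seed = seed)
  classification_metrics(ds$labels[te],
                         mdl$predict_prob(fit, ds$features[te, , drop = FALSE]))
}

#' Compare registry models under one split plan
#'
#' Produces one train-CV row and one held-out-test row per model. In
#' patient-wise mode it asserts zero patient leakage between the sides and
#' between any training fold and its validation fold.
#'
#' @param ds a `window_dataset`.
#' @param plan a `split_plan`.
#' @param models character vector of registry names, or `"all"`.
#' @param k CV folds.
#' @param seed RNG seed.
#' @return data frame with columns `model`, `side` (`"train_cv"`/`"test"`),
#'   and the five metrics.
#' @export
compare_models <- function(ds, plan, models = "all", k = 10, seed = 1) {
  reg <- model_registry()
  if (identical(models, "all")) models <- names(reg)
  tr <- plan$train_indices; te <- plan$test_indices
  if (plan$strategy == "patient-wise") {
    leak <- intersect(unique(ds$patient_ids[tr]), unique(ds$patient_ids[te]))
    if (length(leak)) stop("patient leakage across the train/test boundary")
  }
  groups <- if (plan$strategy == "patient-wise") ds$patient_ids[tr] else NULL
  out <- lapply(models, function(m) {
    cv <- crossval_train(m, ds$features[tr, , drop = FALSE], ds$labels[tr],
                         groups = groups, k = k, seed = seed)
    tst <- evaluate_model(m, ds, plan, seed = seed)
    rbind(data.frame(model = m, side = "train_cv", t(cv$mean)),
          data.frame(model = m, side = "test", t(tst)))
  })
  do.call(rbind, out)
}
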