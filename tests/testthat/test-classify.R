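# Synthetic feature-level dataset helper: two Gaussian classes whose
# separation is controlled by `shift` (in units of the feature sd).
toy_dataset <- function(n = 600, p = 12, shift = 0, n_patients = 12,
                        seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[labels == 1, 1] <- X[labels == 1, 1] + shift
  colnames(X) <- paste0("f", seq_len(p))
  structure(list(features = X, labels = labels,
                 patient_ids = rep(sprintf("P%02d", seq_len(n_patients)),
                                   length.out = n),
                 trial_ids = rep("T1", n),
                 window_start_s = seq_len(n) * 5),
            class = "window_dataset")
}

test_that("classification metrics match a hand-computed confusion matrix", {
  y <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  prob <- c(rep(0.9, 40), rep(0.9, 10), rep(0.1, 20), rep(0.1, 30))
  m <- classification_metrics(y, prob)
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["precision"]], 0.8)
  expect_equal(m[["recall"]], 2 / 3)
  expect_equal(m[["f1"]], 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
})

test_that("perfect predictions score 1 on every metric", {
  y <- rep(0:1, 50)
  m <- classification_metrics(y, y * 0.98 + 0.01)
  expect_equal(unname(m), rep(1, 5))
})

test_that("F1 is the harmonic mean of precision and recall", {
  set.seed(61)
  for (i in 1:10) {
    y <- rbinom(200, 1, 0.5)
    prob <- runif(200)
    m <- classification_metrics(y, prob)
    expect_equal(m[["f1"]],
                 2 * m[["precision"]] * m[["recall"]] /
                   (m[["precision"]] + m[["recall"]]),
                 tolerance = 1e-9)
  }
})

test_that("record-wise splits are stratified, deterministic and 80/20", {
  ds <- toy_dataset(n = 100)
  plan <- split_records(ds, seed = 5)
  expect_length(plan$test_indices, 20)
  expect_length(plan$train_indices, 80)
  expect_identical(plan$test_indices, split_records(ds, seed = 5)$test_indices)
  expect_false(identical(plan$test_indices,
                         split_records(ds, seed = 6)$test_indices))
  p_tr <- mean(ds$labels[plan$train_indices])
  p_te <- mean(ds$labels[plan$test_indices])
  expect_lt(abs(p_tr - p_te), 0.02)
})

test_that("patient-wise splits never leak a patient across sides", {
  ds <- toy_dataset(n = 600, n_patients = 10)
  plan <- split_patients(ds, seed = 3)
  tr_p <- unique(ds$patient_ids[plan$train_indices])
  te_p <- unique(ds$patient_ids[plan$test_indices])
  expect_length(intersect(tr_p, te_p), 0)
  expect_length(te_p, 2)    # 10 equal-size patients at 20%
  expect_setequal(c(plan$train_indices, plan$test_indices), seq_len(600))

  ds4 <- toy_dataset(n = 40, n_patients = 4)
  expect_error(split_patients(ds4), "5 patients")
})

test_that("patient-wise test fraction approaches the target with unequal sizes", {
  set.seed(62)
  n <- 500
  sizes <- c(200, 120, 80, 50, 30, 20)
  ids <- rep(sprintf("P%d", seq_along(sizes)), times = sizes)
  ds <- toy_dataset(n = n)
  ds$patient_ids <- ids
  for (sd in 1:5) {
    plan <- split_patients(ds, seed = sd)
    frac <- length(plan$test_indices) / n
    # greedy accumulation cannot miss by more than the largest patient
    expect_lt(abs(frac - 0.2), max(sizes) / n)
    expect_length(intersect(unique(ids[plan$train_indices]),
                            unique(ids[plan$test_indices])), 0)
  }
})

test_that("an unknown model name lists the registry", {
  ds <- toy_dataset()
  expect_error(crossval_train("nonsense", ds$features, ds$labels, k = 5),
               "xgboost")
})

test_that("grouped cross-validation keeps patients within one fold", {
  groups <- rep(sprintf("P%d", 1:10), each = 30)
  fold <- claudigait:::group_folds(groups, k = 5, seed = 1)
  expect_true(all(tapply(fold, groups, function(f) length(unique(f))) == 1))
  expect_equal(sort(unique(fold)), 1:5)
})

test_that("strongly separable data is classified almost perfectly", {
  ds <- toy_dataset(shift = 5, seed = 7)
  plan <- split_records(ds, seed = 7)
  for (m in c("xgboost", "random_forest")) {
    metrics <- evaluate_model(m, ds, plan, seed = 7)
    expect_gte(metrics[["accuracy"]], 0.95)
  }
})

test_that("permuted labels give chance accuracy and AUC about one half", {
  ds <- toy_dataset(n = 600, shift = 0, seed = 8)
  plan <- split_records(ds, seed = 8)
  metrics <- evaluate_model("xgboost", ds, plan, seed = 8)
  expect_lt(abs(metrics[["accuracy"]] - 0.5), 0.1)
  expect_lt(abs(metrics[["auc"]] - 0.5), 0.1)
})

test_that("model comparison is bit-identical under a fixed seed", {
  ds <- toy_dataset(n = 200, shift = 2, seed = 9)
  plan <- split_records(ds, seed = 9)
  r1 <- compare_models(ds, plan, models = c("xgboost", "extra_trees"), k = 5,
                       seed = 11)
  r2 <- compare_models(ds, plan, models = c("xgboost", "extra_trees"), k = 5,
                       seed = 11)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4)   # one CV and one test row per model
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
})

test_that("cross-validation refuses more folds than minority cases", {
  ds <- toy_dataset(n = 30)
  expect_error(crossval_train("xgboost", ds$features, ds$labels, k = 20),
               "minority")
})
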