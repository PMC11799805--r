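test_that("stratified folds hold out the prescribed count per class", {
  labels <- rep(c("faculty", "trainee"), each = 55)
  folds <- stratified_folds(labels, k = 10, per_class_holdout = 5, seed = 1)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f, 10)
    expect_equal(sum(labels[f] == "faculty"), 5)
    expect_equal(sum(labels[f] == "trainee"), 5)
  }
  all_test <- unlist(folds)
  expect_equal(length(all_test), 100)        # disjoint
  expect_equal(length(unique(all_test)), 100)
  # exhaustive partition when the arithmetic tiles exactly
  lab2 <- rep(c("faculty", "trainee"), each = 10)
  f2 <- stratified_folds(lab2, k = 2, per_class_holdout = 5, seed = 3)
  expect_setequal(unlist(f2), 1:20)
  # determinism
  expect_identical(folds, stratified_folds(labels, 10, 5, seed = 1))
  expect_false(identical(folds, stratified_folds(labels, 10, 5, seed = 2)))
  # sizing error names the deficient class
  expect_error(stratified_folds(rep(c("faculty", "trainee"), c(4, 60)),
                                k = 2, per_class_holdout = 5),
               "faculty")
})

test_that("feature reduction fits on the training split only", {
  set.seed(8)
  train <- matrix(rnorm(200), 40, 5)
  test <- matrix(rnorm(50), 10, 5)
  # method none is the identity
  out <- reduce_features(train, test, fe_spec("none"))
  expect_identical(out$train, train)
  # variance mode keeps the fewest components reaching the target:
  # axis-aligned data with variance ratio 9:1 keeps one component at 50%
  tr2 <- cbind(a = rep(c(-3, -3, 3, 3), 5), b = rep(c(1, -1, -1, 1), 5))
  out2 <- reduce_features(tr2, tr2, fe_spec("pca", "variance",
                                            variance_target = 0.5))
  expect_equal(ncol(out2$train), 1)
  out99 <- reduce_features(tr2, tr2, fe_spec("pca", "variance",
                                             variance_target = 0.99))
  expect_equal(ncol(out99$train), 2)
  # the projection of the test split must not depend on the test rows
  red_a <- reduce_features(train, test, fe_spec("pca", "dims", dims = 2))
  red_b <- reduce_features(train, test[1:3, ], fe_spec("pca", "dims", dims = 2))
  expect_equal(red_a$test[1:3, ], red_b$test)
  # requesting more dimensions than available degrades with a warning
  expect_warning(reduce_features(tr2, tr2, fe_spec("pca", "dims", dims = 10)),
                 "available")
})

test_that("linear-kernel KPCA agrees with PCA up to component sign", {
  set.seed(12)
  train <- matrix(rnorm(120), 30, 4)
  pca <- reduce_features(train, train, fe_spec("pca", "dims", dims = 2))
  kp <- reduce_features(train, train,
                        fe_spec("kpca", "dims", dims = 2,
                                kernel = "vanilladot"))
  for (j in 1:2) {
    agree <- max(abs(kp$train[, j] - pca$train[, j]))
    flipped <- max(abs(kp$train[, j] + pca$train[, j]))
    expect_lt(min(agree, flipped), 1e-6)
  }
  # rbf KPCA at least produces the requested shape on train and test
  kr <- reduce_features(train, train[1:5, ], fe_spec("kpca", "dims", dims = 2))
  expect_equal(dim(kr$test), c(5, 2))
})

test_that("classification metrics match hand-computed confusion arithmetic", {
  # perfectly separated scores and predictions
  y <- rep(c("faculty", "trainee"), each = 4)
  m <- compute_metrics(y, c(1:4, 11:14) / 14, rep(c("faculty", "trainee"),
                                                  each = 4))
  expect_equal(unname(m), rep(1, 5))
  # all-tied scores give AUC 1/2
  expect_equal(compute_metrics(y, rep(0.5, 8),
                               rep("faculty", 8))[["auc"]], 0.5)
  # TP=3 FN=1 TN=4 FP=2
  y2 <- c(rep("trainee", 4), rep("faculty", 6))
  p2 <- c("trainee", "trainee", "trainee", "faculty",
          "trainee", "trainee", rep("faculty", 4))
  m2 <- compute_metrics(y2, runif(10), p2)
  expect_equal(m2[["sensitivity"]], 0.75)
  expect_equal(m2[["specificity"]], 2 / 3)
  expect_equal(m2[["accuracy"]], 0.7)
  expect_equal(m2[["f1"]], 2 * 3 / (2 * 3 + 2 + 1))
  # single-class truth: AUC undefined, the rest still returned
  expect_warning(m3 <- compute_metrics(rep("trainee", 4), runif(4),
                                       rep("trainee", 4)), "undefined")
  expect_true(is.na(m3[["auc"]]) && m3[["accuracy"]] == 1)
})

test_that("rank-based AUC equals the brute-force all-pairs oracle", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    y <- sample(c("faculty", "trainee"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    score <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    m <- suppressWarnings(compute_metrics(y, score, y))
    expect_equal(m[["auc"]], auc_bruteforce(y, score), tolerance = 1e-12)
  }
})

test_that("fold scoring recovers a separable problem and is deterministic", {
  set.seed(6)
  n <- 30
  y <- rep(c("faculty", "trainee"), each = n / 2)
  x <- cbind(rnorm(n, ifelse(y == "trainee", 3, -3), 0.5), rnorm(n))
  te <- c(1:5, 16:20); tr <- setdiff(1:n, te)
  m <- fit_and_score("lr", x[tr, ], y[tr], x[te, ], y[te], seed = 4)
  expect_equal(m[["auc"]], 1)
  expect_equal(m[["accuracy"]], 1)
  m2 <- fit_and_score("lr", x[tr, ], y[tr], x[te, ], y[te], seed = 4)
  expect_identical(m, m2)
  # 1-nearest-neighbour scored on its own training points is perfect
  knn1 <- classifier_spec("knn", grid = data.frame(k = 1))
  expect_equal(fit_and_score(knn1, x, y, x, y, seed = 1)[["accuracy"]], 1)
  # degenerate single-class training split is refused
  expect_error(fit_and_score("lr", x[1:10, ], y[1:10], x[te, ], y[te]),
               "one class")
})

test_that("gp and xgboost classifiers learn the separable fixture", {
  set.seed(60)
  n <- 40
  y <- rep(c("faculty", "trainee"), each = n / 2)
  x <- cbind(rnorm(n, ifelse(y == "trainee", 2.5, -2.5), 0.6), rnorm(n))
  te <- c(1:6, 21:26); tr <- setdiff(1:n, te)
  for (clf in c("gp", "xgboost")) {
    m <- fit_and_score(clf, x[tr, ], y[tr], x[te, ], y[te], seed = 2)
    expect_gte(m[["auc"]], 0.95)
  }
})

test_that("aggregation means lowest-level records and is order-invariant", {
  rec <- data.frame(device = "d", classifier = c("lr", "lr", "gp"),
                    data_type = "encoded", fe_method = "none",
                    grid = 5, t = 3, seed = 1, fold = c(1, 2, 1),
                    auc = c(0.8, 0.6, 0.9), f1 = c(0.7, 0.5, 0.8),
                    accuracy = 0.5, sensitivity = 0.5, specificity = 0.5)
  agg <- aggregate_records(rec, "classifier")
  expect_equal(agg$auc[agg$classifier == "lr"], 0.7)
  expect_equal(agg$auc_var[agg$classifier == "gp"], 0)  # singleton
  # permutation invariance
  agg_perm <- aggregate_records(rec[c(3, 1, 2), ], "classifier")
  expect_equal(agg, agg_perm)
  # aggregating to the full key reproduces each record
  full <- aggregate_records(rec, c("device", "classifier", "data_type",
                                   "fe_method", "grid", "t", "seed", "fold"))
  expect_equal(sort(full$auc), sort(rec$auc))
  expect_true(all(full$auc_var == 0))
})

test_that("best-configuration selection maximizes mean AUC with simplicity ties", {
  base <- expand.grid(grid = c(5, 10), t = c(3, 10),
                      fe_method = c("none", "pca_2d"),
                      stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    data.frame(device = "d", classifier = "lr", data_type = "encoded",
               base[rep(i, 2), ], seed = 1, fold = 1:2,
               auc = if (base$grid[i] == 10 && base$t[i] == 3 &&
                         base$fe_method[i] == "none") 0.9 else 0.8,
               f1 = 0.5, accuracy = 0.5, sensitivity = 0.5, specificity = 0.5,
               row.names = NULL)
  }))
  best <- select_best_config(rec, "lr")
  expect_equal(c(best$grid, best$t, best$fe_method), c("10", "3", "none"))
  # all-equal records fall back to the simplest configuration
  rec$auc <- 0.8
  tie <- select_best_config(rec, "lr")
  expect_equal(c(tie$grid, tie$t, tie$fe_method), c("5", "3", "none"))
  expect_error(select_best_config(rec, "gp"), "gp")
})

test_that("gain table subtracts traditional from encoded means in points", {
  rec <- expand.grid(device = c("eyelink_like", "tobii_like"),
                     data_type = c("encoded", "traditional"), fold = 1:2,
                     stringsAsFactors = FALSE)
  rec$classifier <- "lr"; rec$fe_method <- "none"
  rec$grid <- 0; rec$t <- 0; rec$seed <- 1
  rec$auc <- ifelse(rec$data_type == "encoded", 0.9, 0.8)
  rec$f1 <- rec$accuracy <- rec$sensitivity <- rec$specificity <- rec$auc
  g <- compare_gain(rec)
  expect_equal(nrow(g), 10)  # one row per device x metric
  expect_true(all(abs(g$gain_points - 10) < 1e-12))
  # identical tables give zero gain
  rec0 <- rec; rec0$auc[] <- 0.7
  rec0$f1 <- rec0$accuracy <- rec0$sensitivity <- rec0$specificity <- 0.7
  expect_true(all(compare_gain(rec0)$gain_points == 0))
  expect_error(compare_gain(rec[rec$data_type == "encoded", ]),
               "traditional")
})

test_that("the sweep emits one deterministic record per key combination", {
  ds <- small_benchmark_dataset(seed = 13)
  sw <- sweep_config(grid_sizes = 4, temporal_groups = 2,
                     data_types = "encoded", classifiers = "lr",
                     k_folds = 2, per_class_holdout = 5, seeds = 7L)
  rec <- run_sweep(ds, sw)
  expect_equal(nrow(rec), 2)  # one per fold
  expect_equal(unique(rec$grid), 4)
  expect_equal(unique(rec$t), 2)
  rec2 <- run_sweep(ds, sw)
  expect_equal(as.data.frame(rec), as.data.frame(rec2))
  # fold records reproduce a direct fit on the same split (no hidden state)
  enc <- encode_dataset(ds, encoding_config(4, t = 2))
  y <- factor(enc$label, levels = c("faculty", "trainee"))
  folds <- stratified_folds(y, k = 2, per_class_holdout = 5, seed = 7)
  te <- folds[[1]]; tr <- setdiff(seq_along(y), te)
  m <- fit_and_score("lr", enc$features[tr, ], y[tr], enc$features[te, ],
                     y[te], seed = 7 * 1000L + 1L * 10L + 1L)
  expect_equal(rec$auc[1], m[["auc"]])
  expect_equal(rec$f1[1], m[["f1"]])
})
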