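#' Classifier specification
#'
#' Names a classifier from the benchmark roster together with its
#' hyperparameter grid. Hyperparameters are tuned by inner stratified
#' cross-validation on the training split only, maximizing balanced accuracy
#' (mean of sensitivity and specificity); the model is then refit on the full
#' training split.
#'
#' Default grids:
#' * `knn` — neighbours `k` in {1, 3, 5, 7, 11};
#' * `lr` — logistic regression with ridge penalty, strength over 5
#'   log-spaced values `10^(-3..1)`;
#' * `xgboost` — depth {2, 3, 4} x rounds {50, 100, 200} x learning rate
#'   {0.1, 0.3};
#' * `gp` — Gaussian process classifier (Laplace approximation to the
#'   non-Gaussian posterior, as implemented by [kernlab::gausspr()]) with RBF
#'   kernel; the bandwidth is the median pairwise-distance heuristic scaled
#'   by a tuned factor in {0.25, 1, 4}.
#'
#' @param name one of `"gp"`, `"lr"`, `"knn"`, `"xgboost"`.
#' @param grid optional data frame / list overriding the default grid.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("gp", "lr", "knn", "xgboost"),
                            grid = NULL) {
  name <- match.arg(name)
  if (is.null(grid)) {
    grid <- switch(name,
      knn = data.frame(k = c(1, 3, 5, 7, 11)),
      lr = data.frame(lambda = 10^seq(-3, 1, length.out = 5)),
      xgboost = expand.grid(max_depth = c(2, 3, 4),
                            nrounds = c(50, 100, 200),
                            eta = c(0.1, 0.3)),
      gp = data.frame(sigma_scale = c(0.25, 1, 4)))
  }
  structure(list(name = name, grid = as.data.frame(grid)),
            class = "classifier_spec")
}

balanced_accuracy <- function(y_true, y_pred, positive = "trainee") {
  m <- compute_metrics(y_true, y_score = rep(0, length(y_true)),
                       y_pred = y_pred, positive = positive)
  unname((m["sensitivity"] + m["specificity"]) / 2)
}

# train on (x, y) with one hyperparameter row, predict scores for the trainee
# class and hard labels on xte; y is a factor with levels (faculty, trainee)
train_predict <- function(name, hyper, x, y, xte, seed) {
  lev <- levels(y)
  positive <- lev[2]
  if (name == "lr") {
    # small-n class-size warnings from glmnet are expected at inner-CV sizes
    fit <- suppressWarnings(glmnet::glmnet(x, y, family = "binomial",
                                           alpha = 0, lambda = hyper$lambda))
    score <- as.numeric(predict(fit, xte, type = "response",
                                s = hyper$lambda))
  } else if (name == "knn") {
    set.seed(seed)  # class::knn breaks exact distance ties at random
    pred <- class::knn(train = x, test = xte, cl = y, k = hyper$k,
                       prob = TRUE)
    p_win <- attr(pred, "prob")
    score <- ifelse(pred == positive, p_win, 1 - p_win)
    return(list(score = score,
                pred = factor(as.character(pred), levels = lev)))
  } else if (name == "gp") {
    sig <- median_heuristic_sigma(x) * hyper$sigma_scale
    fit <- kernlab::gausspr(x, y, kernel = "rbfdot", scaled = FALSE,
                            kpar = list(sigma = sig), type = "classification")
    pr <- kernlab::predict(fit, xte, type = "probabilities")
    score <- pr[, positive]
  } else if (name == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == positive))
    params <- list(objective = "binary:logistic",
                   max_depth = hyper$max_depth, eta = hyper$eta,
                   nthread = 1, seed = seed)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = hyper$nrounds, verbose = 0)
    score <- predict(fit, xgboost::xgb.DMatrix(xte))
  } else stop("unknown classifier: ", name, call. = FALSE)
  pred <- factor(ifelse(score > 0.5, lev[2], lev[1]), levels = lev)
  list(score = score, pred = pred)
}

# pick the grid row maximizing inner-CV balanced accuracy (first row wins
# ties); single-row grids skip the inner loop
tune_classifier <- function(spec, x, y, inner_k = 3, seed = 1) {
  grid <- spec$grid
  if (nrow(grid) <= 1) return(grid[1, , drop = FALSE])
  inner <- stratified_folds(y, k = inner_k, per_class_holdout = NULL,
                            seed = seed)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_along(inner), function(f) {
      te <- inner[[f]]; tr <- setdiff(seq_along(y), te)
      if (length(unique(y[tr])) < 2) return(NA_real_)
      out <- train_predict(spec$name, grid[g, , drop = FALSE],
                           x[tr, , drop = FALSE], y[tr],
                           x[te, , drop = FALSE], seed = seed + f)
      balanced_accuracy(y[te], out$pred)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(scores), , drop = FALSE]
}

#' Train, tune and score one classifier on one cross-validation fold
#'
#' Applies the full per-fold protocol: optional standardization (mean/sd
#' estimated on the training split), dimensionality reduction fitted on the
#' training split only, hyperparameter tuning by inner stratified CV on
#' balanced accuracy, refit on the whole training split, and metric
#' computation on the untouched test split.
#'
#' @param spec a [classifier_spec()] (or classifier name).
#' @param x_train,y_train,x_test,y_test fold data; `y` as factor or character
#'   with classes `faculty`/`trainee`.
#' @param fe an [fe_spec()]; default no reduction.
#' @param standardize center/scale features using training-split statistics.
#' @param inner_k inner folds used for tuning.
#' @param seed integer controlling tuning folds and stochastic learners.
#' @return Named numeric metric vector from [compute_metrics()].
#' @export
fit_and_score <- function(spec, x_train, y_train, x_test, y_test,
                          fe = fe_spec("none"), standardize = FALSE,
                          inner_k = 3, seed = 1) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  y_train <- factor(as.character(y_train), levels = expertise_levels)
  y_test <- factor(as.character(y_test), levels = expertise_levels)
  if (length(unique(y_train)) < 2) {
    stop("degenerate training split: only one class present", call. = FALSE)
  }
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (standardize) {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2, sd); sdv[sdv == 0] <- 1
    x_train <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
    x_test <- sweep(sweep(x_test, 2, mu), 2, sdv, "/")
  }
  red <- reduce_features(x_train, x_test, fe)
  best <- tune_classifier(spec, red$train, y_train, inner_k = inner_k,
                          seed = seed)
  out <- train_predict(spec$name, best, red$train, y_train, red$test,
                       seed = seed)
  compute_metrics(y_test, out$score, out$pred)
}
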