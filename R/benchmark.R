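#' Stratified cross-validation folds with fixed per-class hold-out
#'
#' Builds `k` disjoint test-index sets. With `per_class_holdout = h`, each
#' test set contains exactly `h` trials of each class, drawn without
#' replacement from a seeded shuffle; `k * h` trials per class are consumed,
#' any surplus trials never appear in a test set but stay in every fold's
#' training set. With `per_class_holdout = NULL` a plain stratified k-fold
#' partition is returned (each class split into `k` near-equal parts).
#'
#' @param labels class vector (character or factor).
#' @param k number of folds (>= 2).
#' @param per_class_holdout test-set size per class per fold, or `NULL`.
#' @param seed integer seed controlling the shuffle.
#' @return List of `k` integer vectors of test indices.
#' @export
stratified_folds <- function(labels, k = 10, per_class_holdout = 5, seed = 1) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in classes) {
    idx <- which(labels == cls)
    if (!is.null(per_class_holdout)) {
      need <- k * per_class_holdout
      if (length(idx) < need) {
        stop("sizing error: class '", cls, "' has ", length(idx),
             " members but ", need, " are required for ", k, " folds x ",
             per_class_holdout, " hold-outs", call. = FALSE)
      }
      chosen <- sample(idx, need)
      for (f in seq_len(k)) {
        take <- chosen[((f - 1) * per_class_holdout + 1):(f * per_class_holdout)]
        folds[[f]] <- c(folds[[f]], take)
      }
    } else {
      shuffled <- sample(idx)
      sizes <- diff(floor(seq(0, length(shuffled), length.out = k + 1)))
      start <- cumsum(c(1, head(sizes, -1)))
      for (f in seq_len(k)) {
        if (sizes[f] > 0) {
          folds[[f]] <- c(folds[[f]],
                          shuffled[start[f]:(start[f] + sizes[f] - 1)])
        }
      }
    }
  }
  lapply(folds, sort)
}

#' Specification of a dimensionality-reduction step
#'
#' @param method `"none"`, `"pca"` or `"kpca"`.
#' @param mode `"dims"` (keep exactly `dims` components) or `"variance"`
#'   (keep the smallest number of components whose cumulative explained
#'   variance — kernel-space eigenvalue fraction for kpca — reaches
#'   `variance_target`).
#' @param dims component count for `mode = "dims"` (the benchmark uses 2).
#' @param variance_target one of 0.50, 0.90, 0.99 conventionally.
#' @param kernel kpca kernel: `"rbfdot"` (default; bandwidth set by the
#'   median pairwise-distance heuristic on the training split) or
#'   `"vanilladot"` (linear).
#' @return An object of class `fe_spec`.
#' @export
fe_spec <- function(method = c("none", "pca", "kpca"),
                    mode = c("dims", "variance"),
                    dims = 2, variance_target = 0.9, kernel = "rbfdot") {
  method <- match.arg(method)
  mode <- match.arg(mode)
  structure(list(method = method, mode = mode, dims = dims,
                 variance_target = variance_target, kernel = kernel,
                 label = if (method == "none") "none" else {
                   paste0(method, "_", if (mode == "dims") paste0(dims, "d")
                          else paste0("v", round(100 * variance_target)))
                 }),
            class = "fe_spec")
}

#' Fit a dimensionality reduction on a training split and apply it
#'
#' The projection is fitted on `train` only and applied unchanged to `test`,
#' so no information leaks from the test split.
#'
#' @param train,test numeric matrices with identical columns.
#' @param spec an [fe_spec()].
#' @return List with `train` and `test` reduced matrices.
#' @export
reduce_features <- function(train, test, spec) {
  stopifnot(inherits(spec, "fe_spec"), nrow(train) > 0)
  if (spec$method == "none") return(list(train = train, test = test))
  if (spec$method == "pca") {
    pc <- prcomp(train, center = TRUE, scale. = FALSE)
    evar <- pc$sdev^2
    d <- n_components(spec, evar, max_d = ncol(pc$rotation))
    list(train = pc$x[, seq_len(d), drop = FALSE],
         test = predict(pc, test)[, seq_len(d), drop = FALSE])
  } else {
    kern <- if (spec$kernel == "vanilladot") {
      kernlab::vanilladot()
    } else {
      sig <- median_heuristic_sigma(train)
      kernlab::rbfdot(sigma = sig)
    }
    kp <- kernlab::kpca(train, kernel = kern, features = 0)
    evar <- kernlab::eig(kp)
    d <- n_components(spec, evar, max_d = ncol(kernlab::rotated(kp)))
    # kernlab returns projections inflated by sqrt(n) relative to the usual
    # principal-score convention; rescale so a linear kernel reproduces PCA
    s <- 1 / sqrt(nrow(train))
    tr <- kernlab::rotated(kp)[, seq_len(d), drop = FALSE] * s
    te <- kernlab::predict(kp, test)[, seq_len(d), drop = FALSE] * s
    list(train = tr, test = te)
  }
}

# smallest component count per spec, with a warning when dims exceed rank
n_components <- function(spec, evar, max_d) {
  if (spec$mode == "dims") {
    d <- spec$dims
    if (d > max_d) {
      warning("requested ", d, " components but only ", max_d,
              " available; using ", max_d, call. = FALSE)
      d <- max_d
    }
    max(1L, as.integer(d))
  } else {
    frac <- cumsum(evar) / sum(evar)
    max(1L, as.integer(which(frac >= spec$variance_target)[1]))
  }
}

# rbf bandwidth: kernlab's rbfdot uses exp(-sigma * ||x - y||^2); the median
# pairwise-distance heuristic sets sigma = 1 / (2 * median_dist^2)
median_heuristic_sigma <- function(x, max_n = 200) {
  n <- nrow(x)
  if (n > max_n) x <- x[seq(1, n, length.out = max_n), , drop = FALSE]
  d <- stats::dist(x)
  m <- median(d[d > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m^2)
}

#' Binary classification metrics
#'
#' Computes AUC, F1, accuracy, sensitivity and specificity with the trainee
#' class as positive: sensitivity is recall on trainees, specificity recall
#' on faculty, and F1 is computed on the trainee class. AUC uses the rank
#' (Mann-Whitney) statistic with tied scores counted 1/2 — the probability
#' that a random trainee trial scores above a random faculty trial.
#'
#' @param y_true true labels (`"faculty"`/`"trainee"`).
#' @param y_score numeric scores for the trainee class.
#' @param y_pred predicted labels.
#' @param positive the positive class (default `"trainee"`).
#' @return Named numeric vector `auc, f1, accuracy, sensitivity, specificity`
#'   (all in `[0, 1]`). If only one class is present in `y_true` the AUC is
#'   undefined and returned as `NA` with a warning.
#' @export
compute_metrics <- function(y_true, y_score, y_pred, positive = "trainee") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  pos <- y_true == positive
  npos <- sum(pos); nneg <- sum(!pos)
  auc <- if (npos == 0 || nneg == 0) {
    warning("AUC undefined: only one class present in y_true", call. = FALSE)
    NA_real_
  } else {
    r <- rank(y_score)  # midranks: ties counted 1/2
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  tp <- sum(pos & y_pred == positive)
  fn <- sum(pos & y_pred != positive)
  tn <- sum(!pos & y_pred != positive)
  fp <- sum(!pos & y_pred == positive)
  sens <- if (npos > 0) tp / npos else NA_real_
  spec <- if (nneg > 0) tn / nneg else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  acc <- (tp + tn) / length(y_true)
  c(auc = auc, f1 = f1, accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Aggregate metric records to a level of granularity
#'
#' Means (and variances) are always computed directly over the lowest-level
#' records sharing the level key — never by re-averaging already-averaged
#' values — so the result is independent of record order and of intermediate
#' groupings.
#'
#' @param records a metric-record data frame as returned by [run_sweep()].
#' @param level character vector of key columns to aggregate to (subset of
#'   `device, classifier, data_type, fe_method, grid, t, seed, fold`).
#' @return Data frame with one row per level key and, for each metric, a
#'   `<metric>` mean column and a `<metric>_var` variance column (variance 0
#'   for singleton groups).
#' @export
aggregate_records <- function(records, level) {
  metric_cols <- c("auc", "f1", "accuracy", "sensitivity", "specificity")
  stopifnot(all(level %in% names(records)), all(metric_cols %in% names(records)))
  if (nrow(records) == 0) {
    return(records[, c(level, metric_cols), drop = FALSE])
  }
  records <- as.data.frame(records)
  key <- interaction(records[level], drop = TRUE, lex.order = TRUE)
  out <- unique(records[level])
  out <- out[order(interaction(out[level], drop = TRUE, lex.order = TRUE)), ,
             drop = FALSE]
  rownames(out) <- NULL
  for (m in metric_cols) {
    mu <- tapply(records[[m]], key, mean)
    va <- tapply(records[[m]], key, function(v) {
      if (length(v) < 2) 0 else var(v)
    })
    out[[m]] <- as.numeric(mu)
    out[[paste0(m, "_var")]] <- as.numeric(va)
  }
  out
}

#' Best encoding configuration per classifier
#'
#' Among encoded-data records of one classifier, finds the
#' `(grid, t, fe_method)` configuration with the highest mean AUC over seeds
#' and folds. Ties prefer the simpler model: smaller grid, then smaller `t`,
#' then `fe_method = "none"` first.
#'
#' @param records a metric-record data frame.
#' @param classifier classifier name to select for.
#' @return One-row data frame with `grid`, `t`, `fe_method` and `auc`.
#' @export
select_best_config <- function(records, classifier) {
  sub <- records[records$classifier == classifier &
                 records$data_type == "encoded", , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no encoded records for classifier '", classifier, "'",
         call. = FALSE)
  }
  agg <- aggregate_records(sub, c("grid", "t", "fe_method"))
  fe_rank <- ifelse(agg$fe_method == "none", 0L, 1L)
  ord <- order(-agg$auc, agg$grid, agg$t, fe_rank, agg$fe_method)
  agg[ord[1], c("grid", "t", "fe_method", "auc"), drop = FALSE]
}

#' Encoded-vs-traditional performance gain
#'
#' For each device and metric: mean over encoded records minus mean over
#' traditional records, in absolute percentage points (x100).
#'
#' @param records a metric-record data frame containing both data types.
#' @return Data frame with columns `device`, `metric`, `encoded_mean`,
#'   `traditional_mean`, `gain_points`.
#' @export
compare_gain <- function(records) {
  for (dt in c("encoded", "traditional")) {
    if (!any(records$data_type == dt)) {
      stop("comparison error: no '", dt, "' records present", call. = FALSE)
    }
  }
  metric_cols <- c("auc", "f1", "accuracy", "sensitivity", "specificity")
  out <- do.call(rbind, lapply(unique(records$device), function(dev) {
    sub <- records[records$device == dev, , drop = FALSE]
    do.call(rbind, lapply(metric_cols, function(m) {
      enc <- mean(sub[[m]][sub$data_type == "encoded"])
      trad <- mean(sub[[m]][sub$data_type == "traditional"])
      data.frame(device = dev, metric = m, encoded_mean = enc,
                 traditional_mean = trad,
                 gain_points = 100 * (enc - trad),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
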