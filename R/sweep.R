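#' Configuration of the benchmarking sweep
#'
#' Describes the full-factorial evaluation: for encoded features, every
#' combination of square grid size and temporal-group count; for traditional
#' features, the five-column baseline; each crossed with the
#' dimensionality-reduction variants and classifiers, under stratified
#' k-fold cross-validation regenerated per seed.
#'
#' @param grid_sizes square grid subdivisions for the encoder (default
#'   `c(5, 7, 10, 15)`).
#' @param temporal_groups temporal-group counts (default `c(3, 5, 10, 20)`).
#' @param data_types subset of `c("encoded", "traditional")`.
#' @param fe_specs list of [fe_spec()] reduction variants (default: none).
#' @param classifiers character names or [classifier_spec()] objects
#'   (default all four: gp, lr, knn, xgboost).
#' @param k_folds folds per seed (default 10).
#' @param per_class_holdout trials per class in each test set (default 5),
#'   or `NULL` for a plain stratified partition.
#' @param seeds integer vector; folds are regenerated for each seed and the
#'   seed is part of every record's key.
#' @param binning temporal binning mode for the encoder.
#' @param standardize_encoded,standardize_traditional per-fold
#'   standardization switches. Encoded counts are used raw by default; the
#'   five traditional features live on incommensurate scales and are
#'   standardized by default.
#' @param loc_grid_size location grid for the regressive-fixation feature.
#' @param inner_k inner folds for hyperparameter tuning.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(grid_sizes = c(5, 7, 10, 15),
                         temporal_groups = c(3, 5, 10, 20),
                         data_types = c("encoded", "traditional"),
                         fe_specs = list(fe_spec("none")),
                         classifiers = c("gp", "lr", "knn", "xgboost"),
                         k_folds = 10, per_class_holdout = 5, seeds = 1L,
                         binning = c("time", "count"),
                         standardize_encoded = FALSE,
                         standardize_traditional = TRUE,
                         loc_grid_size = 5, inner_k = 3) {
  binning <- match.arg(binning)
  data_types <- match.arg(data_types, several.ok = TRUE)
  classifiers <- lapply(classifiers, function(cl) {
    if (is.character(cl)) classifier_spec(cl) else cl
  })
  stopifnot(length(grid_sizes) > 0, length(temporal_groups) > 0,
            length(classifiers) > 0, length(fe_specs) > 0, k_folds >= 2)
  structure(list(grid_sizes = grid_sizes, temporal_groups = temporal_groups,
                 data_types = data_types, fe_specs = fe_specs,
                 classifiers = classifiers, k_folds = k_folds,
                 per_class_holdout = per_class_holdout,
                 seeds = as.integer(seeds), binning = binning,
                 standardize_encoded = standardize_encoded,
                 standardize_traditional = standardize_traditional,
                 loc_grid_size = loc_grid_size, inner_k = inner_k),
            class = "sweep_config")
}

#' Run the cross-validated benchmarking sweep
#'
#' Produces one metric record per
#' `data_type x fe x grid x t x classifier x seed x fold` combination
#' (grid and t apply to encoded rows only; traditional rows carry the
#' sentinel `grid = t = 0`). Records are deterministic given the sweep seeds.
#'
#' @param ds a [gaze_dataset()].
#' @param sweep a [sweep_config()].
#' @return An object of class `gaze_benchmark`: a data frame with key columns
#'   `device, classifier, data_type, fe_method, grid, t, seed, fold` and
#'   metric columns `auc, f1, accuracy, sensitivity, specificity`.
#' @export
run_sweep <- function(ds, sweep = sweep_config()) {
  stopifnot(inherits(ds, "gaze_dataset"), inherits(sweep, "sweep_config"))
  val <- validate_dataset(ds)
  if (!val$geometry_ok || !val$participant_class_ok) {
    stop("dataset failed validation: ", paste(val$issues, collapse = "; "),
         call. = FALSE)
  }
  y <- factor(dataset_labels(ds), levels = expertise_levels)

  # feature sets: one per encoding configuration + one traditional baseline
  feature_sets <- list()
  if ("encoded" %in% sweep$data_types) {
    for (g in sweep$grid_sizes) {
      for (tt in sweep$temporal_groups) {
        cfg <- encoding_config(grid_x = g, t = tt, binning = sweep$binning)
        feature_sets[[length(feature_sets) + 1]] <-
          list(data_type = "encoded", grid = g, t = tt,
               x = encode_dataset(ds, cfg)$features,
               standardize = sweep$standardize_encoded)
      }
    }
  }
  if ("traditional" %in% sweep$data_types) {
    feature_sets[[length(feature_sets) + 1]] <-
      list(data_type = "traditional", grid = 0, t = 0,
           x = extract_traditional(ds, loc_grid_size = sweep$loc_grid_size)$features,
           standardize = sweep$standardize_traditional)
  }

  rows <- list()
  for (seed in sweep$seeds) {
    folds <- stratified_folds(y, k = sweep$k_folds,
                              per_class_holdout = sweep$per_class_holdout,
                              seed = seed)
    for (fs in feature_sets) {
      for (fe in sweep$fe_specs) {
        for (ci in seq_along(sweep$classifiers)) {
          spec <- sweep$classifiers[[ci]]
          for (f in seq_along(folds)) {
            te <- folds[[f]]; tr <- setdiff(seq_along(y), te)
            m <- tryCatch(
              fit_and_score(spec, fs$x[tr, , drop = FALSE], y[tr],
                            fs$x[te, , drop = FALSE], y[te], fe = fe,
                            standardize = fs$standardize,
                            inner_k = sweep$inner_k,
                            seed = seed * 1000L + f * 10L + ci),
              error = function(e) {
                stop("sweep cell failed (", fs$data_type, ", fe=", fe$label,
                     ", grid=", fs$grid, ", t=", fs$t, ", ", spec$name,
                     ", seed=", seed, ", fold=", f, "): ",
                     conditionMessage(e), call. = FALSE)
              })
            rows[[length(rows) + 1]] <- data.frame(
              device = ds$device, classifier = spec$name,
              data_type = fs$data_type, fe_method = fe$label,
              grid = fs$grid, t = fs$t, seed = seed, fold = f,
              auc = m[["auc"]], f1 = m[["f1"]], accuracy = m[["accuracy"]],
              sensitivity = m[["sensitivity"]],
              specificity = m[["specificity"]], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  class(records) <- c("gaze_benchmark", "data.frame")
  records
}

#' @export
print.gaze_benchmark <- function(x, ...) {
  cat(sprintf("<gaze_benchmark> %d records: %d classifier(s), %d seed(s), %s\n",
              nrow(x), length(unique(x$classifier)), length(unique(x$seed)),
              paste(unique(x$data_type), collapse = " + ")))
  NextMethod()
}

#' @export
summary.gaze_benchmark <- function(object, ...) {
  agg <- aggregate_records(object, c("classifier", "data_type", "fe_method"))
  cat("Mean metrics by classifier, data type and feature extraction:\n")
  print(agg[, c("classifier", "data_type", "fe_method", "auc", "f1",
                "accuracy", "sensitivity", "specificity")], digits = 3)
  invisible(agg)
}
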