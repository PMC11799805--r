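#' @keywords internal
expertise_levels <- c("faculty", "trainee")

#' Construct a single scanpath trial
#'
#' A trial is one ordered fixation sequence produced by one participant on one
#' displayed image, together with the display geometry and the participant's
#' expertise label. Fixations are stored as a data frame with columns `x`, `y`
#' (pixels, origin top-left, y downward), `onset`, `duration` (seconds) and
#' `valid` (logical artifact flag). On construction the fixations are stably
#' sorted by onset, so ties keep their input order.
#'
#' @param trial_id,participant_id opaque identifiers (coerced to character).
#' @param label expertise class, `"faculty"` or `"trainee"`.
#' @param display_w,display_h display extent in pixels (> 0).
#' @param fixations data frame with columns `x`, `y`, `onset`, `duration` and
#'   optionally `valid` (defaults to `TRUE`).
#' @return An object of class `gaze_trial`.
#' @export
gaze_trial <- function(trial_id, participant_id, label, display_w, display_h,
                       fixations = empty_fixations()) {
  if (!label %in% expertise_levels) {
    stop("unknown expertise label '", label, "': must be one of ",
         paste(expertise_levels, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(display_w) || !is.numeric(display_h) ||
      display_w <= 0 || display_h <= 0) {
    stop("display_w and display_h must be positive", call. = FALSE)
  }
  fx <- as.data.frame(fixations)
  if (is.null(fx$valid)) fx$valid <- rep(TRUE, nrow(fx))
  required <- c("x", "y", "onset", "duration", "valid")
  missing_cols <- setdiff(required, names(fx))
  if (length(missing_cols)) {
    stop("fixations missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fx <- fx[required]
  if (nrow(fx)) {
    if (any(fx$onset < 0)) stop("fixation onsets must be >= 0", call. = FALSE)
    if (any(fx$duration < 0)) stop("fixation durations must be >= 0", call. = FALSE)
    fx <- fx[order(fx$onset), , drop = FALSE]  # stable: ties keep file order
    rownames(fx) <- NULL
  }
  structure(
    list(trial_id = as.character(trial_id),
         participant_id = as.character(participant_id),
         label = label,
         display_w = as.numeric(display_w), display_h = as.numeric(display_h),
         fixations = fx),
    class = "gaze_trial"
  )
}

empty_fixations <- function() {
  data.frame(x = numeric(0), y = numeric(0), onset = numeric(0),
             duration = numeric(0), valid = logical(0))
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf("<gaze_trial %s> participant %s (%s), %d fixations, %gx%g px\n",
              x$trial_id, x$participant_id, x$label, nrow(x$fixations),
              x$display_w, x$display_h))
  invisible(x)
}

#' Construct a gaze dataset
#'
#' Bundles trials recorded with one device into a dataset. All trials must
#' share the same display geometry; each participant must carry a single
#' expertise label throughout.
#'
#' @param trials list of [gaze_trial()] objects.
#' @param device acquisition tag: `"eyelink_like"` (pre-filtered fixations),
#'   `"tobii_like"` (raw gaze ingested as fixations) or `"other"`.
#' @param check enforce the invariants at construction time (default). With
#'   `check = FALSE` an inconsistent dataset can be built so that
#'   [validate_dataset()] can report on it.
#' @return An object of class `gaze_dataset`.
#' @export
gaze_dataset <- function(trials = list(), device = "other", check = TRUE) {
  device <- match.arg(device, c("eyelink_like", "tobii_like", "other"))
  stopifnot(all(vapply(trials, inherits, logical(1), "gaze_trial")))
  if (check && length(trials)) {
    geoms <- unique(t(vapply(trials, function(tr) c(tr$display_w, tr$display_h),
                             numeric(2))))
    if (nrow(geoms) > 1L) {
      stop("mixed display geometries within one dataset", call. = FALSE)
    }
    pl <- unique(data.frame(
      participant = vapply(trials, `[[`, character(1), "participant_id"),
      label = vapply(trials, `[[`, character(1), "label")))
    if (anyDuplicated(pl$participant)) {
      stop("participant(s) mapped to more than one expertise class: ",
           paste(pl$participant[duplicated(pl$participant)], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(device = device, trials = trials), class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<gaze_dataset> device=%s, %d trials (%d faculty / %d trainee)\n",
              x$device, length(x$trials),
              sum(labs == "faculty"), sum(labs == "trainee")))
  invisible(x)
}

#' @export
length.gaze_dataset <- function(x) length(x$trials)

dataset_labels <- function(ds) {
  vapply(ds$trials, `[[`, character(1), "label")
}

dataset_geometry <- function(ds) {
  if (!length(ds$trials)) return(c(w = NA_real_, h = NA_real_))
  c(w = ds$trials[[1]]$display_w, h = ds$trials[[1]]$display_h)
}

#' Default column mapping for fixation tables
#'
#' Describes how CSV columns map onto the fixation schema and which time unit
#' the file uses. The default matches the schema written by
#' [write_fixation_table()]:
#' `trial_id,participant_id,label,x,y,onset_s,duration_s,valid`.
#'
#' @param trial,participant,label,x,y,onset,duration,valid column names in the
#'   file; `valid` is optional in the file and defaults to all-valid.
#' @param time_unit `"s"` or `"ms"`; onsets/durations are converted to
#'   seconds on read.
#' @return A list usable as the `dialect` argument of [read_fixation_table()].
#' @export
fixation_dialect <- function(trial = "trial_id", participant = "participant_id",
                             label = "label", x = "x", y = "y",
                             onset = "onset_s", duration = "duration_s",
                             valid = "valid", time_unit = c("s", "ms")) {
  list(columns = c(trial = trial, participant = participant, label = label,
                   x = x, y = y, onset = onset, duration = duration,
                   valid = valid),
       time_unit = match.arg(time_unit))
}

#' Read a delimited fixation table into a gaze dataset
#'
#' Reads a UTF-8 CSV with a header row, one row per fixation, groups rows by
#' trial (trials appear in order of first occurrence) and sorts fixations by
#' onset within each trial (stable for ties). Times are converted to seconds
#' according to the dialect's `time_unit`.
#'
#' @param path path to the CSV file.
#' @param dialect column mapping from [fixation_dialect()].
#' @param display_w,display_h display extent in pixels shared by all trials
#'   (the file format does not carry geometry).
#' @param device acquisition tag stored on the dataset.
#' @return A [gaze_dataset()].
#' @export
read_fixation_table <- function(path, dialect = fixation_dialect(),
                                display_w = 1920, display_h = 1080,
                                device = "other") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- dialect$columns
  required <- setdiff(names(cols), "valid")
  for (role in required) {
    if (!cols[[role]] %in% names(raw)) {
      stop("schema error: required column '", cols[[role]], "' (", role,
           ") not found in ", path, call. = FALSE)
    }
  }
  num_col <- function(role) {
    v <- raw[[cols[[role]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad)) {
      stop("parse error: non-numeric value '", v[bad[1]], "' in column '",
           cols[[role]], "' at data row ", bad[1], call. = FALSE)
    }
    out
  }
  scale <- if (dialect$time_unit == "ms") 1e-3 else 1
  d <- data.frame(
    trial = as.character(raw[[cols[["trial"]]]]),
    participant = as.character(raw[[cols[["participant"]]]]),
    label = as.character(raw[[cols[["label"]]]]),
    x = num_col("x"), y = num_col("y"),
    onset = num_col("onset") * scale, duration = num_col("duration") * scale,
    stringsAsFactors = FALSE)
  d$valid <- if (cols[["valid"]] %in% names(raw)) {
    as.logical(as.integer(raw[[cols[["valid"]]]]))
  } else rep(TRUE, nrow(d))
  bad_lab <- setdiff(unique(d$label), expertise_levels)
  if (length(bad_lab)) {
    stop("label error: unknown expertise label(s) ",
         paste(sQuote(bad_lab), collapse = ", "), call. = FALSE)
  }
  trial_ids <- unique(d$trial)  # order of first occurrence
  trials <- lapply(trial_ids, function(id) {
    rows <- d[d$trial == id, , drop = FALSE]
    gaze_trial(id, rows$participant[1], rows$label[1], display_w, display_h,
               rows[c("x", "y", "onset", "duration", "valid")])
  })
  gaze_dataset(trials, device = device)
}

#' Write a gaze dataset as a fixation CSV
#'
#' Writes the default schema
#' `trial_id,participant_id,label,x,y,onset_s,duration_s,valid` (seconds,
#' `valid` as 0/1). [read_fixation_table()] on the result round-trips the
#' dataset field-for-field (given the same display geometry).
#'
#' @param ds a [gaze_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(ds, path) {
  rows <- lapply(ds$trials, function(tr) {
    fx <- tr$fixations
    data.frame(trial_id = rep(tr$trial_id, nrow(fx)),
               participant_id = rep(tr$participant_id, nrow(fx)),
               label = rep(tr$label, nrow(fx)),
               x = fx$x, y = fx$y, onset_s = fx$onset, duration_s = fx$duration,
               valid = as.integer(fx$valid), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(trial_id = character(0), participant_id = character(0),
                      label = character(0), x = numeric(0), y = numeric(0),
                      onset_s = numeric(0), duration_s = numeric(0),
                      valid = integer(0))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove artifact fixations from a trial
#'
#' Drops fixations flagged invalid (`valid == FALSE`) and fixations falling
#' outside the display rectangle grown by `margin` pixels on every side,
#' i.e. outside `[-margin, display_w + margin] x [-margin, display_h + margin]`.
#' The surviving fixations keep their order; the input trial is not modified.
#' Applying the filter twice gives the same result as applying it once.
#'
#' @param trial a [gaze_trial()].
#' @param margin non-negative tolerance in pixels around the display edge.
#' @return A filtered copy of the trial. If every fixation is removed the
#'   trial is returned empty with a warning.
#' @export
filter_artifacts <- function(trial, margin = 0) {
  stopifnot(inherits(trial, "gaze_trial"), margin >= 0)
  fx <- trial$fixations
  keep <- fx$valid &
    fx$x >= -margin & fx$x <= trial$display_w + margin &
    fx$y >= -margin & fx$y <= trial$display_h + margin
  out <- trial
  out$fixations <- fx[keep, , drop = FALSE]
  rownames(out$fixations) <- NULL
  if (nrow(fx) > 0 && nrow(out$fixations) == 0) {
    warning("all fixations removed from trial ", trial$trial_id, call. = FALSE)
  }
  out
}

#' Apply artifact filtering to every trial of a dataset
#'
#' @param ds a [gaze_dataset()].
#' @param margin passed to [filter_artifacts()].
#' @return A filtered [gaze_dataset()].
#' @export
filter_dataset <- function(ds, margin = 0) {
  gaze_dataset(lapply(ds$trials, filter_artifacts, margin = margin),
               device = ds$device)
}

#' Validate a gaze dataset
#'
#' Produces a non-mutating report: trial counts per participant and per
#' expertise class, empty trials, display-geometry consistency and onset
#' monotonicity. All findings are report entries; nothing throws.
#'
#' @param ds a [gaze_dataset()].
#' @return A list of class `gaze_validation` with components
#'   `n_trials`, `trials_per_participant`, `trials_per_class`,
#'   `empty_trials`, `geometry_ok`, `monotonic_ok`, `participant_class_ok`,
#'   `issues` (character vector, empty when clean).
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "gaze_dataset"))
  issues <- character(0)
  n <- length(ds$trials)
  part <- vapply(ds$trials, `[[`, character(1), "participant_id")
  labs <- dataset_labels(ds)
  per_part <- if (n) table(part) else table(character(0))
  per_class <- table(factor(labs, levels = expertise_levels))
  empty <- if (n) {
    vapply(ds$trials, function(tr) nrow(tr$fixations) == 0L, logical(1))
  } else logical(0)
  if (any(empty)) {
    issues <- c(issues, paste0("empty trial(s): ",
      paste(vapply(ds$trials[empty], `[[`, character(1), "trial_id"),
            collapse = ", ")))
  }
  geom_ok <- TRUE
  if (n) {
    geoms <- unique(t(vapply(ds$trials,
      function(tr) c(tr$display_w, tr$display_h), numeric(2))))
    geom_ok <- nrow(geoms) == 1L
    if (!geom_ok) issues <- c(issues, "mixed display geometries")
  }
  mono_ok <- all(vapply(ds$trials, function(tr) {
    !is.unsorted(tr$fixations$onset)
  }, logical(1)))
  if (!mono_ok) issues <- c(issues, "fixations not sorted by onset")
  pc <- unique(data.frame(participant = part, label = labs,
                          stringsAsFactors = FALSE))
  pc_ok <- !anyDuplicated(pc$participant)
  if (!pc_ok) {
    issues <- c(issues, paste0("participant(s) with inconsistent class: ",
      paste(unique(pc$participant[duplicated(pc$participant)]),
            collapse = ", ")))
  }
  structure(list(n_trials = n,
                 trials_per_participant = per_part,
                 trials_per_class = per_class,
                 empty_trials = sum(empty),
                 geometry_ok = geom_ok,
                 monotonic_ok = mono_ok,
                 participant_class_ok = pc_ok,
                 issues = issues),
            class = "gaze_validation")
}

#' @export
print.gaze_validation <- function(x, ...) {
  cat("Gaze dataset validation\n")
  cat("  trials:", x$n_trials, "\n")
  if (length(x$trials_per_participant)) {
    cat("  per participant:",
        paste(names(x$trials_per_participant), x$trials_per_participant,
              sep = "=", collapse = ", "), "\n")
  }
  cat("  per class:",
      paste(names(x$trials_per_class), x$trials_per_class,
            sep = "=", collapse = ", "), "\n")
  if (length(x$issues)) {
    cat("  issues:\n"); for (i in x$issues) cat("   -", i, "\n")
  } else cat("  no issues found\n")
  invisible(x)
}
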