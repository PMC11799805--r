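#' Configuration of the spatiotemporal encoding
#'
#' Defines how a trial's fixations are discretized: the display is tiled by a
#' `grid_x`-by-`grid_y` Cartesian grid, the fixation sequence is split into
#' `t` ordered temporal groups, and fixations are counted per grid cell per
#' group. The resulting vector has length `grid_x * grid_y * t` regardless of
#' trial duration or fixation count.
#'
#' Two temporal splitting modes are provided. `"time"` divides the trial's
#' temporal span (first onset to last onset + last duration) into `t` equal
#' intervals and assigns fixations by onset; longer dwelling in one phase of
#' inspection therefore concentrates counts in that group. `"count"` splits
#' the ordered fixation sequence into `t` near-equal-size groups (sizes
#' differing by at most one, larger groups first).
#'
#' Out-of-display fixations are handled by `oob`: `"clamp"` (default) assigns
#' them to the nearest edge cell — the natural behaviour of
#' nearest-centroid assignment — so the total count is conserved; `"drop"`
#' discards them before counting.
#'
#' @param grid_x horizontal subdivisions (integer >= 1).
#' @param grid_y vertical subdivisions; defaults to `grid_x` (square grid).
#' @param t number of temporal groups (integer >= 1).
#' @param binning `"time"` or `"count"`.
#' @param oob `"clamp"` or `"drop"`.
#' @return An object of class `encoding_config`.
#' @export
encoding_config <- function(grid_x = 5, grid_y = grid_x, t = 3,
                            binning = c("time", "count"),
                            oob = c("clamp", "drop")) {
  binning <- match.arg(binning)
  oob <- match.arg(oob)
  if (grid_x < 1 || grid_y < 1 || t < 1 ||
      grid_x != as.integer(grid_x) || grid_y != as.integer(grid_y) ||
      t != as.integer(t)) {
    stop("grid_x, grid_y and t must be integers >= 1", call. = FALSE)
  }
  structure(list(grid_x = as.integer(grid_x), grid_y = as.integer(grid_y),
                 t = as.integer(t), binning = binning, oob = oob),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat(sprintf("<encoding_config> %dx%d grid, t=%d (%s binning, oob=%s) -> length %d\n",
              x$grid_x, x$grid_y, x$t, x$binning, x$oob,
              x$grid_x * x$grid_y * x$t))
  invisible(x)
}

#' Length of the encoded vector implied by a configuration
#' @param config an [encoding_config()].
#' @return `grid_x * grid_y * t`.
#' @export
encoding_length <- function(config) {
  config$grid_x * config$grid_y * config$t
}

#' Grid-cell centroids tiling a display
#'
#' Cells tile the display exactly: cell width is `display_w / grid_x` and cell
#' height `display_h / grid_y`. The centroid of the cell in row `i`, column
#' `j` (0-based, row-major: row index moves down the display) is
#' `((j + 0.5) * cell_w, (i + 0.5) * cell_h)`.
#'
#' @param config an [encoding_config()].
#' @param display_w,display_h display extent in pixels (> 0).
#' @return An object of class `cell_grid`: list with `centroids` (matrix
#'   `(grid_x*grid_y) x 2`, columns `cx`, `cy`, rows in row-major cell order),
#'   `cell_w`, `cell_h`, `grid_x`, `grid_y`.
#' @export
cell_centroids <- function(config, display_w, display_h) {
  if (!is.numeric(display_w) || !is.numeric(display_h) ||
      display_w <= 0 || display_h <= 0) {
    stop("geometry error: display extent must be positive", call. = FALSE)
  }
  gx <- config$grid_x; gy <- config$grid_y
  cw <- display_w / gx; ch <- display_h / gy
  cx <- (seq_len(gx) - 0.5) * cw
  cy <- (seq_len(gy) - 0.5) * ch
  centroids <- cbind(cx = rep(cx, times = gy), cy = rep(cy, each = gx))
  structure(list(centroids = centroids, cell_w = cw, cell_h = ch,
                 grid_x = gx, grid_y = gy),
            class = "cell_grid")
}

#' Assign fixations to nearest grid cells
#'
#' Returns, for each coordinate pair, the row-major index (1-based) of the
#' grid cell whose centroid is nearest in Euclidean distance. A point exactly
#' equidistant between centroids (i.e. on a shared cell boundary) is assigned
#' the lowest row-major index among the tied cells. Points outside the display
#' are naturally assigned to the nearest edge cell.
#'
#' The implementation uses closed-form index arithmetic equivalent to the
#' argmin over all centroids: along each axis the nearest centroid for
#' coordinate `v` with cell extent `w` is `clamp(ceiling(v / w) - 1, 0, g - 1)`,
#' which resolves boundary ties downward, matching the lowest-row-major rule.
#'
#' @param x,y numeric vectors of display coordinates (pixels).
#' @param grid a [cell_centroids()] grid.
#' @return Integer vector of 1-based row-major cell indices.
#' @export
assign_cell <- function(x, y, grid) {
  stopifnot(inherits(grid, "cell_grid"))
  col <- pmin(pmax(ceiling(x / grid$cell_w) - 1, 0), grid$grid_x - 1L)
  row <- pmin(pmax(ceiling(y / grid$cell_h) - 1, 0), grid$grid_y - 1L)
  as.integer(row * grid$grid_x + col + 1L)
}

#' Split a trial's fixations into temporal groups
#'
#' @param trial a [gaze_trial()].
#' @param t number of groups (integer >= 1).
#' @param mode `"time"`: the span from the first onset to the last onset plus
#'   last duration is divided into `t` equal half-open intervals `[a, b)`
#'   (the final interval closed on the right) and fixations are assigned by
#'   onset; a zero-length span puts all fixations in the first group.
#'   `"count"`: the ordered sequence is split into `t` groups whose sizes
#'   differ by at most one, larger groups first (`n = q*t + r` gives `r`
#'   leading groups of size `q + 1`).
#' @return List of `t` data frames of fixations; their concatenation restores
#'   the trial's fixation order. An empty trial yields `t` empty groups.
#' @export
split_temporal <- function(trial, t, mode = c("time", "count")) {
  mode <- match.arg(mode)
  if (t < 1 || t != as.integer(t)) {
    stop("configuration error: t must be an integer >= 1", call. = FALSE)
  }
  t <- as.integer(t)
  fx <- trial$fixations
  n <- nrow(fx)
  idx <- temporal_group_index(fx$onset, fx$duration, n, t, mode)
  lapply(seq_len(t), function(b) {
    g <- fx[idx == b, , drop = FALSE]
    rownames(g) <- NULL
    g
  })
}

# group index per fixation (1..t); onsets assumed sorted
temporal_group_index <- function(onset, duration, n, t, mode) {
  if (n == 0L) return(integer(0))
  if (t == 1L) return(rep(1L, n))
  if (mode == "count") {
    q <- n %/% t; r <- n %% t
    sizes <- c(rep(q + 1L, r), rep(q, t - r))
    rep(seq_len(t), times = sizes)
  } else {
    a <- onset[1]
    b <- onset[n] + duration[n]
    span <- b - a
    if (span <= 0) return(rep(1L, n))
    g <- floor((onset - a) / span * t) + 1L
    pmin(as.integer(g), t)  # onset == b (final closed endpoint) -> group t
  }
}

#' Encode one trial as a spatiotemporal count vector
#'
#' Splits the trial's fixations into `t` temporal groups, counts the fixations
#' of each group per spatial grid cell, and flattens temporal-major (group 1's
#' full grid first), row-major within each grid. Entry
#' `counts[(b-1)*grid_x*grid_y + c]` is the number of group-`b` fixations
#' assigned to cell `c`.
#'
#' With `oob = "clamp"` the vector total equals the trial's fixation count;
#' with `"drop"`, fixations outside `[0, display_w] x [0, display_h]` are
#' discarded before temporal splitting.
#'
#' @param trial a [gaze_trial()].
#' @param config an [encoding_config()].
#' @return An object of class `encoded_vector`: list with integer `counts`
#'   (length `grid_x*grid_y*t`) and the `config` used.
#' @export
encode_trial <- function(trial, config) {
  stopifnot(inherits(trial, "gaze_trial"), inherits(config, "encoding_config"))
  grid <- cell_centroids(config, trial$display_w, trial$display_h)
  fx <- trial$fixations
  if (config$oob == "drop" && nrow(fx)) {
    keep <- fx$x >= 0 & fx$x <= trial$display_w &
            fx$y >= 0 & fx$y <= trial$display_h
    fx <- fx[keep, , drop = FALSE]
  }
  n <- nrow(fx)
  ncell <- config$grid_x * config$grid_y
  counts <- integer(ncell * config$t)
  if (n) {
    bin <- temporal_group_index(fx$onset, fx$duration, n, config$t,
                                config$binning)
    cell <- assign_cell(fx$x, fx$y, grid)
    flat <- (bin - 1L) * ncell + cell
    tab <- tabulate(flat, nbins = length(counts))
    counts <- as.integer(tab)
  }
  structure(list(counts = counts, config = config), class = "encoded_vector")
}

#' @export
print.encoded_vector <- function(x, ...) {
  cat(sprintf("<encoded_vector> length %d (%dx%d grid, t=%d), total count %d\n",
              length(x$counts), x$config$grid_x, x$config$grid_y, x$config$t,
              sum(x$counts)))
  invisible(x)
}

#' Names of the encoded feature columns
#'
#' `b{bin}_r{row}_c{col}`, 1-based, temporal-major then row-major.
#' @param config an [encoding_config()].
#' @return Character vector of length `encoding_length(config)`.
#' @export
encoding_colnames <- function(config) {
  gx <- config$grid_x; gy <- config$grid_y
  cell <- paste0("r", rep(seq_len(gy), each = gx), "_c", rep(seq_len(gx), gy))
  paste0("b", rep(seq_len(config$t), each = gx * gy), "_", cell)
}

#' Encode every trial of a dataset into a feature matrix
#'
#' @param ds a [gaze_dataset()].
#' @param config an [encoding_config()].
#' @return A list of class `gaze_encoding`: `features` (integer matrix,
#'   trials x `encoding_length(config)`, columns named `b{bin}_r{row}_c{col}`),
#'   `trial_id`, `participant_id`, `label` (aligned character vectors) and
#'   `config`. Row order follows dataset trial order.
#' @export
encode_dataset <- function(ds, config) {
  stopifnot(inherits(ds, "gaze_dataset"))
  len <- encoding_length(config)
  n <- length(ds$trials)
  features <- matrix(0L, nrow = n, ncol = len,
                     dimnames = list(NULL, encoding_colnames(config)))
  for (i in seq_len(n)) {
    v <- tryCatch(encode_trial(ds$trials[[i]], config), error = function(e) {
      stop("encoding failed for trial ", ds$trials[[i]]$trial_id, ": ",
           conditionMessage(e), call. = FALSE)
    })
    features[i, ] <- v$counts
  }
  structure(list(features = features,
                 trial_id = vapply(ds$trials, `[[`, character(1), "trial_id"),
                 participant_id = vapply(ds$trials, `[[`, character(1),
                                         "participant_id"),
                 label = dataset_labels(ds),
                 config = config),
            class = "gaze_encoding")
}

#' @export
print.gaze_encoding <- function(x, ...) {
  cat(sprintf("<gaze_encoding> %d trials x %d features (%dx%d grid, t=%d)\n",
              nrow(x$features), ncol(x$features),
              x$config$grid_x, x$config$grid_y, x$config$t))
  invisible(x)
}

#' Write an encoded feature matrix as CSV
#'
#' Columns `trial_id,participant_id,label` followed by the encoded features.
#' @param enc a [encode_dataset()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_encoding <- function(enc, path) {
  out <- data.frame(trial_id = enc$trial_id,
                    participant_id = enc$participant_id,
                    label = enc$label, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(enc$features))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
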