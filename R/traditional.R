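#' Total scan time of a trial
#'
#' Span from the first fixation's onset to the end of the last fixation
#' (last onset + last duration), in seconds. Trials with no fixations
#' score 0.
#'
#' @param trial a [gaze_trial()].
#' @return Seconds (numeric scalar >= 0).
#' @export
total_scan_time <- function(trial) {
  fx <- trial$fixations
  n <- nrow(fx)
  if (n == 0L) return(0)
  (fx$onset[n] + fx$duration[n]) - fx$onset[1]
}

#' Number of fixations in a trial
#' @param trial a [gaze_trial()].
#' @return Integer count.
#' @export
fixation_count <- function(trial) {
  nrow(trial$fixations)
}

#' Regressive fixation count
#'
#' Counts fixations that return to a previously visited location after the
#' gaze has moved elsewhere. "Location" is made operational via a coarse
#' spatial grid: each fixation maps to a cell of `loc_grid`, and a fixation is
#' regressive when its cell was visited earlier in the trial *and* at least
#' one intervening fixation fell in a different cell. Consecutive same-cell
#' fixations are dwell, not regression.
#'
#' @param trial a [gaze_trial()].
#' @param loc_grid a [cell_centroids()] grid defining "locations"; defaults to
#'   a 5x5 grid over the trial's display.
#' @return Integer count (<= `fixation_count(trial) - 1` for non-empty trials).
#' @export
regressive_fixation_count <- function(trial, loc_grid = NULL) {
  fx <- trial$fixations
  n <- nrow(fx)
  if (n < 2L) return(0L)
  if (is.null(loc_grid)) {
    loc_grid <- cell_centroids(encoding_config(grid_x = 5, t = 1),
                               trial$display_w, trial$display_h)
  }
  cells <- assign_cell(fx$x, fx$y, loc_grid)
  visited <- logical(loc_grid$grid_x * loc_grid$grid_y)
  visited[cells[1]] <- TRUE
  count <- 0L
  for (j in 2:n) {
    cur <- cells[j]; prev <- cells[j - 1L]
    if (cur != prev && visited[cur]) count <- count + 1L
    visited[cur] <- TRUE
  }
  count
}

#' Total saccade length
#'
#' Sum over consecutive fixation pairs of the Euclidean distance between their
#' coordinates, in pixels — the spatial path length of the scan. Trials with
#' fewer than two fixations score 0.
#'
#' @param trial a [gaze_trial()].
#' @return Pixels (numeric scalar >= 0).
#' @export
total_saccade_length <- function(trial) {
  fx <- trial$fixations
  n <- nrow(fx)
  if (n < 2L) return(0)
  sum(sqrt(diff(fx$x)^2 + diff(fx$y)^2))
}

#' Salient-region mask from a grayscale image
#'
#' A salient region is image area that is not peripheral black background
#' (for a chest x-ray: the radiograph content as displayed, framed by black
#' letterboxing). The mask is built by thresholding normalized intensity,
#' morphologically closing the result (to bridge dark structures inside the
#' content, e.g. the lung fields), and keeping everything inside the bounding
#' box of the largest connected component — so the peripheral border is
#' removed while dark interior anatomy stays salient.
#'
#' @param image numeric matrix of grayscale intensities in `[0, 1]`, indexed
#'   `[row, col]` = `[y, x]` (top-left origin), or a path to a grayscale PNG.
#' @param threshold intensity above which a pixel counts as content.
#' @param brush_size diameter (pixels, odd) of the disc used for closing.
#' @return An object of class `salient_mask`: list with `mask` (logical
#'   matrix `[y, x]`) and `salient_area` (number of `TRUE` pixels).
#' @export
salient_mask_from_image <- function(image, threshold = 0.05, brush_size = 7) {
  if (is.character(image)) {
    image <- png::readPNG(image)
    if (length(dim(image)) == 3L) image <- image[, , 1]
  }
  stopifnot(is.matrix(image))
  if (max(image) > 1) image <- image / max(image)
  bw <- image > threshold
  if (!any(bw)) {
    stop("degenerate mask: no pixel above threshold (all-black image?)",
         call. = FALSE)
  }
  # EBImage indexes images [x, y]; transpose in and out
  eb <- EBImage::Image(t(bw))
  closed <- EBImage::closing(eb, EBImage::makeBrush(brush_size, shape = "disc"))
  labels <- EBImage::bwlabel(closed)
  lab_m <- t(EBImage::imageData(labels))
  tab <- tabulate(lab_m[lab_m > 0])
  biggest <- which.max(tab)
  comp <- lab_m == biggest
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  structure(list(mask = mask, salient_area = sum(mask)),
            class = "salient_mask")
}

#' Full-display salient mask
#'
#' Used when no stimulus image is available: the whole display is treated as
#' salient.
#' @param display_w,display_h display extent in pixels.
#' @return A `salient_mask` covering the display.
#' @export
salient_mask_full <- function(display_w, display_h) {
  mask <- matrix(TRUE, nrow = as.integer(display_h),
                 ncol = as.integer(display_w))
  structure(list(mask = mask, salient_area = sum(mask)),
            class = "salient_mask")
}

#' @export
print.salient_mask <- function(x, ...) {
  cat(sprintf("<salient_mask> %dx%d px, salient area %d (%.1f%%)\n",
              ncol(x$mask), nrow(x$mask), x$salient_area,
              100 * x$salient_area / length(x$mask)))
  invisible(x)
}

#' Gaze coverage of the salient image area
#'
#' Fraction of salient pixels lying within `radius` pixels of at least one
#' fixation — the union of fixation discs intersected with the salient mask,
#' divided by the salient area. The default radius, 2% of the display
#' diagonal, approximates the ~1 degree spatial accuracy typical of remote
#' eye trackers.
#'
#' @param trial a [gaze_trial()].
#' @param mask a `salient_mask` whose matrix matches the display extent
#'   (`[display_h, display_w]`); defaults to the full display.
#' @param radius disc radius in pixels (> 0); default
#'   `0.02 * sqrt(display_w^2 + display_h^2)`.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(trial, mask = NULL, radius = NULL) {
  if (is.null(mask)) {
    mask <- salient_mask_full(trial$display_w, trial$display_h)
  }
  if (is.null(radius)) {
    radius <- 0.02 * sqrt(trial$display_w^2 + trial$display_h^2)
  }
  stopifnot(inherits(mask, "salient_mask"), radius > 0)
  fx <- trial$fixations
  if (nrow(fx) == 0L) return(0)
  h <- nrow(mask$mask); w <- ncol(mask$mask)
  covered <- matrix(FALSE, h, w)
  r <- radius
  for (k in seq_len(nrow(fx))) {
    # pixel centres: pixel (row i, col j) covers centre (j - 0.5, i - 0.5)
    cx <- fx$x[k]; cy <- fx$y[k]
    j0 <- max(1L, floor(cx - r + 0.5)); j1 <- min(w, ceiling(cx + r + 0.5))
    i0 <- max(1L, floor(cy - r + 0.5)); i1 <- min(h, ceiling(cy + r + 0.5))
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    dx2 <- (jj - 0.5 - cx)^2
    dy2 <- (ii - 0.5 - cy)^2
    covered[ii, jj] <- covered[ii, jj] | outer(dy2, dx2, `+`) <= r^2
  }
  sum(covered & mask$mask) / mask$salient_area
}

#' Extract the five traditional gaze features per trial
#'
#' Computes, for every trial: total scan time (s), fixation count, regressive
#' fixation count (grid-revisit definition, see
#' [regressive_fixation_count()]), total saccade length (px) and coverage of
#' the salient area. Features depending on ground-truth abnormality locations
#' (dwell/fixations/time-to-first-fixation on an area of interest) are
#' deliberately not computed: they require manual annotation of every image.
#'
#' @param ds a [gaze_dataset()].
#' @param loc_grid_size grid size defining "locations" for the regressive
#'   count (default 5).
#' @param masks optional list of `salient_mask` objects, one per trial (or a
#'   single mask recycled for all trials); default: full display salient.
#' @param radius coverage disc radius in pixels; default 2% of the display
#'   diagonal.
#' @return A list of class `gaze_traditional`: `features` (numeric matrix,
#'   trials x 5, columns `total_time_s`, `fixation_count`, `regressive_count`,
#'   `saccade_length_px`, `coverage`), plus aligned `trial_id`,
#'   `participant_id`, `label`.
#' @export
extract_traditional <- function(ds, loc_grid_size = 5, masks = NULL,
                                radius = NULL) {
  stopifnot(inherits(ds, "gaze_dataset"))
  n <- length(ds$trials)
  cols <- c("total_time_s", "fixation_count", "regressive_count",
            "saccade_length_px", "coverage")
  features <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  if (n) {
    geom <- dataset_geometry(ds)
    loc_grid <- cell_centroids(encoding_config(grid_x = loc_grid_size, t = 1),
                               geom["w"], geom["h"])
    shared_mask <- NULL
    if (inherits(masks, "salient_mask")) {
      shared_mask <- masks; masks <- NULL
    }
    if (is.null(masks) && is.null(shared_mask)) {
      shared_mask <- salient_mask_full(geom["w"], geom["h"])
    }
    for (i in seq_len(n)) {
      tr <- ds$trials[[i]]
      m <- if (!is.null(masks)) masks[[i]] else shared_mask
      features[i, ] <- c(total_scan_time(tr),
                         fixation_count(tr),
                         regressive_fixation_count(tr, loc_grid),
                         total_saccade_length(tr),
                         coverage(tr, m, radius))
    }
  }
  structure(list(features = features,
                 trial_id = vapply(ds$trials, `[[`, character(1), "trial_id"),
                 participant_id = vapply(ds$trials, `[[`, character(1),
                                         "participant_id"),
                 label = dataset_labels(ds)),
            class = "gaze_traditional")
}

#' @export
print.gaze_traditional <- function(x, ...) {
  cat(sprintf("<gaze_traditional> %d trials x 5 features\n", nrow(x$features)))
  invisible(x)
}

#' Write traditional features as CSV
#' @param feats an [extract_traditional()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traditional <- function(feats, path) {
  out <- data.frame(trial_id = feats$trial_id,
                    participant_id = feats$participant_id,
                    label = feats$label, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats$features))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
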