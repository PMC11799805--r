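#' Class archetype parameters for synthetic scanpaths
#'
#' Bundles the distributional parameters of one expertise archetype. Per-trial
#' fixation counts follow a negative binomial (mean `n_fix_mean`, dispersion
#' `n_fix_size`; larger size = less dispersion), floored at 1. Fixation
#' locations come from a mixture of `K` isotropic 2-D Gaussian clusters
#' (means and sds as fractions of the display extent) blended with a
#' systematic left-to-right, top-to-bottom sweep component taken with
#' probability `sweep_weight`; a cluster move revisits an already-visited
#' cluster with probability `revisit_prob`. Durations are Gaussian (truncated
#' below), onsets cumulative, and coordinates get isotropic measurement
#' jitter before clamping to the display.
#'
#' @param n_fix_mean,n_fix_size negative-binomial mean and size of the
#'   per-trial fixation count.
#' @param cluster_means K x 2 matrix of cluster centres (display fractions).
#' @param cluster_sd isotropic cluster spread (display fraction).
#' @param cluster_weights mixture weights (length K, sum 1).
#' @param sweep_weight probability in `[0,1]` that a fixation follows the
#'   systematic sweep instead of a cluster draw.
#' @param revisit_prob probability in `[0,1]` that a cluster draw returns to a
#'   previously visited cluster.
#' @param dur_mean,dur_sd fixation duration mean and sd (seconds).
#' @param jitter_sd measurement noise sd (pixels).
#' @return An object of class `archetype_params`.
#' @export
archetype_params <- function(n_fix_mean, n_fix_size, cluster_means, cluster_sd,
                             cluster_weights, sweep_weight, revisit_prob,
                             dur_mean, dur_sd, jitter_sd) {
  cluster_means <- as.matrix(cluster_means)
  stopifnot(ncol(cluster_means) == 2,
            length(cluster_weights) == nrow(cluster_means),
            abs(sum(cluster_weights) - 1) < 1e-8,
            cluster_sd > 0, dur_sd >= 0, jitter_sd >= 0,
            sweep_weight >= 0, sweep_weight <= 1,
            revisit_prob >= 0, revisit_prob <= 1)
  structure(list(n_fix_mean = n_fix_mean, n_fix_size = n_fix_size,
                 cluster_means = cluster_means, cluster_sd = cluster_sd,
                 cluster_weights = cluster_weights / sum(cluster_weights),
                 sweep_weight = sweep_weight, revisit_prob = revisit_prob,
                 dur_mean = dur_mean, dur_sd = dur_sd, jitter_sd = jitter_sd),
            class = "archetype_params")
}

# shared cluster anchor locations (display fractions), used by both classes
archetype_anchor_means <- function() {
  rbind(c(0.30, 0.30), c(0.70, 0.30),
        c(0.30, 0.62), c(0.70, 0.62),
        c(0.50, 0.45), c(0.50, 0.80))
}

#' Faculty and trainee scanpath archetypes
#'
#' Returns the parameter pair for the two expertise classes at a given
#' `separation`. At `separation = 0` the archetypes are identical (both equal
#' the midpoint of the two endpoint behaviours); at `separation = 1` the
#' contrast is maximal: the faculty archetype sweeps the display
#' systematically with near-uniform attention over many dispersed regions and
#' rarely revisits, while the trainee archetype concentrates on a few tight
#' suspicion regions and revisits them often. All parameters interpolate
#' linearly (componentwise) in `separation`.
#'
#' @param separation scalar in `[0, 1]` scaling the class contrast.
#' @return List with elements `faculty` and `trainee`, each an
#'   [archetype_params()].
#' @export
archetypes <- function(separation = 0.8) {
  if (!is.numeric(separation) || length(separation) != 1 ||
      separation < 0 || separation > 1) {
    stop("configuration error: separation must be a scalar in [0, 1]",
         call. = FALSE)
  }
  means <- archetype_anchor_means()
  K <- nrow(means)
  # endpoint (separation = 1) parameter sets
  faculty_end <- list(weights = rep(1 / K, K), sd = 0.085,
                      sweep = 0.60, revisit = 0.15)
  w_tr <- c(0.42, 0.42, 0.05, 0.05, 0.03, 0.03)  # two dominant clusters
  trainee_end <- list(weights = w_tr, sd = 0.035,
                      sweep = 0.08, revisit = 0.55)
  mid <- list(weights = (faculty_end$weights + trainee_end$weights) / 2,
              sd = (faculty_end$sd + trainee_end$sd) / 2,
              sweep = (faculty_end$sweep + trainee_end$sweep) / 2,
              revisit = (faculty_end$revisit + trainee_end$revisit) / 2)
  lerp <- function(a, b) a + separation * (b - a)
  make <- function(end) {
    archetype_params(
      n_fix_mean = 40, n_fix_size = 12,
      cluster_means = means,
      cluster_sd = lerp(mid$sd, end$sd),
      cluster_weights = lerp(mid$weights, end$weights),
      sweep_weight = lerp(mid$sweep, end$sweep),
      revisit_prob = lerp(mid$revisit, end$revisit),
      dur_mean = 0.30, dur_sd = 0.08, jitter_sd = 6)
  }
  list(faculty = make(faculty_end), trainee = make(trainee_end))
}

# serpentine sweep position at progress u in [0, 1], display fractions
sweep_position <- function(u, n_rows = 3) {
  row <- pmin(floor(u * n_rows), n_rows - 1)
  local <- u * n_rows - row
  xfrac <- ifelse(row %% 2 == 0, local, 1 - local)
  cbind(x = 0.08 + 0.84 * xfrac, y = (row + 0.5) / n_rows)
}

#' Simulate one scanpath trial from an archetype
#'
#' Draws the fixation count, then generates an ordered fixation sequence: each
#' fixation either follows the systematic serpentine sweep (probability
#' `sweep_weight`, with position driven by trial progress) or is drawn from
#' the cluster mixture, returning to an already-visited cluster with
#' probability `revisit_prob`. Measurement jitter is added and coordinates are
#' clamped inside the display; onsets are cumulative durations, so they
#' strictly increase whenever durations are positive. Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param params an [archetype_params()].
#' @param trial_id,participant_id,label trial metadata.
#' @param display_w,display_h display extent in pixels.
#' @return A [gaze_trial()].
#' @export
simulate_trial <- function(params, trial_id, participant_id, label,
                           display_w = 1920, display_h = 1080) {
  stopifnot(inherits(params, "archetype_params"))
  n <- max(1L, rnbinom(1, size = params$n_fix_size, mu = params$n_fix_mean))
  K <- nrow(params$cluster_means)
  visited <- integer(0)
  x <- numeric(n); y <- numeric(n)
  for (j in seq_len(n)) {
    u <- if (n == 1L) 0.5 else (j - 1) / (n - 1)
    if (runif(1) < params$sweep_weight) {
      pos <- sweep_position(u)
      px <- pos[1, "x"]; py <- pos[1, "y"]
      sd_here <- params$cluster_sd
    } else {
      k <- if (length(visited) && runif(1) < params$revisit_prob) {
        visited[sample.int(length(visited), 1)]
      } else {
        sample.int(K, 1, prob = params$cluster_weights)
      }
      visited <- union(visited, k)
      px <- params$cluster_means[k, 1]; py <- params$cluster_means[k, 2]
      sd_here <- params$cluster_sd
    }
    x[j] <- px * display_w + rnorm(1, 0, sd_here * display_w)
    y[j] <- py * display_h + rnorm(1, 0, sd_here * display_h)
  }
  x <- pmin(pmax(x + rnorm(n, 0, params$jitter_sd), 0), display_w)
  y <- pmin(pmax(y + rnorm(n, 0, params$jitter_sd), 0), display_h)
  dur <- pmax(abs(rnorm(n, params$dur_mean, params$dur_sd)), 0.02)
  onset <- cumsum(c(0, dur[-n]))
  gaze_trial(trial_id, participant_id, label, display_w, display_h,
             data.frame(x = x, y = y, onset = onset, duration = dur,
                        valid = TRUE))
}

#' Configuration for synthetic dataset generation
#'
#' Presets mirror the two study designs the generator emulates:
#' `"eyelink_like"` — pre-filtered fixation data, 1 faculty + 1 trainee
#' participant, 55 trials each (110 trials); `"tobii_like"` — noisier raw
#' gaze ingested as fixations (more samples per trial, each lasting one
#' inter-sample interval, larger jitter), 4 faculty + 4 trainees, 27 trials
#' each (216 trials).
#'
#' @param preset `"eyelink_like"`, `"tobii_like"` or `"custom"`.
#' @param n_participants_per_class,trials_per_participant design counts
#'   (preset defaults when `NULL`).
#' @param display_w,display_h display extent in pixels.
#' @param separation class contrast in `[0, 1]` passed to [archetypes()].
#' @param seed integer seed; the dataset is a pure function of this config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(preset = c("eyelink_like", "tobii_like",
                                         "custom"),
                              n_participants_per_class = NULL,
                              trials_per_participant = NULL,
                              display_w = 1920, display_h = 1080,
                              separation = 0.8, seed = 1) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    eyelink_like = list(npc = 1L, tpp = 55L),
    tobii_like = list(npc = 4L, tpp = 27L),
    custom = list(npc = 1L, tpp = 10L))
  if (is.null(n_participants_per_class)) n_participants_per_class <- defaults$npc
  if (is.null(trials_per_participant)) trials_per_participant <- defaults$tpp
  stopifnot(n_participants_per_class >= 0, trials_per_participant >= 0,
            separation >= 0, separation <= 1)
  structure(list(preset = preset,
                 n_participants_per_class = as.integer(n_participants_per_class),
                 trials_per_participant = as.integer(trials_per_participant),
                 display_w = display_w, display_h = display_h,
                 separation = separation, seed = as.integer(seed)),
            class = "simulation_config")
}

# gaze-like distortion of an archetype for the tobii_like preset: many more
# samples per trial (raw gaze), duration = inter-sample interval, more noise
gaze_like_params <- function(p) {
  p$n_fix_mean <- p$n_fix_mean * 4
  p$n_fix_size <- p$n_fix_size * 2
  p$dur_mean <- 1 / 30; p$dur_sd <- 1 / 300
  p$jitter_sd <- p$jitter_sd * 4
  p
}

#' Simulate a labeled two-class gaze dataset
#'
#' Generates `2 * n_participants_per_class * trials_per_participant` trials
#' with stable, class-consistent participant ids (`F1..`, `T1..`) and trial
#' ids `<participant>_t<index>`. Each trial is generated from its own RNG
#' substream derived from the dataset seed and a trial counter, so the result
#' is bit-reproducible and individual trials are independent of dataset
#' layout.
#'
#' @param config a [simulation_config()] (or a preset name).
#' @return A [gaze_dataset()] whose `device` tag matches the preset.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  if (is.character(config)) config <- simulation_config(preset = config)
  stopifnot(inherits(config, "simulation_config"))
  arch <- archetypes(config$separation)
  if (config$preset == "tobii_like") {
    arch <- lapply(arch, gaze_like_params)
  }
  trials <- list()
  counter <- 0L
  for (cls in expertise_levels) {
    prefix <- if (cls == "faculty") "F" else "T"
    for (p in seq_len(config$n_participants_per_class)) {
      pid <- paste0(prefix, p)
      for (k in seq_len(config$trials_per_participant)) {
        counter <- counter + 1L
        # per-trial substream: derived seed kept within 32-bit integer range
        set.seed((config$seed %% 100000L) * 20011L + counter * 7L)
        trials[[counter]] <- simulate_trial(
          arch[[cls]], trial_id = paste0(pid, "_t", k), participant_id = pid,
          label = cls, display_w = config$display_w,
          display_h = config$display_h)
      }
    }
  }
  device <- if (config$preset == "custom") "other" else config$preset
  gaze_dataset(trials, device = device)
}
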