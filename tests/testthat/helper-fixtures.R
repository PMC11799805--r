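# Shared fixtures and independent oracles used across the suite.

# quick trial: fixations at (x, y), onsets defaulting to 0, 1, 2, ... with
# fixed 0.3 s durations on a square display
make_trial <- function(x, y, onset = seq_along(x) - 1,
                       duration = rep(0.3, length(x)),
                       valid = rep(TRUE, length(x)),
                       w = 300, h = 300, label = "faculty",
                       id = "t1", participant = "p1") {
  gaze_trial(id, participant, label, w, h,
             data.frame(x = x, y = y, onset = onset, duration = duration,
                        valid = valid))
}

# independent nearest-centroid oracle: explicit squared-distance comparison
# over all centroids, exact ties resolved to the lowest row-major index
argmin_assign <- function(x, y, grid, chunk = 50000L) {
  out <- integer(length(x))
  cx <- grid$centroids[, "cx"]; cy <- grid$centroids[, "cy"]
  for (s in seq(1, length(x), by = chunk)) {
    e <- min(s + chunk - 1L, length(x))
    d2 <- outer(x[s:e], cx, "-")^2 + outer(y[s:e], cy, "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# brute-force AUC: all positive/negative pairs, ties counted one half
auc_bruteforce <- function(y_true, score, positive = "trainee") {
  pos <- score[y_true == positive]
  neg <- score[y_true != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random trial on a small display for property sweeps
random_trial <- function(n = NULL, w = 300, h = 200, off_display = FALSE) {
  if (is.null(n)) n <- sample(0:40, 1)
  if (n == 0) return(make_trial(numeric(0), numeric(0), w = w, h = h))
  spread <- if (off_display) 1.4 else 1
  dur <- runif(n, 0.05, 0.5)
  make_trial(runif(n, -0.2 * w * off_display, w * spread),
             runif(n, -0.2 * h * off_display, h * spread),
             onset = cumsum(c(0, dur[-n])), duration = dur, w = w, h = h)
}

# tiny two-class dataset for fast benchmark tests: 12 trials per class from
# well-separated archetypes
small_benchmark_dataset <- function(seed = 42, separation = 1) {
  simulate_dataset(simulation_config("custom",
                                     n_participants_per_class = 1,
                                     trials_per_participant = 12,
                                     display_w = 400, display_h = 300,
                                     separation = separation, seed = seed))
}
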