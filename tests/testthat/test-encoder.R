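test_that("count-mode temporal split puts remainder in the leading groups", {
  tr <- make_trial(x = 1:10, y = 1:10)
  groups <- split_temporal(tr, 3, "count")
  expect_equal(vapply(groups, nrow, integer(1)), c(4L, 3L, 3L))
  expect_equal(do.call(rbind, groups)$x, tr$fixations$x)
  # t = 1 is the identity
  expect_equal(split_temporal(tr, 1, "count")[[1]], tr$fixations)
  expect_error(split_temporal(tr, 0, "count"), "t must be")
})

test_that("time-mode split divides the temporal span into equal intervals", {
  tr <- make_trial(x = rep(1, 10), y = rep(1, 10), onset = 0:9,
                   duration = rep(0, 10))
  groups <- split_temporal(tr, 2, "time")
  # span [0, 9] halves at 4.5: onsets 0..4 left, 5..9 right
  expect_equal(vapply(groups, nrow, integer(1)), c(5L, 5L))
  # final interval is closed: the last fixation (onset == span end) lands in
  # the last group, not beyond it
  tr2 <- make_trial(x = 1:4, y = 1:4, onset = c(0, 1, 2, 4),
                    duration = rep(0, 4))
  g2 <- split_temporal(tr2, 4, "time")
  expect_equal(vapply(g2, nrow, integer(1)), c(1L, 1L, 1L, 1L))
  # empty trial gives t empty groups
  g0 <- split_temporal(make_trial(numeric(0), numeric(0)), 3, "time")
  expect_equal(vapply(g0, nrow, integer(1)), rep(0L, 3))
})

test_that("cell centroids tile the display exactly", {
  g <- cell_centroids(encoding_config(3, t = 1), 300, 300)
  expect_equal(sort(unique(g$centroids[, "cx"])), c(50, 150, 250))
  expect_equal(sort(unique(g$centroids[, "cy"])), c(50, 150, 250))
  g1 <- cell_centroids(encoding_config(1, t = 1), 640, 480)
  expect_equal(unname(g1$centroids[1, ]), c(320, 240))
  g57 <- cell_centroids(encoding_config(grid_x = 5, grid_y = 7, t = 1),
                        1000, 700)
  expect_equal(nrow(g57$centroids), 35)
  expect_equal(c(g57$cell_w, g57$cell_h), c(200, 100))
  expect_equal(unname(g57$centroids[1, ]), c(100, 50))
  expect_error(cell_centroids(encoding_config(3, t = 1), -10, 100),
               "geometry")
})

test_that("cell assignment matches the nearest-centroid rule with low-index ties", {
  g <- cell_centroids(encoding_config(3, t = 1), 300, 300)
  # exact centroids map to their own cell
  expect_equal(assign_cell(g$centroids[, "cx"], g$centroids[, "cy"], g), 1:9)
  # boundary between cells 1 and 2 (x = 100): tie goes to the lower index
  expect_equal(assign_cell(100, 50, g), 1L)
  expect_equal(assign_cell(100, 100, g), 1L)  # four-way corner tie
  # far out-of-display clamps to the nearest edge cell
  expect_equal(assign_cell(-500, -500, g), 1L)
  expect_equal(assign_cell(1e4, 1e4, g), 9L)
  # fuzzed agreement with the explicit argmin oracle
  set.seed(5)
  for (dims in list(c(3, 3, 300, 300), c(4, 6, 500, 250))) {
    cfg <- encoding_config(grid_x = dims[1], grid_y = dims[2], t = 1)
    grid <- cell_centroids(cfg, dims[3], dims[4])
    x <- runif(500, -50, dims[3] + 50); y <- runif(500, -50, dims[4] + 50)
    expect_equal(assign_cell(x, y, grid), argmin_assign(x, y, grid))
  }
})

test_that("trial encoding counts fixations per cell per temporal group", {
  tr <- make_trial(x = c(50, 150, 250), y = c(50, 150, 250))
  v <- encode_trial(tr, encoding_config(3, t = 1))
  expect_equal(which(v$counts == 1), c(1L, 5L, 9L))
  expect_equal(sum(v$counts), 3)
  # empty trial: all-zero vector of full length
  v0 <- encode_trial(make_trial(numeric(0), numeric(0)),
                     encoding_config(4, t = 5))
  expect_equal(v0$counts, rep(0L, 80))
  # the largest benchmarked configuration yields 4500 variables
  expect_equal(encoding_length(encoding_config(15, t = 20)), 4500)
  v45 <- encode_trial(tr, encoding_config(15, t = 20))
  expect_length(v45$counts, 4500)
})

test_that("flatten order is temporal-major, row-major within each grid", {
  # one fixation per temporal half, in known cells of a 2x2 grid on 200x200:
  # first fixation top-right cell (col 2, row 1) -> cell 2 of group 1;
  # second fixation bottom-left (col 1, row 2) -> cell 3 of group 2
  tr <- make_trial(x = c(150, 50), y = c(50, 150), onset = c(0, 10),
                   duration = c(0.1, 0.1), w = 200, h = 200)
  v <- encode_trial(tr, encoding_config(2, t = 2, binning = "time"))
  expect_equal(v$counts, c(0L, 1L, 0L, 0L,  0L, 0L, 1L, 0L))
  expect_equal(encoding_colnames(encoding_config(2, t = 2)),
               c("b1_r1_c1", "b1_r1_c2", "b1_r2_c1", "b1_r2_c2",
                 "b2_r1_c1", "b2_r1_c2", "b2_r2_c1", "b2_r2_c2"))
})

test_that("clamp conserves the fixation count; drop discards off-display", {
  set.seed(21)
  for (i in 1:30) {
    tr <- random_trial(off_display = TRUE)
    cfg <- encoding_config(sample(2:8, 1), t = sample(1:5, 1),
                           binning = sample(c("time", "count"), 1))
    v <- encode_trial(tr, cfg)
    expect_equal(sum(v$counts), nrow(tr$fixations))
    cfg_drop <- encoding_config(cfg$grid_x, t = cfg$t, oob = "drop")
    expect_lte(sum(encode_trial(tr, cfg_drop)$counts), nrow(tr$fixations))
  }
})

test_that("encoding is invariant to within-group permutation but not across groups", {
  cfg <- encoding_config(3, t = 2, binning = "count")
  # 6 fixations, count mode: groups {1,2,3} and {4,5,6}
  x <- c(50, 150, 250, 50, 150, 250); y <- c(50, 50, 50, 250, 250, 250)
  tr <- make_trial(x, y, onset = 0:5, duration = rep(0.1, 6))
  # permute within each group (same multisets per group)
  perm <- c(3, 1, 2, 6, 5, 4)
  tr_perm <- make_trial(x[perm], y[perm], onset = 0:5,
                        duration = rep(0.1, 6))
  expect_equal(encode_trial(tr_perm, cfg)$counts, encode_trial(tr, cfg)$counts)
  # swap the two groups' contents: different vector (groups differ here)
  swap <- c(4, 5, 6, 1, 2, 3)
  tr_swap <- make_trial(x[swap], y[swap], onset = 0:5,
                        duration = rep(0.1, 6))
  expect_false(identical(encode_trial(tr_swap, cfg)$counts,
                         encode_trial(tr, cfg)$counts))
})

test_that("dataset encoding preserves row order and declared width", {
  ds <- small_benchmark_dataset(seed = 9)
  cfg <- encoding_config(5, t = 3)
  enc <- encode_dataset(ds, cfg)
  expect_equal(dim(enc$features), c(24, 75))
  expect_equal(enc$label, vapply(ds$trials, `[[`, character(1), "label"))
  # permuting trial order permutes rows identically
  perm <- sample(seq_along(ds$trials))
  ds_perm <- gaze_dataset(ds$trials[perm], device = ds$device)
  enc_perm <- encode_dataset(ds_perm, cfg)
  expect_equal(enc_perm$features, enc$features[perm, ])
  # empty dataset keeps the declared width
  enc0 <- encode_dataset(gaze_dataset(), cfg)
  expect_equal(dim(enc0$features), c(0, 75))
})
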