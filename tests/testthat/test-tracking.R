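obs_df <- function(frames, xs, ys, cell = 1L, area = 0.1) {
  data.frame(cell = cell, frame = frames, area_um2 = area,
             mean_intensity = 1, x_um = xs, y_um = ys, axial = 0.1,
             primary = TRUE)
}

test_that("linking follows the step and gap rules", {
  ## one focus present in all frames: a single trajectory
  o <- obs_df(1:6, seq(1, 1.5, by = 0.1), rep(1, 6))
  l <- link_clusters(o, max_step = 1)
  expect_equal(length(unique(l$traj)), 1L)
  ## absence for one frame with max_gap = 0 splits the trajectory
  o2 <- obs_df(c(1, 2, 4, 5), c(1, 1.1, 1.2, 1.3), rep(1, 4))
  expect_equal(length(unique(link_clusters(o2, 1, 0L)$traj)), 2L)
  expect_equal(length(unique(link_clusters(o2, 1, 1L)$traj)), 1L)
  ## displacement above max_step breaks the link
  o3 <- obs_df(1:3, c(1, 1.2, 5), rep(1, 3))
  expect_equal(length(unique(link_clusters(o3, 1)$traj)), 2L)
})

test_that("linking is permutation-invariant with deterministic ties", {
  set.seed(3)
  o <- rbind(obs_df(1:5, c(1, 1.1, 1.2, 1.1, 1.0), rep(1, 5)),
             obs_df(1:5, c(3, 3.1, 3.0, 3.2, 3.1), rep(1.2, 5)))
  a <- link_clusters(o, 1)
  perm <- sample(nrow(o))
  b <- link_clusters(o[perm, ], 1)
  b <- b[order(as.integer(rownames(b))), ]
  ## same partition of observations into trajectories
  key_a <- split(seq_len(nrow(o)), a$traj)
  key_b <- split(seq_len(nrow(o)), b$traj)
  expect_setequal(unname(vapply(key_a, paste, "", collapse = ",")),
                  unname(vapply(key_b, paste, "", collapse = ",")))
})

test_that("trajectory speed is the path length over elapsed time", {
  ## hand oracle: 0.3 um then 0.4 um over two 10-s steps
  tr <- obs_df(1:3, c(0, 0.3, 0.7), rep(0, 3))
  expect_equal(trajectory_speed(tr, 10), 0.7 / 20)
  ## static focus
  expect_equal(trajectory_speed(obs_df(1:4, rep(1, 4), rep(2, 4)), 10), 0)
  ## singleton: undefined
  expect_true(is.na(trajectory_speed(obs_df(1, 1, 1), 10)))
  ## invariant to time reversal
  tr2 <- obs_df(1:4, c(0, 0.5, 0.2, 0.9), c(0, 0.1, 0.3, 0))
  rev2 <- tr2; rev2$frame <- rev(rev2$frame)
  expect_equal(trajectory_speed(tr2, 10), trajectory_speed(rev2, 10))
})

test_that("pipeline trajectories recover ground-truth focus assignments", {
  fx <- fx_small_pop()
  res <- fx$res; sim <- fx$sim
  mm <- fx$match
  ## for every truth cell with a permanent focus, the matched track must
  ## contain one trajectory covering >= 90% of the present frames at the
  ## true positions
  ## pooled over all ground-truth (frame, focus) assignments: the matched
  ## track's dominant trajectory must contain an observation at the true
  ## position for >= 90% of them
  tt <- sim$truth$cells
  scored <- 0L; hits <- 0L
  for (i in seq_len(nrow(mm))) {
    truth_rows <- tt[tt$cell == mm$truth_cell[i] & tt$cluster_present, ]
    if (nrow(truth_rows) < 5) next
    obs <- res$observations[res$observations$cell == mm$cell[i] &
                              res$observations$primary, ]
    scored <- scored + nrow(truth_rows)
    if (nrow(obs) == 0) next
    main_traj <- as.integer(names(which.max(table(obs$traj))))
    obs <- obs[obs$traj == main_traj, ]
    hits <- hits + sum(vapply(seq_len(nrow(truth_rows)), function(j) {
      o <- obs[obs$frame == truth_rows$frame[j], ]
      nrow(o) == 1 &&
        sqrt((o$x_um - truth_rows$cluster_x_um[j])^2 +
             (o$y_um - truth_rows$cluster_y_um[j])^2) < 0.25
    }, TRUE))
  }
  expect_gt(scored, 100)
  expect_gte(hits / scored, 0.9)
})

test_that("motility-suppressed data show no speed-size correlation", {
  reps <- fx_dnp_multi()
  ps <- vapply(reps, function(r) r$spearman$p_value, 0)
  rhos <- vapply(reps, function(r) r$spearman$coefficient, 0)
  expect_gt(median(ps), 0.05)
  expect_lt(median(abs(rhos)), 0.3)
})
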