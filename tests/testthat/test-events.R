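sdi_track <- function(sdi, present = NULL, cell = 1L, dt_min = 3) {
  n <- length(sdi)
  data.frame(cell = cell, frame = seq_len(n),
             time_min = (seq_len(n) - 1) * dt_min, sdi = sdi,
             cluster_present = if (is.null(present)) sdi > 2 * sdi[1]
               else present)
}

test_that("formation detector fires on the doubling rule", {
  ## oracle: series (10,10,10,25,30), window 3, factor 2 -> event at the
  ## 4th frame with ratio 2.5
  tr <- sdi_track(c(10, 10, 10, 25, 30),
                  present = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ev <- detect_formation_event(tr, jump_factor = 2, baseline_window = 3)
  expect_equal(ev$frame, 4L)
  expect_equal(ev$sdi_ratio, 2.5)
  ## constant series: nothing
  expect_null(detect_formation_event(sdi_track(rep(10, 8),
                                               present = rep(TRUE, 8))))
  ## jump without persistent detection does not count
  tr2 <- sdi_track(c(10, 10, 10, 25, 10),
                   present = c(FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_null(detect_formation_event(tr2))
  expect_error(detect_formation_event(sdi_track(c(1, 2, 3))), "at least")
})

test_that("dispersal detector requires a sustained decline or loss", {
  ## linear decay 40 -> 10 over 10 frames with min_rel_drop 0.5
  tr <- sdi_track(seq(40, 10, length.out = 10), present = rep(TRUE, 10))
  ev <- detect_dispersal(tr, slope_window = 5, min_rel_drop = 0.5)
  expect_false(is.null(ev))
  expect_gte(ev$rel_drop, 0.5)
  ## constant track: nothing
  expect_null(detect_dispersal(sdi_track(rep(30, 10),
                                         present = rep(TRUE, 10))))
  ## disappearance for two frames counts as dispersal
  tr2 <- sdi_track(c(30, 30, 2, 2, 2),
                   present = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(is.null(detect_dispersal(tr2)))
  expect_error(detect_dispersal(sdi_track(c(1, 2), present = c(FALSE, TRUE))),
               "begin with")
})

test_that("event detectors are translation-invariant in time", {
  sdi <- c(10, 10, 10, 25, 30, 28, 30)
  pres <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  a <- detect_formation_event(sdi_track(sdi, pres))
  b_tr <- sdi_track(sdi, pres)
  b_tr$frame <- b_tr$frame + 7L
  b_tr$time_min <- b_tr$time_min + 21
  b <- detect_formation_event(b_tr)
  expect_equal(b$frame - a$frame, 7L)
  expect_equal(b$time_min - a$time_min, 21)
})

test_that("quiescence classes split correctly and monotonically", {
  ## all uniform cells: everything is class none
  t0 <- data.frame(cell = 1:10, sdi = rep(0.2, 10),
                   cluster_present = FALSE)
  q <- classify_quiescence_subpopulations(t0)
  expect_equal(unname(q$fractions["none"]), 1)
  ## bimodal SDI: Otsu separates small from big
  t1 <- data.frame(cell = 1:40,
                   sdi = c(rnorm(25, 5, 0.3), rnorm(15, 20, 0.5)),
                   cluster_present = TRUE)
  q1 <- classify_quiescence_subpopulations(t1)
  expect_equal(unname(q1$fractions["small"]), 25 / 40)
  expect_equal(unname(q1$fractions["big"]), 15 / 40)
  ## raising a cell's SDI never demotes it from big to small
  t2 <- t1; t2$sdi[1] <- 50
  q2 <- classify_quiescence_subpopulations(t2, sdi_big_threshold = q1$threshold)
  expect_equal(q2$classes$class[1], "big")
})

test_that("sister scoring partitions pairs and handles edge cases", {
  tracks <- data.frame(cell = c(1, 1, 2, 2, 3, 3, 4, 4),
                       frame = rep(c(5, 6), 4),
                       cluster_present = c(TRUE, TRUE, FALSE, FALSE,
                                           TRUE, TRUE, TRUE, TRUE),
                       parent = c(0, 0, 0, 0, 9, 9, 9, 9),
                       sister = c(2, 2, 1, 1, 4, 4, 3, 3))
  ss <- sister_cluster_status(tracks)
  expect_equal(ss$n_pairs, 2L)
  expect_equal(ss$one_sister_only + ss$both_sisters, 1)
  expect_equal(ss$one_sister_only, 0.5)
  expect_warning(sister_cluster_status(
    data.frame(cell = 1, frame = 1, cluster_present = TRUE,
               parent = NA, sister = NA)), "no completed divisions")
})

test_that("dispersal and re-formation fractions recover the ground truth", {
  fx <- fx_quiescence_tracks()
  lin <- fx$sim$truth$lineage
  tc <- fx$tracks
  ## score founder cells only (divisions restart the bookkeeping)
  founders <- lin$cell[is.na(lin$parent)]
  disp_truth <- lin$fate[is.na(lin$parent)] == "reform"
  detected_disp <- logical(0); detected_reform <- logical(0)
  for (cid in founders) {
    tr <- tc[tc$cell == cid, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 6 || !tr$cluster_present[1]) next
    ev <- detect_dispersal(tr, slope_window = 4, min_rel_drop = 0.4)
    detected_disp <- c(detected_disp, !is.null(ev))
    if (!is.null(ev)) {
      after <- tr[tr$frame >= ev$frame, ]
      ref <- if (nrow(after) >= 4) detect_formation_event(after) else NULL
      detected_reform <- c(detected_reform, !is.null(ref))
    }
  }
  truth_frac <- mean(disp_truth[lin$class[is.na(lin$parent)] != "none"])
  ## among focus-bearing founders, detected dispersal fraction within
  ## 5 percentage points of the configured dispersing share
  expect_lt(abs(mean(detected_disp) - truth_frac), 0.05)
  ## most detected dispersals re-form within the movie
  expect_gt(mean(detected_reform), 0.5)
})

test_that("formation timing is stochastic and cycle-independent", {
  ## deterministic fixed-phase events give perfect phase correlation
  ev <- data.frame(cell = 1:20, type = "formation",
                   time_min = 10 + (1:20) * 2)
  tracks <- data.frame(cell = 1:20, birth_time = (1:20) * 2,
                       birth_length = rnorm(20, 2.5, 0.2),
                       born_with_cluster = FALSE)
  fts <- formation_timing_stats(ev, tracks)
  expect_equal(sd(fts$formation_times), 0)
  ## exponential nucleation: GOF passes, no length linkage
  cfg <- sim_config(n_cells = 300, n_frames = 2,
                    pattern_weights = c(0, 0, 0, 1), nucleation_rate = 0.02,
                    seed = 55)
  sim <- simulate_population(cfg)
  lin <- sim$truth$lineage
  t0 <- sim$truth$cells[sim$truth$cells$frame == 1, ]
  ev2 <- data.frame(cell = lin$cell, type = "formation",
                    time_min = lin$t_nucleate)
  set.seed(14)
  tracks2 <- data.frame(cell = lin$cell, birth_time = 0,
                        birth_length = t0$length_um[match(lin$cell, t0$cell)],
                        born_with_cluster = FALSE,
                        cycle_duration = rnorm(nrow(lin), 60, 5))
  fts2 <- formation_timing_stats(ev2, tracks2)
  expect_gt(fts2$exp_gof$p.value, 0.01)
  expect_lt(abs(fts2$time_length_cor$coefficient), 3 / sqrt(300))
  ## identical growth law: cycle durations do not differ significantly
  tracks3 <- tracks2
  tracks3$born_with_cluster <- rep(c(TRUE, FALSE), length.out = nrow(tracks3))
  fts3 <- formation_timing_stats(ev2, tracks3)
  expect_gt(fts3$cycle_comparison$p.value, 0.05)
})
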