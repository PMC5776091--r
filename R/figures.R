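## Preconfigured simulate-and-analyze recipes, one per figure analogue.
## Every recipe generates its inputs with the synthetic module, runs the
## measurement pipeline on the rendered images, and returns the recovered
## quantity next to the ground truth. Seeds are fanned out per batch so
## batch count never perturbs another batch's draws.

#' Run a preconfigured figure-analogue recipe
#'
#' @param which One of `"fig1"` (pattern-fraction recovery on 1000 cells),
#'   `"fig1e"` (speed-size Spearman; add `dnp = TRUE` for the
#'   motility-suppressed condition), `"fig2"` (stochastic formation:
#'   event detection and timing), `"fig3"` (FRAP untreated +
#'   translation-inhibited endpoints), `"fig5a"` (quiescence-exit
#'   sub-populations), `"fig5sisters"` (sister-cell inheritance), or
#'   `"fig5cd"` (reporter-versus-clustering correlation).
#' @param seed Integer seed driving every random draw of the recipe.
#' @param ... Recipe-specific overrides (see the individual
#'   `recipe_*` functions).
#' @return The recipe's result list; every recipe reports the measured
#'   quantity, the configured truth, and the sample size.
#' @export
run_figure_suite <- function(which = c("fig1", "fig1e", "fig2", "fig3",
                                       "fig5a", "fig5sisters", "fig5cd"),
                             seed = 1L, ...) {
  which <- match.arg(which)
  switch(which,
         fig1 = recipe_fig1(seed, ...),
         fig1e = recipe_fig1e(seed, ...),
         fig2 = recipe_fig2(seed, ...),
         fig3 = recipe_fig3(seed, ...),
         fig5a = recipe_fig5a(seed, ...),
         fig5sisters = recipe_fig5sisters(seed, ...),
         fig5cd = recipe_fig5cd(seed, ...))
}

## Seed fan-out: deterministic per-batch streams below 2^31.
batch_seed <- function(seed, offset, batch)
  (as.integer(seed) * 97L + offset * 1000L + batch) %% 2000000000L

#' Pattern-fraction recovery (growing cells, 1-min frames over 10 min)
#'
#' Simulates `n_cells` cells at the configured four-pattern mixture in
#' batches, runs the full pipeline, classifies every tracked cell, and
#' compares recovered pattern fractions (and per-cell labels) with ground
#' truth.
#'
#' @param seed Seed.
#' @param n_cells Total population size.
#' @param batch_size Cells per rendered field.
#' @param weights Pattern mixture (non_dyn, dyn_1p, dyn_op, uc).
#' @return List: `fractions` (named, percent), `accuracy` (label accuracy
#'   vs truth), `confusion`, `n`.
#' @export
recipe_fig1 <- function(seed = 1L, n_cells = 1000L, batch_size = 100L,
                        weights = c(0.09, 0.43, 0.11, 0.37)) {
  n_batches <- ceiling(n_cells / batch_size)
  labels <- character(0); truths <- character(0)
  for (b in seq_len(n_batches)) {
    nb <- min(batch_size, n_cells - (b - 1L) * batch_size)
    cfg <- sim_config(n_cells = nb, n_frames = 11, frame_interval = 60,
                      pattern_weights = weights, nucleation_rate = 0,
                      seed = batch_seed(seed, 1L, b))
    sim <- simulate_population(cfg)
    res <- run_analysis(sim$stack)
    mm <- match_tracks_to_truth(res$cells, sim$truth)
    lab <- merge(res$labels, mm, by = "cell")
    lab <- lab[!is.na(lab$label), , drop = FALSE]
    labels <- c(labels, lab$label)
    truths <- c(truths, lab$pattern)
  }
  fr <- population_fractions(labels)
  conf <- table(truth = factor(truths, pattern_levels()),
                called = factor(labels, pattern_levels()))
  list(fractions = 100 * fr$fractions, detectable = 100 * fr$detectable,
       accuracy = mean(labels == truths), confusion = conf,
       n = length(labels))
}

#' Speed-size correlation (10-s frames over 5 min)
#'
#' Speed scale and spot size are drawn per cell from a Gaussian copula at
#' `rank_corr`; foci are rendered, tracked, and each cell's longest
#' trajectory contributes a (speed, mean area) pair.
#'
#' @param seed Seed.
#' @param n_cells Number of foci.
#' @param rank_corr Configured speed-size rank correlation.
#' @param dnp Motility-suppressed mode (size-independent residual speed).
#' @return List: `spearman` (a [correlation()] result), `pairs`
#'   (speed/area table), `configured`, `n`.
#' @export
recipe_fig1e <- function(seed = 1L, n_cells = 120L, rank_corr = -0.78,
                         dnp = FALSE) {
  cfg <- sim_config(n_cells = n_cells, n_frames = 31, frame_interval = 10,
                    pixel_size = 0.065, growth_rate = 0,
                    total_intensity_cv = 0,
                    cell_length_range = c(3.5, 3.5),
                    cluster_fraction_range = c(0.5, 0.5),
                    pattern_weights = c(0, 0, 1, 0),
                    nucleation_rate = 0,
                    speed_area_rank_corr = rank_corr,
                    motility_suppressed = dnp,
                    seed = batch_seed(seed, 2L, 1L))
  sim <- simulate_population(cfg)
  res <- run_analysis(sim$stack)
  tr <- res$trajectories[!is.na(res$trajectories$speed_um_s), , drop = FALSE]
  ## one pair per cell: its longest trajectory
  tr <- do.call(rbind, lapply(split(tr, tr$cell), function(d)
    d[which.max(d$n_obs), ]))
  sp <- correlation(tr$speed_um_s, tr$mean_area_um2, method = "spearman")
  list(spearman = sp, pairs = tr, configured = rank_corr, n = nrow(tr))
}

#' Stochastic focus formation (3-min frames over 60 min)
#'
#' All cells start focus-free and nucleate with the configured exponential
#' rate; the pipeline's SDI time series feed the formation-event detector,
#' which is scored against ground-truth nucleation times.
#'
#' Only events that are detectable in principle are scored: the onset
#' must leave at least `baseline_window` frames of pre-formation baseline
#' and two frames of post-formation track (a windowed jump detector
#' cannot, by construction, place an event inside its own baseline).
#'
#' @param seed Seed.
#' @param n_cells Population size.
#' @param rate Nucleation rate, events/min.
#' @param tol_frames Detection counts as a hit within this many frames of
#'   the true onset.
#' @return List: `events` (detected), `truth_events`, `hit_rate` (within
#'   +/- `tol_frames` of truth among scorable events), `mi_change`
#'   (relative MI change across detected events), `n`.
#' @export
recipe_fig2 <- function(seed = 1L, n_cells = 100L, rate = 0.015,
                        tol_frames = 2L) {
  cfg <- sim_config(n_cells = n_cells, n_frames = 21, frame_interval = 180,
                    pattern_weights = c(0, 0, 0, 1),
                    nucleation_rate = rate, growth_rate = 0.01,
                    division_length = 8,
                    seed = batch_seed(seed, 3L, 1L))
  sim <- simulate_population(cfg)
  res <- run_analysis(sim$stack)
  mm <- match_tracks_to_truth(res$cells, sim$truth)
  ev_truth <- sim$truth$events
  ev_truth <- ev_truth[ev_truth$type == "formation", , drop = FALSE]
  dt_min <- cfg$frame_interval / 60
  hits <- 0L; n_scored <- 0L; mi_changes <- numeric(0)
  detected <- list()
  for (i in seq_len(nrow(mm))) {
    tr <- res$cells[res$cells$cell == mm$cell[i], , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    track <- data.frame(cell = tr$cell, frame = tr$frame,
                        time_min = (tr$frame - 1) * dt_min,
                        sdi = tr$sdi, cluster_present = tr$cluster_present)
    ev <- detect_formation_event(track)
    te <- ev_truth$time_min[ev_truth$cell == mm$truth_cell[i]]
    ## scorable: a full baseline before onset, two frames after
    te <- te[te >= 3 * dt_min & te <= (cfg$n_frames - 2) * dt_min]
    if (length(te)) {
      n_scored <- n_scored + 1L
      if (!is.null(ev)) {
        truth_frame <- floor(te[1] / dt_min) + 1
        if (abs(ev$frame - truth_frame) <= tol_frames) hits <- hits + 1L
        pre <- tr$mi[tr$frame < ev$frame]
        post <- tr$mi[tr$frame >= ev$frame]
        if (length(pre) && length(post))
          mi_changes <- c(mi_changes,
                          abs(mean(post) - mean(pre)) / mean(pre))
        detected[[length(detected) + 1L]] <- ev
      }
    }
  }
  list(events = if (length(detected)) do.call(rbind, detected) else NULL,
       truth_events = ev_truth,
       hit_rate = if (n_scored) hits / n_scored else NA_real_,
       mi_change = mi_changes, n = n_scored)
}

#' FRAP recovery endpoints (10-s frames over 600 s)
#'
#' Simulates untreated and translation-inhibited bleach stacks whose
#' analytic recovery at `t_end` equals the configured endpoints, runs the
#' full measurement chain, and reports the pipeline's mean recovery at
#' `t_end`.
#'
#' @param seed Seed.
#' @param endpoint_untreated,endpoint_cm Target recovery (percent) at
#'   `t_end` for the two conditions.
#' @param n_untreated,n_cm Replicate cells.
#' @param k Exchange rate, 1/s.
#' @return List with per-condition results (`recovered`, `truth_endpoint`,
#'   `mean_curve`, `fit`), and `t_end`.
#' @export
recipe_fig3 <- function(seed = 1L, endpoint_untreated = 6,
                        endpoint_cm = 4, n_untreated = 14L, n_cm = 12L,
                        k = 0.005, t_end = 600) {
  run_one <- function(endpoint, n, offset) {
    A <- endpoint / (1 - exp(-k * t_end))
    cfg <- sim_config(n_cells = n, growth_rate = 0,
                      cell_length_range = c(3.2, 4.2),
                      frap = list(n_prebleach = 5, bleach_efficiency = 0.9,
                                  exchange_rate = k, recovery_asymptote = A,
                                  duration = t_end, interval = 10),
                      seed = batch_seed(seed, 4L, offset))
    sim <- simulate_frap_stack(cfg)
    res <- analyze_frap_stack(sim$stack, cfg$frap$n_prebleach)
    list(recovered = recovery_fraction_at(res$mean_curve, t_end),
         truth_endpoint = endpoint, n = length(res$curves),
         mean_curve = res$mean_curve,
         fit = fit_exponential_recovery(res$mean_curve))
  }
  list(untreated = run_one(endpoint_untreated, n_untreated, 1L),
       cm = run_one(endpoint_cm, n_cm, 2L), t_end = t_end)
}

#' Quiescence-exit sub-populations at time 0
#'
#' Simulates an overnight-exit population with the configured
#' (none, small, big) class mixture, measures SDI and focus presence on
#' the first frame, and classifies with the Otsu SDI threshold.
#'
#' @param seed Seed.
#' @param n_cells Population size.
#' @param class_weights Time-0 class mixture.
#' @return List: `fractions` (percent over none/small/big), `accuracy`,
#'   `threshold`, `n`.
#' @export
recipe_fig5a <- function(seed = 1L, n_cells = 269L,
                         class_weights = c(0.13, 0.64, 0.23)) {
  cfg <- sim_config(n_cells = n_cells, n_frames = 2, frame_interval = 900,
                    growth_rate = 0, nucleation_rate = 0,
                    total_intensity_cv = 0.1,
                    seed = batch_seed(seed, 5L, 1L))
  sim <- simulate_quiescence_exit(cfg, class_weights = class_weights)
  res <- run_analysis(sim$stack)
  mm <- match_tracks_to_truth(res$cells, sim$truth)
  t0 <- res$cells[res$cells$frame == 1L, , drop = FALSE]
  t0 <- merge(t0, mm, by = "cell")
  q <- classify_quiescence_subpopulations(
    data.frame(cell = t0$cell, sdi = t0$sdi,
               cluster_present = t0$cluster_present))
  truth_class <- ifelse(t0$class == "none", "none",
                        ifelse(t0$class == "big", "big", "small"))
  called <- q$classes$class[match(t0$cell, q$classes$cell)]
  list(fractions = 100 * q$fractions, threshold = q$threshold,
       accuracy = mean(called == truth_class), n = q$n)
}

#' Sister-cell focus inheritance over one division
#'
#' Simulates mothers that each divide once during a 3-h movie (15-min
#' frames) with nucleation disabled, tracks the daughters, and scores
#' focus presence per sister pair at the final frame.
#'
#' @param seed Seed.
#' @param n_divisions Number of mother cells.
#' @param p_single Probability the focus goes entirely to one daughter.
#' @param batch_size Cells per rendered field.
#' @return List: `one_sister_only`, `both_sisters` (fractions), `n_pairs`,
#'   `configured`, `truth_one_sister` (ground-truth realized fraction).
#' @export
recipe_fig5sisters <- function(seed = 1L, n_divisions = 200L,
                               p_single = 0.72, batch_size = 100L) {
  n_batches <- ceiling(n_divisions / batch_size)
  ones <- 0L; boths <- 0L; truth_one <- 0L; truth_pairs <- 0L
  for (b in seq_len(n_batches)) {
    nb <- min(batch_size, n_divisions - (b - 1L) * batch_size)
    cfg <- sim_config(n_cells = nb, n_frames = 13, frame_interval = 900,
                      growth_rate = 0.005,
                      cell_length_range = c(4.25, 4.75),
                      pattern_weights = c(0, 1, 0, 0),
                      nucleation_rate = 0, inherit_single_prob = p_single,
                      cluster_fraction_range = c(0.3, 0.5),
                      seed = batch_seed(seed, 6L, b))
    sim <- simulate_population(cfg)
    res <- run_analysis(sim$stack)
    ss <- sister_cluster_status(res$cells)
    if (ss$n_pairs > 0) {
      inf <- sum(xor(ss$pairs$a_present, ss$pairs$b_present)) +
        sum(ss$pairs$a_present & ss$pairs$b_present)
      ones <- ones + sum(xor(ss$pairs$a_present, ss$pairs$b_present))
      boths <- boths + sum(ss$pairs$a_present & ss$pairs$b_present)
    }
    ## ground-truth realized inheritance
    lin <- sim$truth$lineage
    dts <- lin[!is.na(lin$sister), , drop = FALSE]
    dts <- dts[dts$cell < dts$sister, , drop = FALSE]
    last <- sim$truth$cells[sim$truth$cells$frame == cfg$n_frames, ]
    for (i in seq_len(nrow(dts))) {
      pa <- last$cluster_present[last$cell == dts$cell[i]]
      pb <- last$cluster_present[last$cell == dts$sister[i]]
      if (length(pa) && length(pb)) {
        truth_pairs <- truth_pairs + 1L
        if (xor(pa, pb)) truth_one <- truth_one + 1L
      }
    }
  }
  tot <- ones + boths
  list(one_sister_only = if (tot) ones / tot else NA_real_,
       both_sisters = if (tot) boths / tot else NA_real_,
       n_pairs = tot, configured = p_single,
       truth_one_sister = if (truth_pairs) truth_one / truth_pairs
         else NA_real_)
}

#' Reporter-versus-clustering correlation
#'
#' Simulates a snapshot population with a continuous clustering margin,
#' attaches the reporter channel at the configured copula rank
#' correlation, quantifies both channels per cell, and reports the
#' Pearson correlation of reporter MI against fluorophore SDI.
#'
#' @param seed Seed.
#' @param n_cells Population size.
#' @param rho Configured rank correlation (0 for the null condition).
#' @return List: `pearson` (a [correlation()] result), `configured`, `n`.
#' @export
recipe_fig5cd <- function(seed = 1L, n_cells = 500L, rho = -0.16) {
  cfg <- sim_config(n_cells = n_cells, n_frames = 2, frame_interval = 60,
                    growth_rate = 0, nucleation_rate = 0,
                    total_intensity_cv = 0.05,
                    cell_length_range = c(3.0, 3.4),
                    cluster_fraction_range = c(0.19, 0.51),
                    cluster_fraction_dist = "normal",
                    pattern_weights = c(0, 1, 0, 0),
                    reporter_rank_corr = rho,
                    seed = batch_seed(seed, 7L, 1L))
  sim <- simulate_population(cfg)
  sim <- simulate_reporter_channel(sim, cfg)
  res <- run_analysis(sim$stack)
  t0 <- res$cells[res$cells$frame == 1L, c("cell", "reporter_mi", "sdi")]
  rv <- reporter_vs_clustering(t0)
  list(pearson = rv$cor, scatter = rv$scatter, configured = rho,
       n = nrow(t0))
}
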