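test_that("degenerate pattern weights produce an all-diffuse population", {
  cfg <- sim_config(n_cells = 12, n_frames = 4,
                    pattern_weights = c(0, 0, 0, 1), nucleation_rate = 0,
                    seed = 2)
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth$cells$pattern == "uc"))
  expect_true(all(!sim$truth$cells$cluster_present))
  expect_true(all(sim$truth$cells$cluster_frac == 0))
})

test_that("ground-truth label fractions match the configured mixture", {
  cfg <- sim_config(n_cells = 1000, n_frames = 2,
                    pattern_weights = c(0.09, 0.43, 0.11, 0.37),
                    nucleation_rate = 0, seed = 3)
  sim <- simulate_population(cfg)
  lab <- sim$truth$cells[sim$truth$cells$frame == 1, "pattern"]
  fr <- as.numeric(table(factor(lab, polefocus:::pattern_levels()))) / 1000
  ## within 3 binomial SDs of the weights (exact by allocation)
  sds <- sqrt(c(0.09, 0.43, 0.11, 0.37) *
              (1 - c(0.09, 0.43, 0.11, 0.37)) / 1000)
  expect_true(all(abs(fr - c(0.09, 0.43, 0.11, 0.37)) <= 3 * sds))
})

test_that("per-cell budget is conserved across a formation event", {
  ## noise-free, background-free render; the whole-field fluorophore sum
  ## must track the summed budgets to well under 0.1% at every frame
  cfg <- sim_config(n_cells = 6, n_frames = 12, frame_interval = 180,
                    pattern_weights = c(0, 0, 0, 1), nucleation_rate = 0.05,
                    background_level = 0, read_noise_frac = 0,
                    growth_rate = 0, seed = 5)
  sim <- simulate_population(cfg)
  formed <- subset(sim$truth$events, type == "formation")
  expect_gt(nrow(formed), 0)
  for (k in seq_len(cfg$n_frames)) {
    total <- sum(sim$stack$frames[[k]][, , 2])
    budget <- sum(sim$truth$cells$budget[sim$truth$cells$frame == k])
    expect_lt(abs(total - budget) / budget, 1e-3)
  }
})

test_that("rendered cells honour the image-formation contract", {
  cfg <- sim_config(seed = 1)
  ## no focus: uniform fill, zero SD over the mask
  st <- list(cx = 3, cy = 1.2, length = 3.5, width = 1, budget = 1000,
             cluster_frac = 0, sigma = 0.2)
  p <- render_cell_frame(st, cfg, 1:24, 1:60)
  expect_equal(sd(p$fluor[p$mask]), 0)
  expect_equal(sum(p$fluor), 1000)
  ## focus: spot-attributable intensity equals its budget share exactly
  st$cluster_frac <- 0.5
  st$cluster_x <- 3 - 1.4; st$cluster_y <- 1.2
  p2 <- render_cell_frame(st, cfg, 1:24, 1:60)
  diffuse <- 1000 * 0.5 / sum(p2$mask)
  spot_sum <- sum(p2$fluor[p2$mask] - diffuse)
  expect_equal(spot_sum, 500, tolerance = 1e-6)
  ## focus centroid outside the mask is a state error
  st$cluster_x <- 3 + 5
  expect_error(render_cell_frame(st, cfg, 1:24, 1:60), "outside the cell")
  ## overlapping masks are rejected at field assembly
  s1 <- list(id = 1, cx = 2, cy = 1.2, length = 3, width = 1,
             budget = 500, cluster_frac = 0, sigma = 0.2)
  s2 <- s1; s2$id <- 2; s2$cx <- 3.5
  expect_error(polefocus:::render_field_frame(list(s1, s2), c(30, 80), cfg),
               "overlap")
})

test_that("nucleation waiting times are exponential and length-independent", {
  cfg <- sim_config(n_cells = 500, n_frames = 2,
                    pattern_weights = c(0, 0, 0, 1), nucleation_rate = 0.02,
                    seed = 8)
  sim <- simulate_population(cfg)
  lin <- sim$truth$lineage
  waits <- lin$t_nucleate[is.finite(lin$t_nucleate)]
  expect_equal(length(waits), 500L)
  gof <- ks.test(waits, "pexp", rate = 0.02)
  expect_gt(gof$p.value, 0.01)
  ## independent of birth length
  t0 <- sim$truth$cells[sim$truth$cells$frame == 1, ]
  r <- cor(waits[t0$cell], t0$length_um, method = "spearman")
  expect_lt(abs(r), 3 / sqrt(500))
})

test_that("generated focus speed follows the configured power law", {
  cfg <- sim_config(n_cells = 200, n_frames = 3,
                    pattern_weights = c(0, 0.5, 0.5, 0), nucleation_rate = 0,
                    seed = 9)
  sim <- simulate_population(cfg)
  tc <- sim$truth$cells[sim$truth$cells$frame == 2, ]
  tc <- tc[tc$speed_um_s > 0, ]
  fit <- lm(log(speed_um_s) ~ log(cluster_area_um2), data = tc)
  slope <- coef(fit)[2]
  ## the generator's power law is exact, so the fit is near-perfect
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  expect_lt(abs(slope - (-cfg$speed_exponent)), max(2 * se, 1e-6))
})

test_that("fixed seeds give bit-identical stacks and truth", {
  cfg <- sim_config(n_cells = 8, n_frames = 5, seed = 123)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("division splits the mother and inheritance obeys p_single = 1", {
  cfg <- sim_config(n_cells = 10, n_frames = 8, frame_interval = 900,
                    growth_rate = 0.005, cell_length_range = c(4.5, 4.8),
                    pattern_weights = c(0, 1, 0, 0), nucleation_rate = 0,
                    inherit_single_prob = 1, seed = 13)
  sim <- simulate_population(cfg)
  lin <- sim$truth$lineage
  daughters <- lin[!is.na(lin$parent), ]
  expect_gt(nrow(daughters), 0)
  ## every divided cell has exactly one sister, and sister ids are mutual
  expect_true(all(table(daughters$parent) == 2))
  for (i in seq_len(nrow(daughters)))
    expect_equal(lin$sister[lin$cell == daughters$sister[i]],
                 daughters$cell[i])
  ## with p_single = 1, exactly one daughter per pair carries the focus
  last <- sim$truth$cells[sim$truth$cells$frame == cfg$n_frames, ]
  pairs <- daughters[daughters$cell < daughters$sister, ]
  for (i in seq_len(nrow(pairs))) {
    pa <- last$cluster_present[last$cell == pairs$cell[i]]
    pb <- last$cluster_present[last$cell == pairs$sister[i]]
    if (length(pa) && length(pb)) expect_true(xor(pa, pb))
  }
})

test_that("reporter channel honours the configured dependence at the limits", {
  base <- sim_config(n_cells = 60, n_frames = 2, growth_rate = 0,
                     nucleation_rate = 0, pattern_weights = c(0, 1, 0, 0),
                     read_noise_frac = 0, background_level = 0, seed = 21)
  ## perfectly anti-monotone limit
  cfg <- base; cfg$reporter_rank_corr <- -1
  sim <- simulate_reporter_channel(simulate_population(cfg), cfg)
  rep <- sim$truth$reporter
  expect_equal(cor(rep$clustering, rep$reporter_mean, method = "spearman"),
               -1)
  ## independence: sample rank correlation within 3 SEs of 0 at n = 300
  cfg2 <- sim_config(n_cells = 300, n_frames = 2, growth_rate = 0,
                     nucleation_rate = 0, pattern_weights = c(0, 1, 0, 0),
                     reporter_rank_corr = 0, seed = 22)
  sim2 <- simulate_reporter_channel(simulate_population(cfg2), cfg2)
  r <- cor(sim2$truth$reporter$clustering,
           sim2$truth$reporter$reporter_mean, method = "spearman")
  expect_lt(abs(r), 3 / sqrt(300))
})
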