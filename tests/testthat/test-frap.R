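test_that("recovery normalization follows the stated formula", {
  ## hand oracle: Fpre = 100, F(0+) = 10, F(600) = 15.4 -> 6.0%
  pole <- c(10, rep(12, 59), 15.4)
  cv <- normalize_recovery_curve(pole, 1, prebleach_value = 100,
                                 interval = 10)
  expect_equal(cv$recovery[1], 0)
  expect_equal(cv$recovery[length(cv$recovery)], 6.0)
  expect_equal(max(cv$times), 600)
  ## constant post-bleach series: recovery identically 0
  cv0 <- normalize_recovery_curve(rep(10, 10), 1, 100, 10)
  expect_true(all(cv0$recovery == 0))
  ## invariant to a global intensity rescale
  cv2 <- normalize_recovery_curve(7.3 * pole, 7.3, 100, 10)
  expect_equal(cv2$recovery, cv$recovery, tolerance = 1e-12)
  ## nothing bleached is an error
  expect_error(normalize_recovery_curve(c(100, 101), 1, 50, 10),
               "bleached")
  expect_error(normalize_recovery_curve(10, 1, 100, 10), "at least 2")
})

test_that("recovery interpolation is linear and bounded", {
  cv <- structure(list(times = c(0, 10, 20), recovery = c(0, 4, 8)),
                  class = "frap_curve")
  expect_equal(recovery_fraction_at(cv, 10), 4)    # exact grid point
  expect_equal(recovery_fraction_at(cv, 15), 6)    # midpoint of 4 and 8
  expect_error(recovery_fraction_at(cv, 25), "span")
})

test_that("exponential fit recovers its generating parameters", {
  t <- seq(0, 600, by = 10)
  y <- 10 * (1 - exp(-0.005 * t))
  fit <- fit_exponential_recovery(list(times = t, recovery = y))
  expect_true(fit$converged)
  expect_equal(fit$A, 10, tolerance = 1e-6)
  expect_equal(fit$k, 0.005, tolerance = 1e-6)
  ## 2% noise, 61 points: within 10% of truth
  set.seed(19)
  yn <- y + rnorm(length(y), 0, 0.02 * 10)
  fitn <- fit_exponential_recovery(list(times = t, recovery = yn))
  expect_lt(abs(fitn$A - 10) / 10, 0.1)
  expect_lt(abs(fitn$k - 0.005) / 0.005, 0.1)
  ## degenerate all-zero curve is flagged
  fit0 <- fit_exponential_recovery(list(times = t, recovery = 0 * t))
  expect_false(fit0$converged)
  expect_equal(fit0$A, 0)
  expect_error(fit_exponential_recovery(list(times = 1:3,
                                             recovery = c(0, 1, 2))),
               "at least 5")
})

test_that("no-exchange stacks show zero recovery through the pipeline", {
  cfg <- sim_config(n_cells = 3, growth_rate = 0, read_noise_frac = 0,
                    frap = list(n_prebleach = 3, bleach_efficiency = 0.9,
                                exchange_rate = 0, recovery_asymptote = 6,
                                duration = 200, interval = 10),
                    seed = 4)
  sim <- simulate_frap_stack(cfg)
  ## analytic truth is identically zero
  expect_true(all(sim$truth$recovery$recovery == 0))
  res <- analyze_frap_stack(sim$stack, 3)
  expect_lt(max(abs(res$mean_curve$recovery)), 0.2)
})

test_that("analytic recovery curve obeys its closed form", {
  k <- 0.004; A <- 8
  cfg <- sim_config(n_cells = 2,
                    frap = list(n_prebleach = 2, bleach_efficiency = 0.9,
                                exchange_rate = k, recovery_asymptote = A,
                                duration = 600, interval = 10),
                    seed = 6)
  sim <- simulate_frap_stack(cfg)
  tr <- sim$truth$recovery
  ## value at t = 1/k equals A (1 - e^-1)
  v <- approx(tr$time_s, tr$recovery, xout = 1 / k)$y
  expect_equal(v, A * (1 - exp(-1)), tolerance = 1e-3)
})

test_that("replicate averaging shrinks the endpoint standard error", {
  set.seed(23)
  mk <- function() {
    y <- 6 * (1 - exp(-0.005 * seq(0, 600, 10))) + rnorm(61, 0, 0.5)
    structure(list(times = seq(0, 600, 10), recovery = y),
              class = "frap_curve")
  }
  c4 <- average_frap_curves(replicate(4, mk(), simplify = FALSE))
  c16 <- average_frap_curves(replicate(16, mk(), simplify = FALSE))
  ## SE at the endpoint scales roughly as 1/sqrt(n)
  expect_lt(mean(c16$se), mean(c4$se))
  expect_equal(mean(c4$se) / mean(c16$se), 2, tolerance = 0.75)
})

test_that("translation inhibition lowers recovery but not early kinetics", {
  r <- recipe_fig3(seed = 2, n_untreated = 4, n_cm = 4)
  expect_gt(r$untreated$recovered, r$cm$recovered)
  ## similar early pace: fitted exchange rates agree within 25%
  expect_lt(abs(r$untreated$fit$k - r$cm$fit$k) / r$untreated$fit$k, 0.25)
})
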