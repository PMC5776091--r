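## FRAP-stack generator and the activity-reporter channel.

#' Simulate a FRAP bleach-and-recovery stack
#'
#' Renders `config$n_cells` static cells, each with one non-dynamic polar
#' focus, acquires `frap$n_prebleach` prebleach frames, then bleaches the
#' focus-bearing pole region (all pixels within 0.35 of the normalized
#' axis at that pole are multiplied by `1 - bleach_efficiency`) and
#' acquires frames every `frap$interval` seconds for `frap$duration`
#' seconds. Recovery follows the analytic curve
#' `A * (1 - exp(-k t))` percent of the bleached-away signal, applied
#' per pixel in drift-corrected units, with the unbleached cell region
#' losing what the pole gains so the whole-cell total stays constant
#' (exchange with the diffuse pool). Any sub-ROI of the bleached zone
#' therefore carries the same normalized recovery curve.
#'
#' @param config A [sim_config()]; `frap$recovery_asymptote` is the total
#'   recovery asymptote A (percent; in the untreated condition it
#'   includes the de-novo-synthesis contribution, in the
#'   translation-inhibited condition that contribution is removed by
#'   configuring a smaller A), `frap$exchange_rate` is k (1/s).
#' @return List with `stack` (channels `phase`, `mcherry`), and `truth`
#'   containing the analytic `recovery` curve (times s, percent), the
#'   per-cell bleach ROI masks, `n_prebleach`, and a config echo.
#' @export
simulate_frap_stack <- function(config) {
  config <- validate_sim_config(config)
  fr <- config$frap
  if (fr$bleach_efficiency <= 0 || fr$bleach_efficiency > 1)
    stop("bleach_efficiency must lie in (0, 1]")
  set.seed(config$seed + 1L)
  ps <- config$pixel_size
  layout <- tile_layout(config)
  n <- config$n_cells
  n_post <- floor(fr$duration / fr$interval) + 1L
  n_frames <- fr$n_prebleach + n_post
  times_post <- (seq_len(n_post) - 1) * fr$interval
  A_t <- fr$recovery_asymptote * (1 - exp(-fr$exchange_rate * times_post))

  cells <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- ((i - 1) %/% layout$ncol) + 1
    tc <- ((i - 1) %% layout$ncol) + 1
    cl <- new_cell(i, tr, tc, layout, config, "non_dyn")
    cl$f_final <- stats::runif(1, max(0.4, config$cluster_fraction_range[1]),
                               config$cluster_fraction_range[2])
    cl$f_now <- cl$f_final
    cells[[i]] <- cl
  }
  states <- lapply(cells, function(cl) {
    L <- cl$L0
    list(id = cl$id, cx = cl$cx, cy = cl$cy, length = L, width = cl$width,
         budget = cl$bpu * L, cluster_frac = cl$f_now, sigma = cl$sigma,
         cluster_x = cl$cx - cl$flip * L / 2 + cl$flip * cl$s,
         cluster_y = cl$cy + cl$u, flip = cl$flip)
  })
  fld <- render_field_frame(states, layout$dim_hw, config)
  est_mean <- vapply(states, function(st) {
    npx <- sum(fld$labels == st$id)
    st$budget / npx
  }, 0)
  noise_sd <- config$read_noise_frac * stats::median(est_mean)

  ## per-cell bleach zone: pixels within 0.35 of the axis at the focus pole
  bleach_masks <- vector("list", n)
  for (st in states) {
    idx <- which(fld$labels == st$id)
    cc <- (idx - 1L) %/% nrow(fld$labels) + 1L
    xs <- (cc - 0.5) * ps
    ax <- (xs - (st$cx - st$length / 2)) / st$length  # 0 = left tip
    ## the focus sits at pole 1 (left tip if flip > 0, right tip otherwise)
    bleach_masks[[st$id]] <- idx[if (st$flip > 0) ax <= 0.35 else ax >= 0.65]
  }

  base <- fld$fluor
  frames <- vector("list", n_frames)
  for (k in seq_len(fr$n_prebleach)) {
    arr <- array(0, dim = c(layout$dim_hw, 2L))
    arr[, , 1] <- apply_camera(fld$body, config$background_level, noise_sd)
    arr[, , 2] <- apply_camera(base, config$background_level, noise_sd)
    frames[[k]] <- arr
  }
  ## post-bleach evolution, per pixel and per cell
  post0 <- base
  for (i in seq_len(n)) {
    bm <- bleach_masks[[i]]
    post0[bm] <- post0[bm] * (1 - fr$bleach_efficiency)
  }
  cell_px <- lapply(seq_len(n), function(i) which(fld$labels == i))
  for (j in seq_len(n_post)) {
    img <- post0
    for (i in seq_len(n)) {
      bm <- bleach_masks[[i]]
      allpx <- cell_px[[i]]
      T_pre <- sum(base[allpx]); T_post <- sum(post0[allpx])
      cfac <- T_post / T_pre
      gain_px <- (A_t[j] / 100) * (cfac * base[bm] - post0[bm])
      img[bm] <- post0[bm] + gain_px
      others <- setdiff(allpx, bm)
      U0 <- sum(post0[others])
      if (U0 > 0)
        img[others] <- post0[others] * (U0 - sum(gain_px)) / U0
    }
    arr <- array(0, dim = c(layout$dim_hw, 2L))
    arr[, , 1] <- apply_camera(fld$body, config$background_level, noise_sd)
    arr[, , 2] <- apply_camera(img, config$background_level, noise_sd)
    frames[[fr$n_prebleach + j]] <- arr
  }
  stack <- image_stack(frames, c("phase", "mcherry"), ps, fr$interval)
  truth <- list(recovery = data.frame(time_s = times_post, recovery = A_t),
                n_prebleach = fr$n_prebleach, bleach_masks = bleach_masks,
                noise_sd = noise_sd, config = config)
  list(stack = stack, truth = truth)
}

#' Attach an activity-reporter channel to a simulated population
#'
#' Draws a per-cell reporter mean from a Gaussian copula with the
#' configured rank correlation against the cell's true clustering level
#' (the time-0 focus budget share), then renders it as a uniform fill
#' over each cell mask plus the camera model. The copula realizes the
#' configured correlation exactly in the latent sample (see the methods
#' vignette), so `reporter_rank_corr = -1` gives a perfectly anti-monotone
#' pairing.
#'
#' @param sim Result of [simulate_population()] (its stack gains a third
#'   channel named `reporter`).
#' @param config The [sim_config()] used; `reporter_rank_corr` sets the
#'   dependence, `reporter_mean`/`reporter_cv` (optional list entries,
#'   defaults 500 and 0.15) the marginal scale.
#' @return `sim` with the extended stack and a `truth$reporter` data.frame
#'   (cell, clustering level, true reporter mean).
#' @export
simulate_reporter_channel <- function(sim, config) {
  rho <- config$reporter_rank_corr
  if (abs(rho) > 1) stop("reporter_rank_corr must lie in [-1, 1]")
  set.seed(config$seed + 2L)
  rep_mean <- config$reporter_mean %||% 500
  rep_cv <- config$reporter_cv %||% 0.15
  t0 <- sim$truth$cells[sim$truth$cells$frame == 1L, , drop = FALSE]
  n <- nrow(t0)
  ## latent score of the clustering level: normal scores of its ranks
  r <- rank(t0$cluster_frac, ties.method = "first")
  z1 <- stats::qnorm(r / (n + 1))
  z1 <- (z1 - mean(z1)) / stats::sd(z1)
  z2 <- stats::rnorm(n)
  z2 <- stats::residuals(stats::lm(z2 ~ z1))
  z2 <- z2 / stats::sd(z2)
  lat <- if (abs(rho) == 1) sign(rho) * z1
    else rho * z1 + sqrt(1 - rho^2) * z2
  rep_true <- rep_mean * (1 + rep_cv * lat)
  rep_true <- pmax(rep_true, 0.05 * rep_mean)
  truth_rep <- data.frame(cell = t0$cell, clustering = t0$cluster_frac,
                          reporter_mean = rep_true)
  ## render: uniform fill per cell over the first frame's masks
  layout <- sim$truth$layout
  cfg2 <- config
  frames <- sim$stack$frames
  noise_sd <- config$read_noise_frac * rep_mean
  for (k in seq_along(frames)) {
    tk <- sim$truth$cells[sim$truth$cells$frame == k, , drop = FALSE]
    img <- matrix(0, layout$dim_hw[1], layout$dim_hw[2])
    for (i in seq_len(nrow(tk))) {
      st <- list(cx = tk$cx_um[i], cy = tk$cy_um[i],
                 length = tk$length_um[i], width = config$cell_width)
      bb <- cell_bbox(st$cx, st$cy, st$length, st$width, config$pixel_size,
                      layout$dim_hw)
      msk <- rod_mask(bb$rows, bb$cols, st$cx, st$cy, st$length, st$width,
                      config$pixel_size)
      v <- truth_rep$reporter_mean[truth_rep$cell == tk$cell[i]]
      if (length(v) == 0L) v <- rep_mean   # cells born after frame 1
      sub <- img[bb$rows, bb$cols]
      sub[msk] <- v
      img[bb$rows, bb$cols] <- sub
    }
    img <- apply_camera(img, config$background_level, noise_sd)
    d <- dim(frames[[k]])
    arr <- array(0, dim = c(d[1], d[2], d[3] + 1L))
    arr[, , seq_len(d[3])] <- frames[[k]]
    arr[, , d[3] + 1L] <- img
    frames[[k]] <- arr
  }
  sim$stack <- image_stack(frames, c(sim$stack$channels, "reporter"),
                           sim$stack$pixel_size, sim$stack$frame_interval)
  sim$truth$reporter <- truth_rep
  sim
}
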