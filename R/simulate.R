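## Synthetic time-lapse generator: rod-shaped cells on a tile grid, each
## carrying a fluorophore budget split between a diffuse pool and at most
## one compact polar focus. Ground truth records everything the pipeline
## later has to recover.

## Ground-truth focus footprint: the 1/e isophote of the Gaussian spot
## (radius sigma * sqrt(2)), which contains 1 - 1/e of the spot signal.
spot_area <- function(sigma) 2 * pi * sigma^2

draw_cluster_fraction <- function(config) {
  rng <- config$cluster_fraction_range
  if (identical(config$cluster_fraction_dist, "normal")) {
    f <- stats::rnorm(1, mean(rng), diff(rng) / 4)
    min(max(f, 0.02), 0.8)
  } else {
    stats::runif(1, rng[1], rng[2])
  }
}

## Fold x into [lo, hi] by reflection.
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

## Tile layout for n cells; tiles are sized so a dividing mother and both
## daughters always fit. Returns rows/cols of the grid and tile size in px.
tile_layout <- function(config) {
  ps <- config$pixel_size
  tile_w <- ceiling((config$division_length + 1.4) / ps)
  tile_h <- ceiling((config$cell_width * 2.4) / ps)
  ncol_t <- ceiling(sqrt(config$n_cells))
  nrow_t <- ceiling(config$n_cells / ncol_t)
  dim_hw <- c(nrow_t * tile_h, ncol_t * tile_w)
  if (!is.null(config$image_shape)) {
    if (config$image_shape[1] < dim_hw[1] || config$image_shape[2] < dim_hw[2])
      stop("image_shape too small for the cell geometry and cell count")
    dim_hw <- config$image_shape
  }
  list(nrow = nrow_t, ncol = ncol_t, tile_h = tile_h, tile_w = tile_w,
       dim_hw = dim_hw)
}

## Per-pattern spot-width multiplier: static foci are the largest, foci
## that escape the pole zone the smallest (size-mobility coupling).
sigma_mult <- c(non_dyn = 1.35, dyn_1p = 1.0, dyn_op = 0.7, uc = 1.0)

new_cell <- function(id, tile_r, tile_c, layout, config, pattern,
                     birth_time = 0, birth_frame = 1L,
                     parent = NA_integer_, sister = NA_integer_,
                     L0 = NULL, flip = NULL, bpu = NULL) {
  ps <- config$pixel_size
  cy <- (tile_r - 0.5) * layout$tile_h * ps
  cx <- (tile_c - 0.5) * layout$tile_w * ps
  if (is.null(L0)) L0 <- stats::runif(1, config$cell_length_range[1],
                                      config$cell_length_range[2])
  if (is.null(flip)) flip <- sample(c(-1, 1), 1)
  if (is.null(bpu)) {
    b0 <- stats::rnorm(1, config$total_intensity_mean,
                       config$total_intensity_mean * config$total_intensity_cv)
    b0 <- max(b0, 0.2 * config$total_intensity_mean)
    bpu <- b0 / L0
  }
  has_cluster <- pattern != "uc"
  f_final <- if (has_cluster) draw_cluster_fraction(config) else 0
  sigma <- config$cluster_sigma * sigma_mult[[pattern]] *
    stats::runif(1, 0.85, 1.15)
  t_nuc <- if (!has_cluster && config$nucleation_rate > 0)
    birth_time + stats::rexp(1, config$nucleation_rate) else Inf
  ## cell-to-cell variability of the motility-suppressed residual motion
  res_mult <- exp(stats::rnorm(1, 0, 0.3))
  ## a Dyn-OP focus relocates across the cell at a random time within the
  ## canonical 10-min observation window (the class is defined by that
  ## relocation); suppressed in copula/DNP speed benchmarks (see
  ## run_simulation)
  t_switch <- if (pattern == "dyn_op") stats::runif(1, 1, 10) else Inf
  list(id = id, tile_r = tile_r, tile_c = tile_c, pattern = pattern,
       class = NA_character_, fate = NA_character_,
       cx = cx, cy = cy, width = config$cell_width,
       L0 = L0, birth_time = birth_time, birth_frame = birth_frame,
       flip = flip, bpu = bpu, sigma = sigma, f_final = f_final,
       f_now = if (has_cluster) f_final else 0,
       s = 0.3, u = 0, v0_i = NA_real_, res_mult = res_mult,
       t_switch = t_switch,
       state = if (has_cluster) "on" else "uc",
       t_nucleate = t_nuc, t_disperse = Inf, t_reform = Inf,
       septum_x = NA_real_, side = 0,
       parent = parent, sister = sister)
}

cell_length_at <- function(cell, t_min, config)
  cell$L0 + config$growth_rate * (t_min - cell$birth_time)

## Expected per-step speed of a cell's focus (um/s).
cell_speed <- function(cell, config) {
  if (config$motility_suppressed)
    return(0.05 * config$speed_coefficient * cell$res_mult)
  if (!is.na(cell$v0_i)) return(cell$v0_i)
  a <- spot_area(cell$sigma)
  config$speed_coefficient * (config$reference_area / a)^config$speed_exponent
}

## One motion step; mutates s (axial um from pole-1 tip) and u (lateral um).
step_cluster <- function(cell, L, dt_s, config) {
  if (cell$pattern == "non_dyn") {
    cell$s <- reflect_into(cell$s + stats::rnorm(1, 0, 0.005),
                           0.28, max(0.34, 0.12 * L))
    cell$speed_now <- 0
    return(cell)
  }
  v <- cell_speed(cell, config)
  bounds <- if (cell$pattern == "dyn_1p")
    c(0.3, max(0.6, 0.30 * L)) else c(0.3, max(0.7, L - 0.3))
  ## the walk is substepped at ~10 s so that long frame intervals show
  ## diffusive (confined) net displacement rather than one straight jump
  n_sub <- max(1L, round(dt_s / 10))
  step <- v * dt_s / n_sub
  theta <- stats::runif(n_sub, 0, 2 * pi)
  s <- cell$s; u <- cell$u
  for (j in seq_len(n_sub)) {
    s <- reflect_into(s + step * cos(theta[j]), bounds[1], bounds[2])
    u <- reflect_into(u + step * sin(theta[j]), -0.15, 0.15)
  }
  cell$s <- s; cell$u <- u
  cell$speed_now <- v
  cell
}

## Cluster-share state machine at absolute time t (minutes).
update_fraction <- function(cell, t_min, config) {
  st <- cell$state
  if (st == "uc" && t_min >= cell$t_nucleate) {
    cell$state <- "ramp"
    st <- "ramp"
    if (cell$pattern == "uc") cell$pattern <- "dyn_1p"
    if (cell$f_final == 0)
      cell$f_final <- draw_cluster_fraction(config)
    cell$t_disperse <- Inf   # a re-formed focus does not re-disperse
  }
  if (st == "ramp") {
    frac <- (t_min - cell$t_nucleate) / max(config$formation_duration, 1e-9)
    cell$f_now <- cell$f_final * min(1, max(0, frac))
    if (frac >= 1) cell$state <- "on"
  } else if (st == "on") {
    cell$f_now <- cell$f_final
    if (t_min >= cell$t_disperse) cell$state <- "disp"
  } else if (st == "disp") {
    rel <- 1 - config$dispersal_rate * (t_min - cell$t_disperse)
    cell$f_now <- cell$f_final * max(0, rel)
    if (cell$f_now < 0.02) {
      cell$state <- "off"
      cell$f_now <- 0
      if (is.finite(cell$t_reform)) {
        cell$t_nucleate <- max(cell$t_reform, t_min + 1e-6)
        cell$state <- "uc"
        cell$pattern <- "uc"
        cell$f_final <- 0
      }
    }
  } else if (st == "off" || st == "uc") {
    cell$f_now <- 0
  }
  cell
}

## Present-in-truth rule: at least 5% of the budget in the focus.
truth_present <- function(f) f >= 0.05

divide_cell <- function(cell, t_min, frame, config, next_id) {
  L <- cell_length_at(cell, t_min, config)
  gap <- 0.3
  Ld <- (L - gap) / 2
  xc_cluster <- cell$cx - cell$flip * L / 2 + cell$flip * cell$s
  left <- cell; right <- cell
  left$id <- next_id; right$id <- next_id + 1L
  left$parent <- cell$id; right$parent <- cell$id
  left$sister <- right$id; right$sister <- left$id
  left$birth_time <- t_min; right$birth_time <- t_min
  left$birth_frame <- frame; right$birth_frame <- frame
  left$L0 <- Ld; right$L0 <- Ld
  left$cx <- cell$cx - L / 2 + Ld / 2
  right$cx <- cell$cx + L / 2 - Ld / 2
  ## daughters are anchored at the septum and pushed outward as they grow
  left$septum_x <- cell$cx; left$side <- -1
  right$septum_x <- cell$cx; right$side <- 1
  left$flip <- 1; right$flip <- -1   # pole 1 = outward (old) pole
  in_left <- xc_cluster < cell$cx
  single <- stats::runif(1) < config$inherit_single_prob
  set_cluster <- function(d, f_new, s_new) {
    d$f_final <- min(0.8, f_new); d$f_now <- d$f_final
    d$s <- min(max(s_new, 0.3), max(0.31, Ld - 0.3))
    d$state <- "on"; d$pattern <- if (cell$pattern == "uc") "dyn_1p"
      else cell$pattern
    d$t_nucleate <- Inf
    d
  }
  clear_cluster <- function(d) {
    d$f_final <- 0; d$f_now <- 0; d$state <- "uc"; d$pattern <- "uc"
    d$t_nucleate <- if (config$nucleation_rate > 0)
      t_min + stats::rexp(1, config$nucleation_rate) else Inf
    d
  }
  if (cell$f_now > 0) {
    f_keep <- cell$f_now * L / Ld
    ## axial position of the focus measured from each daughter's pole 1
    s_left <- xc_cluster - (left$cx - Ld / 2)
    s_right <- (right$cx + Ld / 2) - xc_cluster
    if (single) {
      if (in_left) {
        left <- set_cluster(left, f_keep, s_left); right <- clear_cluster(right)
      } else {
        right <- set_cluster(right, f_keep, s_right); left <- clear_cluster(left)
      }
    } else {
      left <- set_cluster(left, f_keep / 2, if (in_left) s_left else 0.35)
      right <- set_cluster(right, f_keep / 2, if (in_left) 0.35 else s_right)
    }
  } else {
    left <- clear_cluster(left); right <- clear_cluster(right)
  }
  list(left = left, right = right)
}

#' Simulate a population time-lapse with ground truth
#'
#' Generates a two-channel movie (cell-body silhouette + fluorophore) of
#' `config$n_cells` rod-shaped cells laid out on a tile grid. Each cell is
#' assigned one of the four localization patterns; the configured pattern
#' mixture is realized exactly (largest-remainder allocation with a seeded
#' shuffle). Cells born without a focus nucleate one after an exponential
#' waiting time with rate `nucleation_rate` (independent of cell length);
#' focus formation transfers signal from the diffuse pool so the per-cell
#' budget is conserved within every frame. The focus centroid performs a
#' confined random walk whose per-step speed follows the configured
#' power-law speed-size relation (or a size-independent residual in
#' motility-suppressed mode). Cells divide at `division_length`; the focus
#' goes entirely to one daughter with probability `inherit_single_prob`,
#' otherwise it is split between both.
#'
#' @param config A [sim_config()].
#' @return List with `stack` (an [image_stack()] with channels `phase` and
#'   `mcherry`), and `truth`, a list of ground-truth tables: `cells`
#'   (per cell and frame), `lineage` (one row per cell), `events`
#'   (formation / dispersal / division), plus `noise_sd` and a `config`
#'   echo.
#' @export
simulate_population <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  layout <- tile_layout(config)
  n <- config$n_cells
  counts <- allocate_counts(n, config$pattern_weights)
  patterns <- sample(rep(pattern_levels(), counts))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- ((i - 1) %/% layout$ncol) + 1
    tc <- ((i - 1) %% layout$ncol) + 1
    cells[[i]] <- new_cell(i, tr, tc, layout, config, patterns[i])
  }
  if (!is.null(config$speed_area_rank_corr)) {
    z <- copula_normals(n, spearman_to_pearson_latent(
      config$speed_area_rank_corr))
    for (i in seq_len(n)) {
      cells[[i]]$sigma <- config$cluster_sigma *
        exp(pmin(pmax(0.18 * z[i, 1], -0.5), 0.5))
      cells[[i]]$v0_i <- config$speed_coefficient *
        exp(pmin(pmax(0.35 * z[i, 2], -1), 1))
    }
  }
  run_simulation(cells, config, layout)
}

#' Simulate a quiescence-exit (overnight-culture) population
#'
#' Emulates cells emerging from stationary phase: at time 0 the population
#' is composed of three classes — no detectable focus, relatively small
#' focus, and big focus — at the configured weights (allocated exactly).
#' During the movie, a configured share of the small-focus cells gradually
#' disperses its focus at `dispersal_rate` and later re-forms one by
#' stochastic nucleation; the remaining small-focus cells and all big-focus
#' cells keep theirs; focus-free cells nucleate with rate
#' `nucleation_rate`. Growth and division follow `config`.
#'
#' @param config A [sim_config()].
#' @param class_weights Weights of the (none, small, big) time-0 classes.
#' @param small_range,big_range Budget-share ranges of small and big foci.
#' @param reform_frac Fraction of small-focus cells that disperse and later
#'   re-form (the rest never disperse).
#' @param disperse_window Minutes after time 0 within which dispersal
#'   onsets are drawn uniformly.
#' @return Same structure as [simulate_population()]; the `lineage` table
#'   carries the time-0 `class` and the dispersal `fate` of each cell.
#' @export
simulate_quiescence_exit <- function(config,
                                     class_weights = c(0.13, 0.64, 0.23),
                                     small_range = c(0.18, 0.30),
                                     big_range = c(0.50, 0.62),
                                     reform_frac = 0.35 / 0.64,
                                     disperse_window = 30) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  layout <- tile_layout(config)
  n <- config$n_cells
  counts <- allocate_counts(n, class_weights)
  classes <- sample(rep(c("none", "small", "big"), counts))
  n_small <- sum(classes == "small")
  n_reform <- allocate_counts(n_small, c(reform_frac, 1 - reform_frac))[1]
  fates_small <- sample(rep(c("reform", "persist"),
                            c(n_reform, n_small - n_reform)))
  cells <- vector("list", n)
  j <- 0
  for (i in seq_len(n)) {
    tr <- ((i - 1) %/% layout$ncol) + 1
    tc <- ((i - 1) %% layout$ncol) + 1
    cl <- classes[i]
    pat <- if (cl == "none") "uc" else "dyn_1p"
    cell <- new_cell(i, tr, tc, layout, config, pat)
    cell$class <- cl
    if (cl == "none") {
      cell$fate <- "form"
    } else {
      rng <- if (cl == "small") small_range else big_range
      cell$f_final <- stats::runif(1, rng[1], rng[2])
      cell$f_now <- cell$f_final
      if (cl == "small") {
        j <- j + 1
        cell$fate <- fates_small[j]
        if (cell$fate == "reform") {
          cell$t_disperse <- stats::runif(1, 0, disperse_window)
          ## full dispersal takes 1/dispersal_rate minutes from onset
          cell$t_reform <- cell$t_disperse +
            1 / max(config$dispersal_rate, 1e-9) +
            stats::rexp(1, max(config$nucleation_rate, 1e-9))
        }
      } else {
        cell$fate <- "persist"
      }
    }
    cells[[i]] <- cell
  }
  run_simulation(cells, config, layout)
}

## Shared frame loop: growth, division, state machine, motion, rendering.
run_simulation <- function(cells, config, layout) {
  ps <- config$pixel_size
  dt_s <- config$frame_interval
  dt_min <- dt_s / 60
  n_frames <- config$n_frames
  next_id <- length(cells) + 1L
  ## read-noise scale from the initial population's diffuse signal
  est_mean <- vapply(cells, function(cl) {
    npx <- (cl$L0 * cl$width - (1 - pi / 4) * cl$width^2) / ps^2
    cl$bpu * cl$L0 / npx
  }, 0)
  noise_sd <- config$read_noise_frac * stats::median(est_mean)

  truth_rows <- vector("list", n_frames)
  events <- list()
  lineage <- list()
  frames <- vector("list", n_frames)
  for (cl in cells) lineage[[as.character(cl$id)]] <- cl

  for (k in seq_len(n_frames)) {
    t_min <- (k - 1) * dt_min
    ## divisions first (checked at frame boundaries)
    newcells <- list()
    for (cl in cells) {
      L <- cell_length_at(cl, t_min, config)
      if (L >= config$division_length) {
        dd <- divide_cell(cl, t_min, k, config, next_id)
        next_id <- next_id + 2L
        events[[length(events) + 1]] <- data.frame(
          cell = cl$id, type = "division", time_min = t_min)
        lineage[[as.character(cl$id)]]$division_frame <- k
        lineage[[as.character(cl$id)]]$division_time <- t_min
        lineage[[as.character(dd$left$id)]] <- dd$left
        lineage[[as.character(dd$right$id)]] <- dd$right
        newcells <- c(newcells, list(dd$left, dd$right))
      } else {
        newcells <- c(newcells, list(cl))
      }
    }
    cells <- newcells
    ## state machine + motion
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      prev_state <- cl$state
      cl <- update_fraction(cl, t_min, config)
      if (prev_state %in% c("uc", "off") && cl$state %in% c("ramp", "on"))
        events[[length(events) + 1]] <- data.frame(
          cell = cl$id, type = "formation", time_min = cl$t_nucleate)
      if (prev_state == "on" && cl$state == "disp")
        events[[length(events) + 1]] <- data.frame(
          cell = cl$id, type = "dispersal", time_min = cl$t_disperse)
      L <- cell_length_at(cl, t_min, config)
      if (!is.na(cl$septum_x))
        cl$cx <- cl$septum_x + cl$side * (0.15 + L / 2)
      if (cl$pattern == "dyn_op" && t_min >= cl$t_switch &&
          is.null(config$speed_area_rank_corr) &&
          !config$motility_suppressed) {
        cl$s <- L - cl$s   # relocation to the opposite pole region
        cl$t_switch <- Inf
      }
      if (cl$f_now > 0 || cl$pattern != "uc")
        cl <- step_cluster(cl, L, if (k == 1) 0 else dt_s, config)
      if (is.null(cl$speed_now)) cl$speed_now <- 0
      cells[[i]] <- cl
    }
    ## render + record truth
    states <- lapply(cells, function(cl) {
      L <- cell_length_at(cl, t_min, config)
      f <- cl$f_now
      st <- list(id = cl$id, cx = cl$cx, cy = cl$cy, length = L,
                 width = cl$width, budget = cl$bpu * L,
                 cluster_frac = f, sigma = cl$sigma)
      if (f > 0) {
        st$cluster_x <- cl$cx - cl$flip * L / 2 + cl$flip * cl$s
        st$cluster_y <- cl$cy + cl$u
      }
      st
    })
    fld <- render_field_frame(states, layout$dim_hw, config)
    fr <- array(0, dim = c(layout$dim_hw, 2L))
    fr[, , 1] <- apply_camera(fld$body, config$background_level, noise_sd)
    fr[, , 2] <- apply_camera(fld$fluor, config$background_level, noise_sd)
    frames[[k]] <- fr
    truth_rows[[k]] <- do.call(rbind, lapply(seq_along(cells), function(i) {
      cl <- cells[[i]]; st <- states[[i]]
      data.frame(cell = cl$id, frame = k, time_min = t_min,
                 pattern = cl$pattern, class = cl$class,
                 length_um = st$length,
                 cx_um = st$cx, cy_um = st$cy, budget = st$budget,
                 cluster_frac = st$cluster_frac,
                 cluster_present = truth_present(st$cluster_frac),
                 cluster_x_um = if (st$cluster_frac > 0) st$cluster_x else NA,
                 cluster_y_um = if (st$cluster_frac > 0) st$cluster_y else NA,
                 axial = if (st$cluster_frac > 0) cl$s / st$length else NA,
                 cluster_area_um2 = if (st$cluster_frac > 0)
                   spot_area(cl$sigma) else NA,
                 speed_um_s = cl$speed_now)
    }))
  }

  lin_df <- do.call(rbind, lapply(lineage, function(cl) data.frame(
    cell = cl$id, parent = cl$parent, sister = cl$sister,
    birth_frame = cl$birth_frame, birth_time = cl$birth_time,
    division_frame = if (is.null(cl$division_frame)) NA_integer_
      else cl$division_frame,
    division_time = if (is.null(cl$division_time)) NA_real_
      else cl$division_time,
    pattern = cl$pattern, class = cl$class, fate = cl$fate,
    t_nucleate = cl$t_nucleate, t_disperse = cl$t_disperse)))
  rownames(lin_df) <- NULL
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(cell = integer(), type = character(), time_min = numeric())
  stack <- image_stack(frames, c("phase", "mcherry"), ps, dt_s)
  truth <- list(cells = do.call(rbind, truth_rows), lineage = lin_df,
                events = ev_df, noise_sd = noise_sd, layout = layout,
                config = config)
  list(stack = stack, truth = truth)
}
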