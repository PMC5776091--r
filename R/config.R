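#' Simulation configuration for the synthetic microscopy generator
#'
#' Builds and validates the full set of generative parameters of the
#' synthetic world: cell geometry and growth, the per-cell fluorophore
#' budget and how it is split between the diffuse cytoplasmic pool and a
#' compact polar cluster, cluster motion kinetics, the four-way
#' localization-pattern mixture, stochastic nucleation and gradual
#' dispersal kinetics, division and inheritance, imaging noise, FRAP
#' bleaching/recovery parameters, and the reporter-channel dependence.
#'
#' All lengths are in micrometers, times in the units stated per argument,
#' intensities in arbitrary units (AU).
#'
#' @param pixel_size Pixel size, um per pixel.
#' @param frame_interval Time between frames, seconds.
#' @param n_frames Number of frames in the movie.
#' @param n_cells Number of simulated cells.
#' @param image_shape Optional c(rows, cols) of the rendered field in
#'   pixels; if NULL a tile grid large enough for `n_cells` is used.
#' @param cell_length_range Range (um) from which initial cell lengths are
#'   drawn uniformly.
#' @param cell_width Cell width (um).
#' @param growth_rate Elongation rate, um per minute.
#' @param division_length Length (um) at which a cell divides.
#' @param total_intensity_mean,total_intensity_cv Mean and coefficient of
#'   variation of the per-cell fluorophore budget (AU). The budget scales
#'   with cell length so that mean intensity stays constant during growth.
#' @param cluster_fraction_range Range of the share of the budget residing
#'   in the cluster, in [0, 1].
#' @param cluster_fraction_dist "uniform" (default) draws the share
#'   uniformly from the range; "normal" draws it from a Gaussian centred
#'   on the range midpoint with SD a quarter of the range width
#'   (truncated to [0.02, 0.8]) — used when a continuous, approximately
#'   Gaussian clustering margin is wanted.
#' @param cluster_sigma Gaussian spot width (um) of the rendered cluster.
#' @param speed_coefficient Cluster speed scale v0 (um/s) at the reference
#'   area.
#' @param speed_exponent Exponent alpha of the power-law speed-size
#'   relation: expected speed = v0 * (reference_area / area)^alpha.
#' @param reference_area Reference cluster area A_ref (um^2).
#' @param motility_suppressed Logical; metabolic-inhibition (DNP) mode in
#'   which cluster speed is a small size-independent residual.
#' @param pattern_weights Named or ordered 4-vector of mixture weights over
#'   the localization patterns (non_dyn, dyn_1p, dyn_op, uc); must sum to 1.
#' @param nucleation_rate Stochastic cluster nucleation rate lambda for
#'   cells born without a cluster, events per minute per cell.
#' @param formation_duration Minutes over which a nucleating cluster ramps
#'   from zero to its final budget share.
#' @param dispersal_rate Fractional loss of the cluster share per minute
#'   during dispersal.
#' @param inherit_single_prob Probability p_single that the cluster goes
#'   entirely to one daughter at division (otherwise it is split and both
#'   daughters inherit a cluster).
#' @param pole_zone_fraction Fraction of the normalized cell axis that
#'   constitutes each pole zone.
#' @param background_level Camera background offset (AU).
#' @param read_noise_frac Additive Gaussian read-noise SD, expressed as a
#'   fraction of the per-cell mean diffuse signal.
#' @param frap List of FRAP parameters: `n_prebleach` frames,
#'   `bleach_efficiency` in (0, 1], `exchange_rate` k (1/s),
#'   `recovery_asymptote` A (percent of bleached signal), `duration`
#'   (seconds of post-bleach acquisition), `interval` (seconds between
#'   FRAP frames).
#' @param reporter_rank_corr Rank correlation in [-1, 1] between the
#'   reporter-channel per-cell mean and the cell's true clustering level.
#' @param speed_area_rank_corr Optional rank correlation; when non-NULL the
#'   generator draws each cell's speed scale from a Gaussian copula against
#'   its true spot size instead of the power law (used for the speed-size
#'   benchmark).
#' @param seed Integer RNG seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells = 4, n_frames = 5, seed = 1)
#' cfg$pattern_weights
#' @export
sim_config <- function(pixel_size = 0.1,
                       frame_interval = 60,
                       n_frames = 11,
                       n_cells = 50,
                       image_shape = NULL,
                       cell_length_range = c(2.5, 4.5),
                       cell_width = 1,
                       growth_rate = 0.02,
                       division_length = 5,
                       total_intensity_mean = 2000,
                       total_intensity_cv = 0.2,
                       cluster_fraction_range = c(0.25, 0.6),
                       cluster_fraction_dist = c("uniform", "normal"),
                       cluster_sigma = 0.2,
                       speed_coefficient = 0.03,
                       speed_exponent = 1,
                       reference_area = 0.15,
                       motility_suppressed = FALSE,
                       pattern_weights = c(non_dyn = 0.09, dyn_1p = 0.43,
                                           dyn_op = 0.11, uc = 0.37),
                       nucleation_rate = 0.01,
                       formation_duration = 3,
                       dispersal_rate = 0.02,
                       inherit_single_prob = 0.72,
                       pole_zone_fraction = 0.25,
                       background_level = 20,
                       read_noise_frac = 0.02,
                       frap = list(n_prebleach = 5,
                                   bleach_efficiency = 0.9,
                                   exchange_rate = 0.005,
                                   recovery_asymptote = 6.3,
                                   duration = 600,
                                   interval = 10),
                       reporter_rank_corr = -0.16,
                       speed_area_rank_corr = NULL,
                       seed = 1L) {
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
              image_shape = image_shape,
              cell_length_range = cell_length_range, cell_width = cell_width,
              growth_rate = growth_rate, division_length = division_length,
              total_intensity_mean = total_intensity_mean,
              total_intensity_cv = total_intensity_cv,
              cluster_fraction_range = cluster_fraction_range,
              cluster_fraction_dist = match.arg(cluster_fraction_dist),
              cluster_sigma = cluster_sigma,
              speed_coefficient = speed_coefficient,
              speed_exponent = speed_exponent,
              reference_area = reference_area,
              motility_suppressed = isTRUE(motility_suppressed),
              pattern_weights = pattern_weights,
              nucleation_rate = nucleation_rate,
              formation_duration = formation_duration,
              dispersal_rate = dispersal_rate,
              inherit_single_prob = inherit_single_prob,
              pole_zone_fraction = pole_zone_fraction,
              background_level = background_level,
              read_noise_frac = read_noise_frac,
              frap = frap,
              reporter_rank_corr = reporter_rank_corr,
              speed_area_rank_corr = speed_area_rank_corr,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

pattern_levels <- function() c("non_dyn", "dyn_1p", "dyn_op", "uc")

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells,", x$n_frames, "frames @",
      x$frame_interval, "s,", x$pixel_size, "um/px\n")
  cat("  pattern weights:",
      paste(sprintf("%s=%.2f", pattern_levels(), x$pattern_weights),
            collapse = ", "), "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$pattern_weights) != 4L)
    stop("pattern_weights must have 4 elements (non_dyn, dyn_1p, dyn_op, uc)",
         call. = FALSE)
  if (abs(sum(cfg$pattern_weights) - 1) > 1e-9)
    stop("pattern_weights must sum to 1", call. = FALSE)
  if (any(cfg$pattern_weights < 0))
    stop("pattern_weights must be nonnegative", call. = FALSE)
  nn <- c("pixel_size", "frame_interval", "cell_width", "growth_rate",
          "division_length", "total_intensity_mean", "total_intensity_cv",
          "cluster_sigma", "speed_coefficient", "reference_area",
          "nucleation_rate", "formation_duration", "dispersal_rate",
          "pole_zone_fraction", "background_level", "read_noise_frac")
  for (f in nn)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0))
      stop("field '", f, "' must be nonnegative", call. = FALSE)
  if (cfg$pixel_size <= 0 || cfg$frame_interval <= 0)
    stop("pixel_size and frame_interval must be positive", call. = FALSE)
  cf <- cfg$cluster_fraction_range
  if (length(cf) != 2L || cf[1] > cf[2] || cf[1] < 0 || cf[2] > 1)
    stop("cluster_fraction_range must be an increasing range within [0, 1]",
         call. = FALSE)
  if (abs(cfg$reporter_rank_corr) > 1)
    stop("reporter_rank_corr must lie in [-1, 1]", call. = FALSE)
  if (!is.null(cfg$speed_area_rank_corr) &&
      abs(cfg$speed_area_rank_corr) > 1)
    stop("speed_area_rank_corr must lie in [-1, 1]", call. = FALSE)
  if (cfg$inherit_single_prob < 0 || cfg$inherit_single_prob > 1)
    stop("inherit_single_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (cfg$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  fr <- cfg$frap
  if (!is.null(fr)) {
    if (fr$bleach_efficiency <= 0 || fr$bleach_efficiency > 1)
      stop("frap$bleach_efficiency must lie in (0, 1]", call. = FALSE)
    if (fr$exchange_rate < 0 || fr$recovery_asymptote < 0)
      stop("frap rates must be nonnegative", call. = FALSE)
  }
  cfg
}

## Largest-remainder allocation of n items to the given weights; returns
## integer counts summing to n. Used to fix population compositions to the
## configured mixture exactly.
allocate_counts <- function(n, weights) {
  weights <- weights / sum(weights)
  raw <- n * weights
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

## Bivariate standard-normal draws whose *sample* Pearson correlation is
## exactly rho (orthogonalize-and-mix construction). Returns an n x 2 matrix.
copula_normals <- function(n, rho) {
  stopifnot(n >= 3, abs(rho) <= 1)
  z1 <- scale(stats::rnorm(n))[, 1]
  z2 <- stats::rnorm(n)
  z2 <- stats::residuals(stats::lm(z2 ~ z1))
  z2 <- scale(z2)[, 1]
  cbind(z1, rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
}

## Latent normal correlation that yields a given Spearman rank correlation
## for a bivariate Gaussian copula.
spearman_to_pearson_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)
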