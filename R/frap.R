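## FRAP quantification: double normalization of the pole-ROI signal
## (acquisition-drift correction by the whole-cell total, then
## bleach-depth normalization) and an exponential recovery fit.

#' Normalize a FRAP recovery curve
#'
#' Each post-bleach pole-ROI mean is divided by the simultaneous
#' whole-cell total (drift correction); the recovery is then expressed as
#' a percentage of the bleached-away signal:
#' `recovery(t) = (Fhat(t) - Fhat(0+)) / (Fhat_pre - Fhat(0+)) * 100`,
#' where `Fhat` are the ratio-corrected values and `Fhat(0+)` is the first
#' post-bleach frame. Recovery at t = 0 is 0 by construction, and the
#' whole curve is invariant to rescaling all raw intensities by a
#' constant.
#'
#' @param pole_series Post-bleach pole-ROI mean intensities, first element
#'   the first frame after the bleach.
#' @param cell_total_series Whole-cell total intensities at the same
#'   frames (use 1s if already ratio-corrected).
#' @param prebleach_value Ratio-corrected prebleach reference
#'   `Fhat_pre` (pole mean / cell total before the bleach).
#' @param interval Seconds between post-bleach frames.
#' @return Object of class `frap_curve`: list with `times` (s from
#'   bleach), `recovery` (percent), `fhat`, `prebleach`.
#' @export
normalize_recovery_curve <- function(pole_series, cell_total_series = 1,
                                     prebleach_value, interval = 10) {
  if (length(pole_series) < 2L) stop("need at least 2 post-bleach points")
  if (length(cell_total_series) == 1L)
    cell_total_series <- rep(cell_total_series, length(pole_series))
  stopifnot(length(cell_total_series) == length(pole_series))
  fhat <- pole_series / cell_total_series
  depth <- prebleach_value - fhat[1]
  if (depth <= 0)
    stop("prebleach value does not exceed the post-bleach floor: ",
         "nothing was bleached")
  rec <- (fhat - fhat[1]) / depth * 100
  structure(list(times = (seq_along(fhat) - 1) * interval, recovery = rec,
                 fhat = fhat, prebleach = prebleach_value),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  cat("frap_curve:", length(x$times), "points over", max(x$times), "s; ",
      sprintf("recovery at end = %.2f%%\n", x$recovery[length(x$recovery)]))
  invisible(x)
}

#' Interpolated recovery at a given time
#'
#' @param curve A `frap_curve`.
#' @param t Time in seconds from the bleach; must lie within the curve.
#' @return Linearly interpolated recovery, percent.
#' @export
recovery_fraction_at <- function(curve, t) {
  if (t < min(curve$times) || t > max(curve$times))
    stop("t outside the curve's time span")
  stats::approx(curve$times, curve$recovery, xout = t)$y
}

#' Average several FRAP curves point-wise
#'
#' @param curves List of `frap_curve` objects on the same time grid.
#' @return A `frap_curve` whose recovery is the per-time mean, with an
#'   `se` field (standard error over curves).
#' @export
average_frap_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  mat <- vapply(curves, function(cv) cv$recovery,
                numeric(length(curves[[1]]$times)))
  mat <- matrix(mat, ncol = length(curves))
  out <- structure(list(times = curves[[1]]$times,
                        recovery = rowMeans(mat),
                        se = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
                        fhat = NULL, prebleach = NA_real_),
                   class = "frap_curve")
  out
}

#' Fit a single-exponential recovery model
#'
#' Least-squares fit of `A * (1 - exp(-k t))` to a normalized recovery
#' curve (Levenberg-Marquardt).
#'
#' @param curve A `frap_curve` (or list with `times` and `recovery`).
#' @return List with `A` (percent), `k` (1/s), `residual_norm`, and
#'   `converged`; a degenerate all-zero curve returns `A = 0`,
#'   `k = NA`, `converged = FALSE`.
#' @export
fit_exponential_recovery <- function(curve) {
  t <- curve$times; y <- curve$recovery
  if (length(t) < 5L) stop("need at least 5 points to fit")
  if (all(abs(y) < 1e-12))
    return(list(A = 0, k = NA_real_, residual_norm = 0, converged = FALSE))
  a0 <- max(y, 1e-6)
  k0 <- 1 / max(stats::median(t), 1e-6)
  fit <- try(minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)),
                               start = list(A = a0, k = k0),
                               lower = c(0, 0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(A = NA_real_, k = NA_real_, residual_norm = NA_real_,
                converged = FALSE))
  co <- stats::coef(fit)
  list(A = unname(co["A"]), k = unname(co["k"]),
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       converged = TRUE)
}

#' Quantify FRAP recovery from a synthetic bleach stack
#'
#' Runs the full measurement chain on a rendered FRAP movie: segments
#' cells in the cell-body channel of the first frame, finds each cell's
#' focus-bearing pole from the prebleach fluorophore image, takes the
#' pole-zone pixels (axial position within `pole_zone_fraction` of that
#' pole) as the bleach ROI, subtracts the camera background (median of
#' non-cell pixels), and normalizes each cell's pole series with
#' [normalize_recovery_curve()].
#'
#' @param stack An [image_stack()] from [simulate_frap_stack()].
#' @param n_prebleach Number of prebleach frames at the start of the
#'   stack.
#' @param pole_zone_fraction Axial extent of the pole ROI.
#' @param params Optional list overriding detection defaults (`k_sigma`,
#'   `min_area`).
#' @return List with `curves` (per-cell `frap_curve`s), `mean_curve`, and
#'   `per_cell` (data.frame of cell ids and end-point recovery).
#' @export
analyze_frap_stack <- function(stack, n_prebleach,
                               pole_zone_fraction = 0.25, params = list()) {
  ps <- stack$pixel_size
  body1 <- stack_channel(stack, 1, "phase")
  seg <- segment_cells(body1, ps)
  if (nrow(seg$rois) == 0L) stop("no cells found in the FRAP stack")
  n_frames <- length(stack$frames)
  post_idx <- (n_prebleach + 1L):n_frames
  bg <- vapply(seq_len(n_frames), function(k)
    stats::median(stack_channel(stack, k, "mcherry")[seg$labels == 0L]), 0)
  k_sigma <- params$k_sigma %||% 2
  min_area <- params$min_area %||% 0.04
  curves <- list()
  ids <- integer(0)
  for (i in seg$rois$id) {
    mask <- seg$labels == i
    geom <- measure_cell_geometry(mask, ps)
    pre <- stack_channel(stack, 1, "mcherry") - bg[1]
    det <- detect_clusters(mask, pre, ps, k_sigma = k_sigma,
                           min_area = min_area, geom = geom)
    if (nrow(det) == 0L) next
    ax_cl <- det$axial[det$primary][1]
    idxm <- which(mask)
    rrm <- (idxm - 1L) %% nrow(mask) + 1L
    ccm <- (idxm - 1L) %/% nrow(mask) + 1L
    ax_all <- axial_position(geom, (ccm - 0.5) * ps, (rrm - 0.5) * ps)
    roi_sel <- if (ax_cl < 0.5) ax_all <= pole_zone_fraction
      else ax_all >= 1 - pole_zone_fraction
    roi_idx <- idxm[roi_sel]
    if (length(roi_idx) < 4L) next
    pole <- numeric(n_frames); total <- numeric(n_frames)
    for (k in seq_len(n_frames)) {
      fl <- stack_channel(stack, k, "mcherry") - bg[k]
      pole[k] <- mean(fl[roi_idx])
      total[k] <- sum(fl[idxm])
    }
    fhat_pre <- mean(pole[seq_len(n_prebleach)] / total[seq_len(n_prebleach)])
    cv <- try(normalize_recovery_curve(pole[post_idx], total[post_idx],
                                       fhat_pre,
                                       interval = stack$frame_interval),
              silent = TRUE)
    if (inherits(cv, "try-error")) next
    curves[[length(curves) + 1L]] <- cv
    ids <- c(ids, i)
  }
  if (length(curves) == 0L) stop("no analyzable FRAP cells")
  mean_curve <- average_frap_curves(curves)
  per_cell <- data.frame(cell = ids,
                         end_recovery = vapply(curves, function(cv)
                           cv$recovery[length(cv$recovery)], 0))
  list(curves = curves, mean_curve = mean_curve, per_cell = per_cell)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
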