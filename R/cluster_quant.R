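## Focus detection inside cell ROIs and the per-cell intensity statistics
## (MI, SDI) that serve as the clustering proxy.

## Population (n-denominator) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Flatten image background with a white top-hat transform
#'
#' Morphological opening with a disc structuring element of the given
#' radius is subtracted from the image, removing any structure larger than
#' the disc (the diffuse pool and uneven illumination) while preserving
#' compact foci. Used for focus *detection* only; intensity statistics are
#' always computed on the original image.
#'
#' @param img Numeric matrix.
#' @param radius Structuring-element radius in um; should exceed the focus
#'   width and be below the cell length.
#' @param pixel_size um per pixel.
#' @return Matrix of the same size, nonnegative everywhere.
#' @export
homogenize_background <- function(img, radius = 0.5, pixel_size = 0.1) {
  if (radius <= 0) stop("radius must be positive")
  r_px <- max(1L, round(radius / pixel_size))
  rng <- range(img)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (img - rng[1]) / scale
  th <- EBImage::whiteTopHat(EBImage::Image(norm),
                             EBImage::makeBrush(2L * r_px + 1L, "disc"))
  out <- matrix(EBImage::imageData(th), nrow(img)) * scale
  pmax(out, 0)
}

#' Detect fluorescent foci within a cell ROI
#'
#' Thresholds the homogenized fluorophore image restricted to the cell
#' mask at (within-cell mean + `k_sigma` x within-cell SD), labels
#' 8-connected components, and keeps those of at least `min_area` um^2.
#' Component area, mean intensity, and intensity-weighted centroid are
#' measured on the original (non-homogenized) image. The largest component
#' is flagged as the cell's primary focus.
#'
#' @param mask Logical matrix: the cell's pixel mask (same size as `fluor`).
#' @param fluor Numeric matrix, original fluorophore image.
#' @param pixel_size um per pixel.
#' @param k_sigma Threshold stringency (SD units above the cell mean).
#' @param min_area Minimum component area, um^2.
#' @param homogenized Optional precomputed [homogenize_background()] image.
#' @param geom Optional [measure_cell_geometry()] result for axial
#'   positions.
#' @param cell,frame Identifiers copied into the output.
#' @return data.frame with one row per focus: cell, frame, area_um2,
#'   mean_intensity, centroid x/y (um), normalized axial position, and a
#'   `primary` flag. Zero rows when nothing is above threshold.
#' @export
detect_clusters <- function(mask, fluor, pixel_size, k_sigma = 2,
                            min_area = 0.04, homogenized = NULL,
                            geom = NULL, cell = NA_integer_,
                            frame = NA_integer_) {
  if (!any(mask)) stop("empty mask")
  if (k_sigma <= 0) stop("k_sigma must be positive")
  if (is.null(homogenized))
    homogenized <- homogenize_background(fluor, 0.5, pixel_size)
  vals <- homogenized[mask]
  thr <- mean(vals) + k_sigma * pop_sd(vals)
  bin <- homogenized > thr & mask
  empty <- data.frame(cell = integer(), frame = integer(),
                      area_um2 = numeric(), mean_intensity = numeric(),
                      x_um = numeric(), y_um = numeric(), axial = numeric(),
                      primary = logical())
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  labels <- matrix(as.integer(EBImage::imageData(lab)), nrow(fluor))
  npx <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(npx * pixel_size^2 >= min_area)
  if (length(keep) == 0L) return(empty)
  ## centroid weights are background-corrected (within-cell median is
  ## dominated by the diffuse pool) so the pedestal does not drag the
  ## centroid toward the component's geometric center
  pedestal <- stats::median(fluor[mask])
  rows <- lapply(keep, function(l) {
    idx <- which(labels == l)
    rr <- (idx - 1L) %% nrow(labels) + 1L
    cc <- (idx - 1L) %/% nrow(labels) + 1L
    w <- fluor[idx]
    wc <- pmax(w - pedestal, 1e-9)
    wx <- sum((cc - 0.5) * pixel_size * wc) / sum(wc)
    wy <- sum((rr - 0.5) * pixel_size * wc) / sum(wc)
    data.frame(cell = cell, frame = frame,
               area_um2 = length(idx) * pixel_size^2,
               mean_intensity = mean(w), x_um = wx, y_um = wy,
               axial = if (is.null(geom)) NA_real_
                 else axial_position(geom, wx, wy),
               primary = FALSE)
  })
  out <- do.call(rbind, rows)
  out$primary[which.max(out$area_um2)] <- TRUE
  out[order(-out$area_um2), , drop = FALSE]
}

#' Per-cell mean and standard-deviation intensity
#'
#' MI is the mean of the original fluorophore image over the cell mask —
#' a proxy for the per-cell protein amount. SDI is the population standard
#' deviation over the same pixels — the clustering proxy: a uniform cell
#' has SDI 0, and moving budget from the diffuse pool into a focus raises
#' the SDI monotonically.
#'
#' @param mask Logical cell mask.
#' @param fluor Original fluorophore image (same size).
#' @param cluster_present Logical flag copied from [detect_clusters()].
#' @param cell,frame Identifiers copied into the output.
#' @return data.frame row: cell, frame, mi, sdi, cluster_present.
#' @export
cell_intensity_stats <- function(mask, fluor, cluster_present = NA,
                                 cell = NA_integer_, frame = NA_integer_) {
  if (!any(mask)) stop("empty mask")
  v <- fluor[mask]
  data.frame(cell = cell, frame = frame, mi = mean(v), sdi = pop_sd(v),
             cluster_present = cluster_present)
}
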