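## Image formation: rod-shaped cell masks, uniform diffuse pool, Gaussian
## focus. All geometry in micrometers; pixel (r, c) has its center at
## x = (c - 0.5) * pixel_size, y = (r - 0.5) * pixel_size.

## Logical mask of a horizontal rod (spherocylinder silhouette) of total
## length `length` and width `width`, centered at (cx, cy) um, evaluated on
## pixel rows/cols `rows`, `cols` (1-based indices into the field).
rod_mask <- function(rows, cols, cx, cy, length, width, pixel_size) {
  xs <- (cols - 0.5) * pixel_size
  ys <- (rows - 0.5) * pixel_size
  half_seg <- max(0, (length - width) / 2)
  ## squared distance from each pixel center to the central axis segment
  ddx <- xs - pmin(pmax(xs, cx - half_seg), cx + half_seg)
  d2 <- outer((ys - cy)^2, ddx^2, "+")
  d2 <= (width / 2)^2
}

## Pixel bounding box (rows, cols) covering a cell with a small margin.
cell_bbox <- function(cx, cy, length, width, pixel_size, dim_hw,
                      margin_px = 2L) {
  r0 <- max(1L, floor((cy - width / 2) / pixel_size) + 1L - margin_px)
  r1 <- min(dim_hw[1], ceiling((cy + width / 2) / pixel_size) + margin_px)
  c0 <- max(1L, floor((cx - length / 2) / pixel_size) + 1L - margin_px)
  c1 <- min(dim_hw[2], ceiling((cx + length / 2) / pixel_size) + margin_px)
  list(rows = r0:r1, cols = c0:c1)
}

#' Render one cell into a pair of intensity patches
#'
#' Image-formation primitive of the synthetic generator: the cell-body
#' channel is a filled rod silhouette, the fluorophore channel is a uniform
#' diffuse pool over the cell mask plus (optionally) a compact 2-D Gaussian
#' focus whose pixel weights are renormalized over the mask so that the
#' per-cell fluorophore budget is conserved exactly.
#'
#' @param cell_state List with fields `cx`, `cy` (center, um), `length`,
#'   `width` (um), `budget` (AU), `cluster_frac` in [0, 1], `sigma` (um),
#'   and, when `cluster_frac > 0`, the focus center `cluster_x`,
#'   `cluster_y` (um).
#' @param config A [sim_config()] (only `pixel_size` is used here).
#' @param rows,cols Pixel index ranges of the patch; defaults to the cell's
#'   bounding box in a field just large enough for it.
#' @return List with `body` and `fluor` numeric matrices (no background or
#'   noise), the logical `mask`, and the patch `rows`/`cols`.
#' @export
render_cell_frame <- function(cell_state, config, rows = NULL, cols = NULL) {
  ps <- config$pixel_size
  st <- cell_state
  if (is.null(rows) || is.null(cols)) {
    dim_hw <- c(ceiling((st$cy + st$width) / ps),
                ceiling((st$cx + st$length) / ps))
    bb <- cell_bbox(st$cx, st$cy, st$length, st$width, ps, dim_hw)
    rows <- bb$rows; cols <- bb$cols
  }
  mask <- rod_mask(rows, cols, st$cx, st$cy, st$length, st$width, ps)
  npx <- sum(mask)
  if (npx == 0L) stop("cell mask is empty: cell lies outside the patch")
  fluor <- matrix(0, nrow(mask), ncol(mask))
  f <- if (is.null(st$cluster_frac)) 0 else st$cluster_frac
  fluor[mask] <- st$budget * (1 - f) / npx
  if (f > 0) {
    if (!point_in_rod(st$cluster_x, st$cluster_y, st))
      stop("cluster centroid lies outside the cell mask")
    xs <- (cols - 0.5) * ps
    ys <- (rows - 0.5) * ps
    g <- exp(-outer((ys - st$cluster_y)^2, (xs - st$cluster_x)^2, "+") /
               (2 * st$sigma^2))
    g[!mask] <- 0
    gs <- sum(g)
    if (gs > 0) fluor <- fluor + g / gs * st$budget * f
  }
  body <- matrix(0, nrow(mask), ncol(mask))
  body[mask] <- 100
  list(body = body, fluor = fluor, mask = mask, rows = rows, cols = cols)
}

## Is point (x, y) inside the rod of `cell_state` (with a small margin)?
point_in_rod <- function(x, y, st, margin = 0) {
  half_seg <- max(0, (st$length - st$width) / 2)
  px <- min(max(x, st$cx - half_seg), st$cx + half_seg)
  sqrt((x - px)^2 + (y - st$cy)^2) <= st$width / 2 - margin
}

## Render a full field frame from a list of cell states. Raises an error if
## two cell masks would overlap. Returns list(body, fluor, masks_label).
render_field_frame <- function(cells, dim_hw, config) {
  body <- matrix(0, dim_hw[1], dim_hw[2])
  fluor <- matrix(0, dim_hw[1], dim_hw[2])
  labels <- matrix(0L, dim_hw[1], dim_hw[2])
  for (st in cells) {
    bb <- cell_bbox(st$cx, st$cy, st$length, st$width, config$pixel_size,
                    dim_hw)
    patch <- render_cell_frame(st, config, bb$rows, bb$cols)
    sub <- labels[bb$rows, bb$cols]
    if (any(sub[patch$mask] != 0L))
      stop("cell masks overlap in the rendered field")
    sub[patch$mask] <- st$id
    labels[bb$rows, bb$cols] <- sub
    body[bb$rows, bb$cols] <- body[bb$rows, bb$cols] + patch$body
    fluor[bb$rows, bb$cols] <- fluor[bb$rows, bb$cols] + patch$fluor
  }
  list(body = body, fluor = fluor, labels = labels)
}

## Additive camera model: background offset plus Gaussian read noise.
apply_camera <- function(img, background, noise_sd) {
  out <- img + background
  if (noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  out
}

#' Construct an image stack container
#'
#' @param frames List of per-frame arrays `[rows, cols, channels]`.
#' @param channels Character vector of channel names.
#' @param pixel_size um per pixel.
#' @param frame_interval Seconds between frames.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, channels, pixel_size, frame_interval) {
  stopifnot(length(frames) >= 1, length(channels) >= 1)
  for (fr in frames) {
    stopifnot(length(dim(fr)) == 3L, dim(fr)[3] == length(channels))
  }
  structure(list(frames = frames, channels = channels,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("image_stack:", length(x$frames), "frames,", d[1], "x", d[2],
      "px, channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

## Extract one channel of one frame as a plain matrix.
stack_channel <- function(stack, frame, channel) {
  ci <- if (is.character(channel)) match(channel, stack$channels) else channel
  if (is.na(ci)) stop("unknown channel: ", channel)
  stack$frames[[frame]][, , ci]
}
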