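## Cell detection in the cell-body channel: global Otsu threshold, hole
## filling, connected components, size filtering.

#' Segment cells in a cell-body image
#'
#' Applies a global Otsu threshold to the cell-body channel, fills holes,
#' labels 8-connected components, and discards components outside the
#' `[min_area, max_area]` window (um^2) as well as components touching the
#' image border (their geometry would be truncated). ROIs are returned
#' sorted row-major by centroid.
#'
#' @param img Numeric matrix (rows x cols), the cell-body channel.
#' @param pixel_size um per pixel.
#' @param min_area,max_area Component area window in um^2.
#' @param discard_border Drop components touching the image border.
#' @return List with `rois`, a data.frame (id, npx, area_um2, centroid
#'   row/col in pixels, cx_um, cy_um, bounding box), and `labels`, an
#'   integer label matrix in which ROI `id` marks its pixels. A blank
#'   (zero-variance) image yields zero ROIs with a warning.
#' @export
segment_cells <- function(img, pixel_size, min_area = 0.5, max_area = 20,
                          discard_border = TRUE) {
  stopifnot(is.matrix(img), min_area < max_area)
  rng <- range(img)
  empty <- list(rois = data.frame(id = integer(), npx = integer(),
                                  area_um2 = numeric(), centroid_row = numeric(),
                                  centroid_col = numeric(), cx_um = numeric(),
                                  cy_um = numeric(), r0 = integer(),
                                  r1 = integer(), c0 = integer(),
                                  c1 = integer()),
                labels = matrix(0L, nrow(img), ncol(img)))
  if (diff(rng) <= 0) {
    warning("blank image: no cells segmented")
    return(empty)
  }
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  bin <- norm > thr
  bin <- EBImage::fillHull(EBImage::Image(bin))
  lab <- EBImage::bwlabel(bin)
  labels <- matrix(as.integer(EBImage::imageData(lab)), nrow(img))
  if (max(labels) == 0L) {
    warning("no components above threshold")
    return(empty)
  }
  npx <- tabulate(labels[labels > 0L], nbins = max(labels))
  area <- npx * pixel_size^2
  keep <- which(area >= min_area & area <= max_area)
  if (discard_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    keep <- setdiff(keep, border)
  }
  if (length(keep) == 0L) return(empty)
  idx <- which(labels > 0L)
  lv <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  cen_r <- vapply(keep, function(l) mean(rr[lv == l]), 0)
  cen_c <- vapply(keep, function(l) mean(cc[lv == l]), 0)
  ord <- order(cen_r, cen_c)
  keep <- keep[ord]; cen_r <- cen_r[ord]; cen_c <- cen_c[ord]
  out_labels <- matrix(0L, nrow(img), ncol(img))
  rois <- data.frame(id = seq_along(keep), npx = npx[keep],
                     area_um2 = area[keep],
                     centroid_row = cen_r, centroid_col = cen_c,
                     cx_um = (cen_c - 0.5) * pixel_size,
                     cy_um = (cen_r - 0.5) * pixel_size,
                     r0 = NA_integer_, r1 = NA_integer_,
                     c0 = NA_integer_, c1 = NA_integer_)
  for (i in seq_along(keep)) {
    sel <- lv == keep[i]
    out_labels[idx[sel]] <- i
    rois$r0[i] <- min(rr[sel]); rois$r1[i] <- max(rr[sel])
    rois$c0[i] <- min(cc[sel]); rois$c1[i] <- max(cc[sel])
  }
  list(rois = rois, labels = out_labels)
}

#' Measure rod-cell geometry from a pixel mask
#'
#' Length is the extent of the mask projected on its principal axis
#' (plus one pixel, so an axis-aligned n-pixel row measures n pixels);
#' area is the pixel count; the two pole tips are the extremal mask pixels
#' along the principal axis. The axis direction is made deterministic
#' (positive column component, ties broken by positive row component), so
#' pole 1 is always the tip with the smaller projection.
#'
#' @param mask Logical matrix (a single cell's mask), or an integer label
#'   matrix together with `id`.
#' @param pixel_size um per pixel.
#' @param id Label to extract when `mask` is a label matrix.
#' @return List with `length_um`, `area_um2`, `orientation` (radians),
#'   `pole1`, `pole2` (xy um), `centroid` (xy um), `axis` (unit vector,
#'   xy), and `proj_range` (um, for axial normalization).
#' @export
measure_cell_geometry <- function(mask, pixel_size, id = NULL) {
  if (!is.logical(mask)) {
    stopifnot(!is.null(id))
    mask <- mask == id
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  x <- (cc - 0.5) * pixel_size
  y <- (rr - 0.5) * pixel_size
  cx <- mean(x); cy <- mean(y)
  if (length(idx) == 1L) {
    ax <- c(1, 0)
  } else {
    cv <- stats::cov(cbind(x - cx, y - cy))
    eg <- eigen(cv, symmetric = TRUE)
    ax <- eg$vectors[, 1]
    if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  }
  proj <- (x - cx) * ax[1] + (y - cy) * ax[2]
  i_min <- which.min(proj); i_max <- which.max(proj)
  list(length_um = (max(proj) - min(proj)) + pixel_size,
       area_um2 = length(idx) * pixel_size^2,
       orientation = atan2(ax[2], ax[1]),
       pole1 = c(x[i_min], y[i_min]), pole2 = c(x[i_max], y[i_max]),
       centroid = c(cx, cy), axis = ax,
       proj_range = c(min(proj), max(proj)))
}

## Normalized axial position in [0, 1] (0 = pole 1) of points (xy um)
## given a cell's geometry.
axial_position <- function(geom, x, y) {
  p <- (x - geom$centroid[1]) * geom$axis[1] +
       (y - geom$centroid[2]) * geom$axis[2]
  s <- (p - geom$proj_range[1]) / max(diff(geom$proj_range), 1e-12)
  pmin(pmax(s, 0), 1)
}

## Link segmented cells across consecutive frames by maximum mask overlap;
## declare a division when one mask at frame t maps to two masks at t+1.
## `label_list` is a list of per-frame label matrices. Returns a data.frame
## with one row per (track, frame): track, frame, roi (label in frame),
## parent, sister, birth_frame.
link_cell_rois <- function(label_list, min_overlap_px = 10L) {
  n_frames <- length(label_list)
  tracks <- list()      # track id -> list(frames=, rois=, parent=, sister=)
  next_track <- 1L
  l1 <- label_list[[1]]
  active <- integer(max(max(l1), 0L))  # roi id in current frame -> track id
  for (r in seq_len(max(max(l1), 0L))) {
    tracks[[next_track]] <- list(frames = 1L, rois = r,
                                 parent = NA_integer_, sister = NA_integer_,
                                 birth = 1L)
    active[r] <- next_track
    next_track <- next_track + 1L
  }
  for (k in seq_len(n_frames - 1L)) {
    la <- label_list[[k]]; lb <- label_list[[k + 1L]]
    sel <- la > 0L & lb > 0L
    new_active <- integer(max(max(lb), 0L))
    if (any(sel)) {
      ov <- table(factor(la[sel]), factor(lb[sel]))
      ovm <- matrix(as.integer(ov), nrow(ov), ncol(ov),
                    dimnames = dimnames(ov))
      a_ids <- as.integer(rownames(ovm)); b_ids <- as.integer(colnames(ovm))
      ## for each next-frame roi, its best previous roi
      best_prev <- a_ids[apply(ovm, 2, which.max)]
      best_px <- apply(ovm, 2, max)
      ok <- best_px >= min_overlap_px
      for (a in a_ids) {
        children <- b_ids[ok & best_prev == a]
        tr <- if (a <= length(active)) active[a] else 0L
        if (tr == 0L || length(children) == 0L) next
        if (length(children) == 1L) {
          tracks[[tr]]$frames <- c(tracks[[tr]]$frames, k + 1L)
          tracks[[tr]]$rois <- c(tracks[[tr]]$rois, children)
          new_active[children] <- tr
        } else {
          ## division: two largest-overlap children become daughters
          cov2 <- ovm[as.character(a), as.character(children)]
          children <- children[order(cov2, decreasing = TRUE)][1:2]
          d1 <- next_track; d2 <- next_track + 1L
          tracks[[d1]] <- list(frames = k + 1L, rois = children[1],
                               parent = tr, sister = d2, birth = k + 1L)
          tracks[[d2]] <- list(frames = k + 1L, rois = children[2],
                               parent = tr, sister = d1, birth = k + 1L)
          new_active[children] <- c(d1, d2)
          next_track <- next_track + 2L
        }
      }
    }
    active <- new_active
  }
  rows <- lapply(seq_along(tracks), function(tr) {
    t0 <- tracks[[tr]]
    data.frame(track = tr, frame = t0$frames, roi = t0$rois,
               parent = t0$parent, sister = t0$sister,
               birth_frame = t0$birth)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track = integer(), frame = integer(),
                                      roi = integer(), parent = integer(),
                                      sister = integer(),
                                      birth_frame = integer())
  out
}
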