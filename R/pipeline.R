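## End-to-end analysis: stack -> per-cell tables -> trajectories, labels,
## events. The pipeline is deterministic for a fixed stack and parameters.

default_params <- function() {
  list(seg_min_area = 0.5, seg_max_area = 20,
       homog_radius = 0.5, k_sigma = 2, det_min_area = 0.04,
       max_step = 1.0, max_gap = 0L,
       pole_zone_fraction = 0.25, d_static = 0.2, presence_min = 0.2)
}

#' Run the full analysis pipeline on an image stack
#'
#' Executes segmentation of the cell-body channel, frame-to-frame cell
#' linking (maximum mask overlap; a division is declared when one mask
#' maps to two), per-cell geometry, focus detection on the homogenized
#' fluorophore channel, MI/SDI statistics on the original intensities,
#' focus-trajectory linking, and four-way pattern classification.
#'
#' @param stack An [image_stack()] with channels `phase` and `mcherry`
#'   (optionally `reporter`).
#' @param params Named list overriding entries of the defaults:
#'   `seg_min_area`, `seg_max_area` (um^2), `homog_radius` (um),
#'   `k_sigma`, `det_min_area` (um^2), `max_step` (um), `max_gap`
#'   (frames), `pole_zone_fraction`, `d_static` (um), `presence_min`.
#' @return List of tables: `cells` (one row per tracked cell and frame:
#'   geometry, MI, SDI, focus presence and primary-focus measurements,
#'   lineage columns), `observations` (every detected focus),
#'   `trajectories` (per-trajectory summary), `labels` (per-cell pattern
#'   label and supporting metrics), `fractions` (pattern fractions over
#'   classifiable cells), and `params`.
#' @export
run_analysis <- function(stack, params = list()) {
  p <- utils::modifyList(default_params(), params)
  ps <- stack$pixel_size
  n_frames <- length(stack$frames)
  has_reporter <- "reporter" %in% stack$channels

  segs <- vector("list", n_frames)
  homogs <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    body <- stack_channel(stack, k, "phase")
    segs[[k]] <- suppressWarnings(
      segment_cells(body, ps, p$seg_min_area, p$seg_max_area))
    homogs[[k]] <- homogenize_background(stack_channel(stack, k, "mcherry"),
                                         p$homog_radius, ps)
  }
  links <- link_cell_rois(lapply(segs, `[[`, "labels"))
  if (nrow(links) == 0L) {
    warning("no cells tracked in this stack")
    return(list(cells = NULL, observations = NULL, trajectories = NULL,
                labels = NULL, fractions = NULL, params = p))
  }

  cell_rows <- vector("list", nrow(links))
  obs_rows <- list()
  for (i in seq_len(nrow(links))) {
    k <- links$frame[i]; roi <- links$roi[i]
    seg <- segs[[k]]
    info <- seg$rois[seg$rois$id == roi, ]
    rr <- info$r0:info$r1; cc <- info$c0:info$c1
    mask <- seg$labels[rr, cc, drop = FALSE] == roi
    fluor <- stack_channel(stack, k, "mcherry")[rr, cc, drop = FALSE]
    hpatch <- homogs[[k]][rr, cc, drop = FALSE]
    geom <- measure_cell_geometry(mask, ps)
    off <- c((rr[1] - 1L) * ps, (cc[1] - 1L) * ps)  # (y, x) offsets
    geom$centroid <- geom$centroid + c(off[2], off[1])
    geom$pole1 <- geom$pole1 + c(off[2], off[1])
    geom$pole2 <- geom$pole2 + c(off[2], off[1])
    det <- detect_clusters(mask, fluor, ps, k_sigma = p$k_sigma,
                           min_area = p$det_min_area, homogenized = hpatch,
                           geom = NULL, cell = links$track[i], frame = k)
    if (nrow(det) > 0L) {
      det$x_um <- det$x_um + off[2]
      det$y_um <- det$y_um + off[1]
      det$axial <- axial_position(geom, det$x_um, det$y_um)
      obs_rows[[length(obs_rows) + 1L]] <- det
    }
    st <- cell_intensity_stats(mask, fluor, cluster_present = nrow(det) > 0L,
                               cell = links$track[i], frame = k)
    prim <- if (nrow(det) > 0L) det[det$primary, ][1, ] else NULL
    if (has_reporter) {
      rep_img <- stack_channel(stack, k, "reporter")[rr, cc, drop = FALSE]
      rep_mi <- mean(rep_img[mask])
    } else rep_mi <- NA_real_
    cell_rows[[i]] <- data.frame(
      cell = links$track[i], frame = k, roi = roi,
      length_um = geom$length_um, area_um2 = geom$area_um2,
      cx_um = geom$centroid[1], cy_um = geom$centroid[2],
      orientation = geom$orientation,
      mi = st$mi, sdi = st$sdi, cluster_present = st$cluster_present,
      cluster_x_um = if (is.null(prim)) NA_real_ else prim$x_um,
      cluster_y_um = if (is.null(prim)) NA_real_ else prim$y_um,
      cluster_area_um2 = if (is.null(prim)) NA_real_ else prim$area_um2,
      cluster_axial = if (is.null(prim)) NA_real_ else prim$axial,
      reporter_mi = rep_mi,
      parent = links$parent[i], sister = links$sister[i],
      birth_frame = links$birth_frame[i])
  }
  cells <- do.call(rbind, cell_rows)
  observations <- if (length(obs_rows)) do.call(rbind, obs_rows) else
    data.frame(cell = integer(), frame = integer(), area_um2 = numeric(),
               mean_intensity = numeric(), x_um = numeric(),
               y_um = numeric(), axial = numeric(), primary = logical())
  obs_linked <- link_clusters(observations, max_step = p$max_step,
                              max_gap = p$max_gap)
  trajectories <- summarize_trajectories(obs_linked, stack$frame_interval)

  zones <- assign_pole_zones(p$pole_zone_fraction)
  labels <- do.call(rbind, lapply(split(cells, cells$cell), function(tr) {
    track <- data.frame(frame = tr$frame,
                        cluster_present = tr$cluster_present,
                        x_um = tr$cluster_x_um, y_um = tr$cluster_y_um,
                        axial = tr$cluster_axial)
    res <- classify_pattern(track, zones, p$d_static, p$presence_min)
    data.frame(cell = tr$cell[1], label = res$label,
               presence = res$presence, max_disp_um = res$max_disp_um,
               n_frames = nrow(tr))
  }))
  fractions <- if (any(!is.na(labels$label)))
    population_fractions(labels$label) else NULL
  list(cells = cells, observations = obs_linked,
       trajectories = trajectories, labels = labels, fractions = fractions,
       params = p)
}

#' Match pipeline tracks to ground-truth cells
#'
#' Pairs each tracked cell with the nearest ground-truth cell (centroid
#' distance at the track's birth frame).
#'
#' @param cells Pipeline `cells` table from [run_analysis()].
#' @param truth Ground truth from [simulate_population()].
#' @param max_dist Maximum accepted centroid distance, um.
#' @return data.frame with columns `cell` (pipeline track) and
#'   `truth_cell`, plus the truth `pattern` and `class`.
#' @export
match_tracks_to_truth <- function(cells, truth, max_dist = 1.5) {
  first <- do.call(rbind, lapply(split(cells, cells$cell), function(tr) {
    tr[which.min(tr$frame), c("cell", "frame", "cx_um", "cy_um")]
  }))
  tc <- truth$cells
  rows <- lapply(seq_len(nrow(first)), function(i) {
    cand <- tc[tc$frame == first$frame[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    d <- sqrt((cand$cx_um - first$cx_um[i])^2 +
              (cand$cy_um - first$cy_um[i])^2)
    j <- which.min(d)
    if (d[j] > max_dist) return(NULL)
    data.frame(cell = first$cell[i], truth_cell = cand$cell[j],
               pattern = cand$pattern[j], class = cand$class[j],
               dist_um = d[j])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cell = integer(),
                                      truth_cell = integer(),
                                      pattern = character(),
                                      class = character(),
                                      dist_um = numeric())
  out
}
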