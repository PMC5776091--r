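## Four-way localization-pattern classification: non-dynamic (non-Dyn),
## dynamic within one pole (Dyn-1P), dynamic outside the pole zone
## (Dyn-OP), and undetectable cluster (UC).

#' Pole and midcell zones on the normalized cell axis
#'
#' The two pole zones are `[0, f]` and `[1 - f, 1]` and the midcell band is
#' `[0.5 - f/2, 0.5 + f/2]` of the normalized axial coordinate, so the
#' zones rescale automatically as the cell elongates.
#'
#' @param pole_zone_fraction Fraction f of the axis per pole zone,
#'   in (0, 0.5).
#' @return List with `pole1`, `pole2`, `midcell` intervals.
#' @export
assign_pole_zones <- function(pole_zone_fraction = 0.25) {
  f <- pole_zone_fraction
  if (f <= 0 || f >= 0.5)
    stop("pole_zone_fraction must lie in (0, 0.5)")
  list(pole1 = c(0, f), pole2 = c(1 - f, 1),
       midcell = c(0.5 - f / 2, 0.5 + f / 2))
}

in_zone <- function(x, zone) x >= zone[1] & x <= zone[2]

#' Classify a cell's localization pattern
#'
#' Applied to one cell's per-frame focus record: UC if the focus is
#' present in fewer than `presence_min` of the frames; otherwise non-Dyn
#' if the maximum pairwise centroid displacement is below `d_static`;
#' otherwise Dyn-OP if any centroid enters the pole zone opposite the
#' trajectory's starting pole or the midcell band (a trajectory starting
#' outside both pole zones is Dyn-OP by convention); otherwise Dyn-1P.
#' The rule is symmetric under left-right relabeling of the poles.
#'
#' @param track data.frame with one row per frame of the cell's track:
#'   columns `frame`, `cluster_present`, and for present frames `x_um`,
#'   `y_um` (focus centroid) and `axial` (normalized position).
#' @param zones From [assign_pole_zones()].
#' @param d_static Displacement below which a focus counts as static, um.
#' @param presence_min Minimum presence fraction for a detectable focus.
#' @return List with `label` (one of "non_dyn", "dyn_1p", "dyn_op", "uc")
#'   and supporting metrics (`presence`, `max_disp_um`, `zone_exit`).
#' @export
classify_pattern <- function(track, zones = assign_pole_zones(),
                             d_static = 0.2, presence_min = 0.2) {
  n <- nrow(track)
  if (n < 4L) return(list(label = NA_character_, presence = NA_real_,
                          max_disp_um = NA_real_, zone_exit = NA,
                          reason = "track shorter than 4 frames"))
  present <- !is.na(track$cluster_present) & track$cluster_present
  presence <- mean(present)
  if (presence < presence_min)
    return(list(label = "uc", presence = presence, max_disp_um = NA_real_,
                zone_exit = NA))
  xs <- track$x_um[present]; ys <- track$y_um[present]
  ax <- track$axial[present]
  ## a single usable centroid cannot show movement
  max_disp <- if (sum(present) < 2L) 0
    else max(stats::dist(cbind(xs, ys)))
  if (max_disp < d_static)
    return(list(label = "non_dyn", presence = presence,
                max_disp_um = max_disp, zone_exit = FALSE))
  s0 <- ax[1]
  start_pole <- if (in_zone(s0, zones$pole1)) "pole1"
    else if (in_zone(s0, zones$pole2)) "pole2" else "none"
  if (start_pole == "none")
    return(list(label = "dyn_op", presence = presence,
                max_disp_um = max_disp, zone_exit = TRUE))
  other <- if (start_pole == "pole1") zones$pole2 else zones$pole1
  exit <- any(in_zone(ax, other)) || any(in_zone(ax, zones$midcell))
  list(label = if (exit) "dyn_op" else "dyn_1p", presence = presence,
       max_disp_um = max_disp, zone_exit = exit)
}

#' Population fractions over the four localization patterns
#'
#' @param labels Character vector of per-cell labels (values among
#'   "non_dyn", "dyn_1p", "dyn_op", "uc"; NAs are dropped).
#' @return List with `fractions` (named, summing to 1), `counts`, `n`, and
#'   `detectable` = 1 - UC fraction (fraction of cells with a detectable
#'   focus).
#' @export
population_fractions <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("no labels to tabulate")
  counts <- table(factor(labels, levels = pattern_levels()))
  fr <- as.numeric(counts) / length(labels)
  names(fr) <- pattern_levels()
  list(fractions = fr, counts = as.integer(counts), n = length(labels),
       detectable = 1 - fr[["uc"]])
}
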