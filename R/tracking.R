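## Linking of per-frame focus observations into trajectories and the
## path-length speed statistic.

#' Link focus observations into trajectories
#'
#' Within each cell, focus centroids in consecutive frames are linked by
#' nearest-neighbour matching: candidate links are sorted by distance
#' (ties broken by observation index, so linking is deterministic and
#' permutation-invariant) and accepted greedily while the displacement is
#' at most `max_step`. A focus missing for more than `max_gap` consecutive
#' frames ends its trajectory; unlinked observations start new ones.
#'
#' @param obs data.frame of focus observations with columns `cell`,
#'   `frame`, `x_um`, `y_um` (e.g. from [detect_clusters()]).
#' @param max_step Maximum accepted displacement between linked frames, um.
#' @param max_gap Maximum number of missed frames bridged by a link.
#' @return `obs` with an added `traj` column (trajectory id, unique across
#'   cells).
#' @export
link_clusters <- function(obs, max_step = 1.0, max_gap = 0L) {
  stopifnot(max_step > 0, max_gap >= 0)
  if (nrow(obs) == 0L) {
    obs$traj <- integer(0)
    return(obs)
  }
  obs$.row <- seq_len(nrow(obs))
  obs$traj <- NA_integer_
  next_traj <- 1L
  for (cid in unique(obs$cell)) {
    sub <- obs[obs$cell == cid, , drop = FALSE]
    sub <- sub[order(sub$frame, sub$.row), , drop = FALSE]
    ## open trajectories: list(traj =, frame =, x =, y =)
    open <- list()
    for (fr in sort(unique(sub$frame))) {
      cur <- sub[sub$frame == fr, , drop = FALSE]
      ## drop expired trajectories
      open <- Filter(function(o) fr - o$frame <= max_gap + 1L, open)
      links <- NULL
      if (length(open) && nrow(cur)) {
        cand <- expand.grid(o = seq_along(open), j = seq_len(nrow(cur)))
        cand$d <- sqrt((vapply(open, `[[`, 0, "x")[cand$o] - cur$x_um[cand$j])^2 +
                       (vapply(open, `[[`, 0, "y")[cand$o] - cur$y_um[cand$j])^2)
        cand <- cand[cand$d <= max_step, , drop = FALSE]
        cand <- cand[order(cand$d, cand$j), , drop = FALSE]
        used_o <- logical(length(open)); used_j <- logical(nrow(cur))
        links <- list()
        for (i in seq_len(nrow(cand))) {
          o <- cand$o[i]; j <- cand$j[i]
          if (!used_o[o] && !used_j[j]) {
            used_o[o] <- TRUE; used_j[j] <- TRUE
            links[[length(links) + 1L]] <- c(o, j)
          }
        }
      }
      linked_j <- integer(0)
      for (lk in links) {
        o <- lk[1]; j <- lk[2]
        obs$traj[obs$.row == cur$.row[j]] <- open[[o]]$traj
        open[[o]]$frame <- fr
        open[[o]]$x <- cur$x_um[j]; open[[o]]$y <- cur$y_um[j]
        linked_j <- c(linked_j, j)
      }
      for (j in setdiff(seq_len(nrow(cur)), linked_j)) {
        obs$traj[obs$.row == cur$.row[j]] <- next_traj
        open[[length(open) + 1L]] <- list(traj = next_traj, frame = fr,
                                          x = cur$x_um[j], y = cur$y_um[j])
        next_traj <- next_traj + 1L
      }
    }
  }
  obs$.row <- NULL
  obs
}

#' Average speed of a focus trajectory
#'
#' Path length divided by elapsed time: the sum of consecutive centroid
#' displacements over the time between the first and last linked frames.
#' This matches the jagged, zigzag character of focus paths (net
#' displacement would underestimate them).
#'
#' @param traj data.frame of one trajectory's observations (`frame`,
#'   `x_um`, `y_um`), in any row order.
#' @param frame_interval Seconds between consecutive frames.
#' @return Speed in um/s, or `NA` for a singleton trajectory.
#' @export
trajectory_speed <- function(traj, frame_interval) {
  traj <- traj[order(traj$frame), , drop = FALSE]
  n <- nrow(traj)
  if (n < 2L) return(NA_real_)
  path <- sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2))
  elapsed <- (traj$frame[n] - traj$frame[1]) * frame_interval
  path / elapsed
}

#' Summarize trajectories: mean area and average speed
#'
#' @param obs Observations with a `traj` column from [link_clusters()].
#' @param frame_interval Seconds between frames.
#' @return data.frame with one row per trajectory: traj, cell, n_obs,
#'   start/end frame, mean_area_um2, speed_um_s (NA for singletons).
#' @export
summarize_trajectories <- function(obs, frame_interval) {
  if (nrow(obs) == 0L)
    return(data.frame(traj = integer(), cell = integer(), n_obs = integer(),
                      start_frame = integer(), end_frame = integer(),
                      mean_area_um2 = numeric(), speed_um_s = numeric()))
  do.call(rbind, lapply(split(obs, obs$traj), function(tr) {
    data.frame(traj = tr$traj[1], cell = tr$cell[1], n_obs = nrow(tr),
               start_frame = min(tr$frame), end_frame = max(tr$frame),
               mean_area_um2 = mean(tr$area_um2),
               speed_um_s = trajectory_speed(tr, frame_interval))
  }))
}
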