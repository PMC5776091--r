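## Formation and dispersal event detection in per-cell SDI time series,
## quiescence-exit sub-population classification, sister-cell inheritance,
## and formation-timing statistics.

#' Detect a focus-formation event in a cell track
#'
#' Formation is called at the first frame where the SDI is at least
#' `jump_factor` times the median SDI of the trailing baseline window and
#' the focus is detected for at least two consecutive frames from that
#' frame on (the SDI roughly doubles upon formation, which is why the
#' default jump factor is 2).
#'
#' @param track data.frame with columns `frame`, `time_min`, `sdi`,
#'   `cluster_present` ordered or orderable by frame.
#' @param jump_factor SDI ratio that signals formation.
#' @param baseline_window Number of trailing frames forming the baseline.
#' @return data.frame with one event row (cell, type = "formation",
#'   frame, time_min, sdi_ratio), or NULL if no event is found.
#' @export
detect_formation_event <- function(track, jump_factor = 2,
                                   baseline_window = 3L) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < baseline_window + 1L)
    stop("track needs at least baseline_window + 1 frames")
  present <- !is.na(track$cluster_present) & track$cluster_present
  for (i in (baseline_window + 1L):n) {
    base <- stats::median(track$sdi[(i - baseline_window):(i - 1L)])
    if (base <= 0) base <- 1e-12
    ratio <- track$sdi[i] / base
    persist <- present[i] && (i == n || present[i + 1L])
    if (ratio >= jump_factor && persist) {
      return(data.frame(cell = track$cell[1], type = "formation",
                        frame = track$frame[i],
                        time_min = track$time_min[i], sdi_ratio = ratio))
    }
  }
  NULL
}

#' Detect gradual focus dispersal in a cell track
#'
#' Dispersal is declared when a monotone non-increasing SDI run spanning
#' `slope_window` frames accumulates a relative drop of at least
#' `min_rel_drop`, or when the focus disappears (cluster_present false)
#' for at least two consecutive frames. The event time is the end of the
#' run.
#'
#' @param track data.frame as in [detect_formation_event()]; the track
#'   must begin with the focus present.
#' @param slope_window Length of the declining run, frames.
#' @param min_rel_drop Relative SDI drop that signals dispersal.
#' @return data.frame with one event row (cell, type = "dispersal", frame,
#'   time_min, rel_drop), or NULL.
#' @export
detect_dispersal <- function(track, slope_window = 5L, min_rel_drop = 0.4) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  present <- !is.na(track$cluster_present) & track$cluster_present
  if (!present[1]) stop("track must begin with the focus present")
  ## disappearance rule
  for (i in seq_len(n - 1L)) {
    if (!present[i] && !present[i + 1L]) {
      return(data.frame(cell = track$cell[1], type = "dispersal",
                        frame = track$frame[i], time_min = track$time_min[i],
                        rel_drop = NA_real_))
    }
  }
  ## gradual-decline rule
  if (n >= slope_window) {
    for (i in seq_len(n - slope_window + 1L)) {
      w <- track$sdi[i:(i + slope_window - 1L)]
      if (all(diff(w) <= 1e-12) && w[1] > 0) {
        drop <- (w[1] - w[slope_window]) / w[1]
        if (drop >= min_rel_drop) {
          return(data.frame(cell = track$cell[1], type = "dispersal",
                            frame = track$frame[i + slope_window - 1L],
                            time_min = track$time_min[i + slope_window - 1L],
                            rel_drop = drop))
        }
      }
    }
  }
  NULL
}

#' Classify quiescence-exit cells by their time-0 focus status
#'
#' Cells without a detectable focus at time 0 form the "none" class; cells
#' with a focus are split into "small" and "big" by a threshold on the
#' time-0 SDI — by default Otsu's threshold computed on the SDI
#' distribution of the focus-bearing cells.
#'
#' @param time0 data.frame with one row per cell: columns `cell`, `sdi`,
#'   `cluster_present`.
#' @param sdi_big_threshold Numeric threshold, or NULL for Otsu.
#' @return List with `classes` (data.frame cell/class), `fractions` over
#'   (none, small, big), `threshold`, and `n`.
#' @export
classify_quiescence_subpopulations <- function(time0,
                                               sdi_big_threshold = NULL) {
  stopifnot(nrow(time0) > 0)
  present <- !is.na(time0$cluster_present) & time0$cluster_present
  cls <- rep("none", nrow(time0))
  thr <- NA_real_
  if (any(present)) {
    sdis <- time0$sdi[present]
    thr <- if (is.null(sdi_big_threshold)) otsu_threshold(sdis)
      else sdi_big_threshold
    cls[present] <- ifelse(sdis > thr, "big", "small")
  }
  fr <- as.numeric(table(factor(cls, levels = c("none", "small", "big")))) /
    nrow(time0)
  names(fr) <- c("none", "small", "big")
  list(classes = data.frame(cell = time0$cell, class = cls),
       fractions = fr, threshold = thr, n = nrow(time0))
}

## 1-D Otsu threshold: midpoint between classes that maximizes the
## between-class variance of the two-group split of a numeric vector.
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(if (n) x[1] else NA_real_)
  best <- -Inf; thr <- mean(x)
  csum <- cumsum(x); total <- csum[n]
  for (k in seq_len(n - 1L)) {
    w1 <- k / n; w2 <- 1 - w1
    m1 <- csum[k] / k; m2 <- (total - csum[k]) / (n - k)
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best) { best <- v; thr <- (x[k] + x[k + 1L]) / 2 }
  }
  thr
}

#' Sister-cell focus status after division
#'
#' For every completed division with both daughters tracked, evaluates
#' focus presence at the evaluation frame (by default each pair's last
#' common tracked frame) and reports the fraction of pairs in which only
#' one sister carries a focus versus both; these two fractions sum to 1
#' over the pairs with at least one focus-bearing sister. Pairs in which
#' neither sister has a focus are reported separately.
#'
#' @param tracks data.frame with one row per (cell, frame): columns
#'   `cell`, `frame`, `cluster_present`, `parent`, `sister`.
#' @param at Evaluation frame; NULL = each pair's last common frame.
#' @return List with `pairs` (per-pair detail), `one_sister_only`,
#'   `both_sisters`, `neither`, `n_pairs`, and `final_frame_cluster_frac`
#'   (fraction of all cells with a focus at their last frame).
#' @export
sister_cluster_status <- function(tracks, at = NULL) {
  div <- unique(tracks[!is.na(tracks$sister), c("cell", "sister")])
  div <- div[div$cell < div$sister, , drop = FALSE]
  if (nrow(div) == 0L) {
    warning("no completed divisions in the track table")
    return(list(pairs = NULL, one_sister_only = NA_real_,
                both_sisters = NA_real_, neither = NA_real_, n_pairs = 0L,
                final_frame_cluster_frac = NA_real_))
  }
  rows <- lapply(seq_len(nrow(div)), function(i) {
    a <- tracks[tracks$cell == div$cell[i], , drop = FALSE]
    b <- tracks[tracks$cell == div$sister[i], , drop = FALSE]
    common <- intersect(a$frame, b$frame)
    if (length(common) == 0L) return(NULL)
    fr <- if (is.null(at)) max(common) else at
    if (!(fr %in% common)) return(NULL)
    pa <- isTRUE(a$cluster_present[a$frame == fr])
    pb <- isTRUE(b$cluster_present[b$frame == fr])
    data.frame(cell_a = div$cell[i], cell_b = div$sister[i], frame = fr,
               a_present = pa, b_present = pb)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no sister pair shares a tracked frame")
    return(list(pairs = NULL, one_sister_only = NA_real_,
                both_sisters = NA_real_, neither = NA_real_, n_pairs = 0L,
                final_frame_cluster_frac = NA_real_))
  }
  one <- xor(pairs$a_present, pairs$b_present)
  both <- pairs$a_present & pairs$b_present
  neither <- !pairs$a_present & !pairs$b_present
  informative <- sum(one) + sum(both)
  last <- tapply(seq_len(nrow(tracks)), tracks$cell, function(ii) {
    jj <- ii[which.max(tracks$frame[ii])]
    isTRUE(tracks$cluster_present[jj])
  })
  list(pairs = pairs,
       one_sister_only = if (informative) sum(one) / informative else NA_real_,
       both_sisters = if (informative) sum(both) / informative else NA_real_,
       neither = mean(neither), n_pairs = nrow(pairs),
       final_frame_cluster_frac = mean(unlist(last)))
}

#' Formation-timing distributions and cell-cycle association tests
#'
#' Summarizes when new foci form relative to cell birth: the
#' formation-time distribution, the cell-length-at-formation
#' distribution, the rank correlation of formation time with birth
#' length (a cell-cycle-phase proxy), an exponential goodness-of-fit test
#' of the formation times, and a comparison of cycle durations between
#' cells born with and without a focus.
#'
#' @param events data.frame of formation events (columns `cell`,
#'   `time_min`).
#' @param tracks data.frame with per-cell rows: `cell`, `birth_time`,
#'   `birth_length`, `born_with_cluster`, and optionally `cycle_duration`.
#' @return List with `formation_times`, `lengths_at_formation`,
#'   `time_length_cor` (a [correlation()] result), `exp_gof` (ks.test),
#'   and `cycle_comparison` (t.test or NULL).
#' @export
formation_timing_stats <- function(events, tracks) {
  ev <- events[events$type == "formation" | is.null(events$type), ,
               drop = FALSE]
  if (nrow(ev) < 10L) stop("need at least 10 formation events")
  m <- merge(ev, tracks, by = "cell")
  ft <- m$time_min - m$birth_time
  len_at <- m$birth_length + (if (!is.null(m$growth_rate)) m$growth_rate
                              else 0) * ft
  tl <- correlation(ft, m$birth_length, method = "spearman")
  ## ties arise legitimately for degenerate (fixed-phase) event sets
  gof <- suppressWarnings(stats::ks.test(ft, "pexp", rate = 1 / mean(ft)))
  cyc <- NULL
  if (!is.null(tracks$cycle_duration) &&
      length(unique(tracks$born_with_cluster)) == 2L) {
    grp <- split(tracks$cycle_duration, tracks$born_with_cluster)
    if (all(vapply(grp, length, 0L) >= 2L))
      cyc <- stats::t.test(grp[[1]], grp[[2]])
  }
  list(formation_times = ft, lengths_at_formation = len_at,
       time_length_cor = tl, exp_gof = gof, cycle_comparison = cyc)
}
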