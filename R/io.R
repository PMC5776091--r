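## Disk interfaces: result tables as CSV with a JSON manifest, image
## stacks as multi-page TIFF (channel-major within frame).

#' Write analysis result tables to a directory
#'
#' Writes `cells.csv`, `observations.csv`, `trajectories.csv`,
#' `labels.csv` and a `manifest.json` carrying the package version, the
#' parameter set, a parameter hash, and the seed, so a run can be
#' identified and reproduced. Refuses to overwrite a manifest written
#' with different parameters unless `overwrite = TRUE`.
#'
#' @param result List from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @param overwrite Allow replacing results from a different run.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, seed = NA_integer_,
                          overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- param_signature(result$params)
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath) && !overwrite) {
    old <- jsonlite::read_json(mpath)
    if (!identical(old$param_hash, hash))
      stop("directory holds results from different parameters; ",
           "set overwrite = TRUE to replace them")
  }
  for (nm in c("cells", "observations", "trajectories", "labels")) {
    if (!is.null(result[[nm]]))
      utils::write.csv(result[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  manifest <- list(package = "polefocus",
                   version = as.character(utils::packageVersion("polefocus")),
                   param_hash = hash, seed = seed,
                   params = result$params)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

## Canonical parameter signature recorded in the manifest; two runs with
## the same signature used identical parameters.
param_signature <- function(params) {
  params <- params[order(names(params))]
  paste(names(params), vapply(params, function(x)
    paste(format(x, digits = 12), collapse = ","), ""),
    sep = "=", collapse = ";")
}

#' Write an image stack as multi-page TIFF
#'
#' Pages are ordered frame-major, channel-minor; intensities are scaled
#' to [0, 1] by the stack maximum (recorded in the sidecar JSON together
#' with pixel size, frame interval, and channel names, so the stack can
#' be read back losslessly up to float precision).
#'
#' @param stack An [image_stack()].
#' @param path Output `.tif` path; the sidecar is written at
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  mx <- max(vapply(stack$frames, max, 0), 1e-12)
  pages <- list()
  for (fr in stack$frames)
    for (ci in seq_along(stack$channels))
      pages[[length(pages) + 1L]] <- fr[, , ci] / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(channels = stack$channels,
                            pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            n_frames = length(stack$frames),
                            intensity_scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path with its `<path>.json` sidecar.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channels)
  frames <- vector("list", meta$n_frames)
  for (k in seq_len(meta$n_frames)) {
    d <- dim(pages[[1]])
    arr <- array(0, dim = c(d[1], d[2], nc))
    for (ci in seq_len(nc))
      arr[, , ci] <- pages[[(k - 1L) * nc + ci]] * meta$intensity_scale
    frames[[k]] <- arr
  }
  image_stack(frames, meta$channels, meta$pixel_size, meta$frame_interval)
}

#' Write ground truth tables to CSV
#'
#' @param truth Truth list from [simulate_population()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$lineage, file.path(dir, "lineage.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  cfg <- truth$config
  cfg$frap <- NULL
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
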