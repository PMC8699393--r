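# Migration velocity from centroid tracks.
#
# Centroids are compared on a 2-h grid because shorter intervals put step
# distances within microscope stage-relocation error.  The grid is anchored
# at each cell's first observation (daughters are born off any global
# grid).  When the final observation falls less than one interval after the
# last grid point, that grid point is removed so the final interval exceeds
# the grid spacing.

#' Resample a centroid path to the velocity grid
#'
#' Keeps observations at whole multiples of `interval` after the first
#' point plus the final observation, then applies the last-interval rule:
#' if the gap from the last retained grid point to the final point is
#' shorter than `interval`, that grid point is dropped.
#'
#' @param path Data frame with columns `time_h`, `x_um`, `y_um`, strictly
#'   increasing in time.
#' @param interval Grid spacing, hours (default 2).
#' @return The resampled path with attribute `short_track` set to `TRUE`
#'   when the whole track spans less than one interval.
#' @export
resample_to_grid <- function(path, interval = 2) {
  stopifnot(all(c("time_h", "x_um", "y_um") %in% names(path)))
  path <- path[order(path$time_h), , drop = FALSE]
  if (nrow(path) > 1L && any(diff(path$time_h) <= 0))
    stop("parameter error: observation times must be strictly increasing")
  n <- nrow(path)
  if (n < 2L) {
    attr(path, "short_track") <- TRUE
    return(path)
  }
  t0 <- path$time_h[1L]
  rel <- path$time_h - t0
  tol <- 1e-9
  on_grid <- abs(rel / interval - round(rel / interval)) < tol
  keep <- on_grid
  keep[n] <- TRUE
  idx <- which(keep)
  # last-interval rule
  if (length(idx) >= 3L) {
    last <- idx[length(idx)]
    prev <- idx[length(idx) - 1L]
    if (prev != last && path$time_h[last] - path$time_h[prev] < interval - tol)
      idx <- idx[-(length(idx) - 1L)]
  }
  out <- path[idx, , drop = FALSE]
  attr(out, "short_track") <-
    (out$time_h[nrow(out)] - out$time_h[1L]) < interval - tol
  out
}

#' Mean migration velocity of a centroid path
#'
#' Sum of Euclidean step distances between successive retained centroids,
#' divided by the total time tracked, expressed in micrometres per day.
#'
#' @param path Resampled centroid path ([resample_to_grid()]) with at
#'   least 2 points.
#' @return Velocity in micrometres/day.
#' @export
migration_velocity <- function(path) {
  if (nrow(path) < 2L)
    stop("degenerate-path error: at least 2 points required")
  elapsed_h <- path$time_h[nrow(path)] - path$time_h[1L]
  if (elapsed_h <= 0) stop("parameter error: zero elapsed time")
  dist <- sum(sqrt(diff(path$x_um)^2 + diff(path$y_um)^2))
  dist / (elapsed_h / 24)
}

#' Migration velocities for every cell of a forest
#'
#' @param forest A [lineage_forest()].
#' @param interval Grid spacing in hours.
#' @param cell_type,condition Restrict to these cells.
#' @return Data frame: `cell_id`, `n_points_used`, `elapsed_days`,
#'   `velocity_um_per_day` (`NA` for degenerate single-point tracks),
#'   `short_track` flag.
#' @export
migration_velocities <- function(forest, interval = 2,
                                 cell_type = "SAOS-2",
                                 condition = "co-culture") {
  stopifnot(inherits(forest, "lineage_forest"))
  cells <- forest$cells
  ids <- cells$cell_id[cells$cell_type == cell_type &
                       cells$condition == condition]
  out <- lapply(ids, function(id) {
    o <- cell_obs(forest, id)
    o <- o[!is.na(o$x_um) & !is.na(o$y_um), c("time_h", "x_um", "y_um")]
    if (nrow(o) < 2L)
      return(data.frame(cell_id = id, n_points_used = nrow(o),
                        elapsed_days = NA_real_,
                        velocity_um_per_day = NA_real_, short_track = TRUE,
                        stringsAsFactors = FALSE))
    rs <- resample_to_grid(o, interval)
    if (nrow(rs) < 2L)
      return(data.frame(cell_id = id, n_points_used = nrow(rs),
                        elapsed_days = NA_real_,
                        velocity_um_per_day = NA_real_, short_track = TRUE,
                        stringsAsFactors = FALSE))
    data.frame(cell_id = id, n_points_used = nrow(rs),
               elapsed_days = (rs$time_h[nrow(rs)] - rs$time_h[1L]) / 24,
               velocity_um_per_day = migration_velocity(rs),
               short_track = isTRUE(attr(rs, "short_track")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
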