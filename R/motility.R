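# 2D migration metrics (speed, path-ratio persistence) and 3D spheroid
# invasion fold change.

.check_track <- function(t_min, x_um, y_um) {
  if (length(t_min) != length(x_um) || length(t_min) != length(y_um)) {
    stopf("times and positions must have equal length")
  }
  if (length(t_min) < 2L) stopf("a trajectory needs at least 2 time points")
  if (any(diff(t_min) <= 0)) stopf("times must be strictly increasing")
}

#' Cell migration speed of one trajectory
#'
#' Total path length (sum of successive Euclidean steps) divided by elapsed
#' time. Missing frames are tolerated: steps are taken between available
#' consecutive samples and elapsed time is last minus first observed time.
#'
#' @param t_min Times in minutes, strictly increasing.
#' @param x_um,y_um Positions in micrometres.
#' @return Speed in micrometres per minute.
#' @export
track_speed <- function(t_min, x_um, y_um) {
  .check_track(t_min, x_um, y_um)
  path <- sum(sqrt(diff(x_um)^2 + diff(y_um)^2))
  path / (t_min[length(t_min)] - t_min[1])
}

#' Path-ratio persistence of one trajectory
#'
#' Euclidean distance between start and finish divided by the total distance
#' travelled; 1 for straight-line motion, 0 for a track returning to its
#' start. Undefined (NA, with a warning) for a zero-length path.
#'
#' @inheritParams track_speed
#' @return Persistence in [0, 1], or NA for a stationary track.
#' @export
track_persistence <- function(t_min, x_um, y_um) {
  .check_track(t_min, x_um, y_um)
  path <- sum(sqrt(diff(x_um)^2 + diff(y_um)^2))
  if (path <= 0) {
    warnf("zero path length: persistence undefined")
    return(NA_real_)
  }
  net <- sqrt((x_um[length(x_um)] - x_um[1])^2 +
                (y_um[length(y_um)] - y_um[1])^2)
  min(net / path, 1)
}

#' Spheroid invasion fold change
#'
#' Day-5 projected area divided by day-1 area, the single 3D-invasion metric.
#'
#' @param area_day1,area_day5 Projected spheroid areas (> 0), square
#'   micrometres. Vectorised.
#' @return Fold change(s).
#' @export
fold_change <- function(area_day1, area_day5) {
  if (any(area_day1 <= 0) || any(area_day5 <= 0)) {
    stopf("spheroid areas must be positive")
  }
  area_day5 / area_day1
}

#' Per-cell migration metrics from a trajectory table
#'
#' Computes speed and persistence for every track in a long-format trajectory
#' table (as written by the synthetic generator). Tracks with fewer than 3
#' time points are dropped: the persistence of a 2-point track is identically
#' 1 and uninformative.
#'
#' @param tracks Data frame with columns
#'   \code{condition, cell_id, t_min, x_um, y_um}.
#' @return Data frame with one row per retained cell:
#'   \code{condition, cell_id, speed, persistence}.
#' @export
motility_table <- function(tracks) {
  need <- c("condition", "cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stopf("tracks must have columns %s", paste(need, collapse = ", "))
  }
  key <- interaction(tracks$condition, tracks$cell_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(tracks)), key), function(ii) {
    tr <- tracks[ii, ]
    tr <- tr[order(tr$t_min), ]
    if (nrow(tr) < 3L) return(NULL)
    data.frame(condition = tr$condition[1], cell_id = tr$cell_id[1],
               speed = track_speed(tr$t_min, tr$x_um, tr$y_um),
               persistence = track_persistence(tr$t_min, tr$x_um, tr$y_um))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-spheroid fold changes from a spheroid table
#'
#' @param spheroids Data frame with columns
#'   \code{condition, replicate, area_day1_um2, area_day5_um2}.
#' @return The input with a \code{fold} column appended.
#' @export
spheroid_folds <- function(spheroids) {
  need <- c("condition", "replicate", "area_day1_um2", "area_day5_um2")
  if (!all(need %in% names(spheroids))) {
    stopf("spheroids must have columns %s", paste(need, collapse = ", "))
  }
  spheroids$fold <- fold_change(spheroids$area_day1_um2,
                                spheroids$area_day5_um2)
  spheroids
}
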