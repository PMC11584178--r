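#' @title CASA kinematic parameters and the sideward-movement ratio
#'
#' @description
#' Per-trajectory kinematic parameters in the computer-assisted sperm
#' analysis (CASA) convention:
#' \describe{
#'   \item{VCL}{curvilinear velocity — total path length divided by track
#'     duration (um/s). Gap-closed missing frames contribute one straight
#'     segment between their flanking spots.}
#'   \item{VSL}{straight-line velocity — distance between the first and
#'     last spots divided by track duration (um/s).}
#'   \item{LIN}{linearity of forward progression — VSL/VCL, in `[0, 1]`.}
#'   \item{SWR}{straight line-to-sideward movement ratio — track
#'     displacement divided by the maximum sideward movement distance: the
#'     width of the narrowest band parallel to the displacement line that
#'     contains every spot.}
#' }
#' Degenerate cases (single spot, zero path, zero displacement, perfectly
#' straight track for SWR) yield `NA` markers that propagate as missing
#' values rather than zeros.
#'
#' A trajectory is a data frame with numeric columns `frame`, `x_um`,
#' `y_um`, one row per retained spot, frames strictly increasing.
#'
#' @param traj Trajectory data frame (columns `frame`, `x_um`, `y_um`).
#' @param fps Frame rate (frames/s).
#' @return A single numeric value, or for [compute_kinematics()] a one-row
#'   data frame per track.
#' @name kinematics
NULL

traj_xy <- function(traj) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(traj)))
  if (nrow(traj) >= 2 && any(diff(traj$frame) <= 0)) {
    stop("trajectory frames must be strictly increasing", call. = FALSE)
  }
  cbind(traj$x_um, traj$y_um)
}

#' @rdname kinematics
#' @export
total_time <- function(traj, fps) {
  stopifnot(fps > 0)
  if (nrow(traj) < 2) stop("duration undefined for a single-spot trajectory",
                           call. = FALSE)
  (traj$frame[nrow(traj)] - traj$frame[1]) / fps
}

#' @rdname kinematics
#' @export
vcl <- function(traj, fps) {
  xy <- traj_xy(traj)
  path_length(xy) / total_time(traj, fps)
}

#' @rdname kinematics
#' @export
vsl <- function(traj, fps) {
  xy <- traj_xy(traj)
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2)) / total_time(traj, fps)
}

#' @rdname kinematics
#' @export
lin <- function(traj, fps) {
  v <- vcl(traj, fps)
  if (!is.finite(v) || v == 0) return(NA_real_)
  vsl(traj, fps) / v
}

#' @rdname kinematics
#' @export
max_sideward <- function(traj) {
  xy <- traj_xy(traj)
  if (nrow(xy) < 2) stop("need at least two spots", call. = FALSE)
  disp <- xy[nrow(xy), ] - xy[1, ]
  nd <- sqrt(sum(disp^2))
  if (nd == 0) return(NA_real_)  # displacement direction undefined
  n <- c(-disp[2], disp[1]) / nd
  proj <- xy %*% n
  max(proj) - min(proj)
}

#' @rdname kinematics
#' @export
swr <- function(traj) {
  xy <- traj_xy(traj)
  if (nrow(xy) < 2) stop("need at least two spots", call. = FALSE)
  disp <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  ms <- max_sideward(traj)
  if (is.na(ms) || ms < 1e-9) return(NA_real_)
  disp / ms
}

path_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Kinematics table for a set of trajectories
#'
#' Computes all kinematic parameters for every track in a spot table.
#'
#' @param spots Data frame of spots with columns `track_id`, `frame`,
#'   `x_um`, `y_um` (one or more tracks).
#' @param fps Frame rate (frames/s).
#' @return Data frame with one row per track: `track_id`, `n_spots`,
#'   `duration_s`, `vcl`, `vsl`, `lin`, `swr`, `displacement_um`,
#'   `max_sideward_um`, `total_path_um`. Undefined quantities are `NA`.
#' @export
#' @examples
#' zig <- data.frame(track_id = 1, frame = 0:4,
#'                   x_um = 0:4, y_um = c(0, 1, 0, 1, 0))
#' compute_kinematics(zig, fps = 30)
compute_kinematics <- function(spots, fps) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(spots)))
  ids <- unique(spots$track_id)
  out <- lapply(ids, function(id) {
    tr <- spots[spots$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) {
      return(data.frame(track_id = id, n_spots = nrow(tr),
                        duration_s = NA_real_, vcl = NA_real_,
                        vsl = NA_real_, lin = NA_real_, swr = NA_real_,
                        displacement_um = NA_real_,
                        max_sideward_um = NA_real_,
                        total_path_um = NA_real_))
    }
    xy <- traj_xy(tr)
    dur <- total_time(tr, fps)
    tp <- path_length(xy)
    disp <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
    v1 <- tp / dur
    v2 <- disp / dur
    ms <- max_sideward(tr)
    data.frame(
      track_id = id, n_spots = nrow(tr), duration_s = dur,
      vcl = v1, vsl = v2,
      lin = if (v1 > 0) v2 / v1 else NA_real_,
      swr = if (!is.na(ms) && ms >= 1e-9) disp / ms else NA_real_,
      displacement_um = disp, max_sideward_um = ms, total_path_um = tp
    )
  })
  do.call(rbind, out)
}
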