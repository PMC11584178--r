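#' Extract boundary pixels from a binary wall mask
#'
#' Boundary pixels are foreground pixels with at least one background
#' 4-neighbour. Coordinates use the pixel-centre convention, 0-based
#' (x = column, y = row), scaled to micrometres.
#'
#' @param mask Binary matrix (0 background, non-zero foreground).
#' @param pixel_size_um Pixel size in micrometres.
#' @return Data frame with columns `x_um`, `y_um`.
#' @export
extract_boundary <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  fg <- mask != 0
  if (!any(fg) || all(fg)) {
    stop("mask must contain both foreground and background pixels",
         call. = FALSE)
  }
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- fg
  # replicate edges: pixels at the image border are boundary only if a
  # background pixel neighbours them inside the image
  pad[1, 2:(w + 1)] <- fg[1, ]
  pad[h + 2, 2:(w + 1)] <- fg[h, ]
  pad[2:(h + 1), 1] <- fg[, 1]
  pad[2:(h + 1), w + 2] <- fg[, w]
  inner <- pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)]
  bnd <- fg & !inner
  idx <- which(bnd, arr.ind = TRUE)
  out <- data.frame(x_um = (idx[, "col"] - 1) * pixel_size_um,
                    y_um = (idx[, "row"] - 1) * pixel_size_um)
  rownames(out) <- NULL
  out
}

#' Fit a straight wall line to boundary points
#'
#' Ordinary least squares on the axis of larger coordinate extent: y is
#' regressed on x when the x-range is at least the y-range, otherwise x on
#' y. The axis choice avoids the degenerate-slope case of a near-vertical
#' wall. A total-least-squares (orthogonal) fit is available as an option.
#'
#' @param points Data frame or matrix with two columns (`x_um`, `y_um`).
#' @param method `"ols"` (axis chosen by extent) or `"tls"` (orthogonal
#'   regression via principal axis).
#' @return A [wall_model()] with `fit_rmse_um` the RMS perpendicular
#'   residual of the points about the line.
#' @export
#' @examples
#' fit_wall(data.frame(x_um = 0:10, y_um = 0.5 * (0:10) + 2))
fit_wall <- function(points, method = c("ols", "tls")) {
  method <- match.arg(method)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(unique(pts)) < 2) {
    stop("need at least two distinct points to fit a wall", call. = FALSE)
  }
  rx <- diff(range(pts[, 1])); ry <- diff(range(pts[, 2]))
  if (rx == 0 && ry == 0) stop("zero extent on both axes", call. = FALSE)

  if (method == "tls") {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    dir <- sv$v[, 1]
    point <- ctr
  } else if (rx >= ry) {
    fit <- stats::lm.fit(cbind(1, pts[, 1]), pts[, 2])
    b <- fit$coefficients
    dir <- c(1, b[2])
    point <- c(0, b[1])
  } else {
    fit <- stats::lm.fit(cbind(1, pts[, 2]), pts[, 1])
    b <- fit$coefficients
    dir <- c(b[2], 1)
    point <- c(b[1], 0)
  }
  wm <- wall_model(point, dir)
  res <- wall_signed_distance(pts[, 1], pts[, 2], wm)
  wm$fit_rmse_um <- sqrt(mean(res^2))
  wm$n_points <- nrow(pts)
  wm
}

#' Wall distance of a trajectory
#'
#' Perpendicular distance from the trajectory's temporal midpoint spot
#' (index `floor((n - 1) / 2)` of the retained spots, 0-based) to the wall
#' line. The spot centroid is available as an alternative reference.
#'
#' @param traj Trajectory data frame (`frame`, `x_um`, `y_um`).
#' @param wall A [wall_model()].
#' @param ref `"midpoint"` (default) or `"centroid"`.
#' @return Distance in micrometres (>= 0).
#' @export
wall_distance <- function(traj, wall, ref = c("midpoint", "centroid")) {
  ref <- match.arg(ref)
  xy <- traj_xy(traj)
  if (nrow(xy) < 1) stop("empty trajectory", call. = FALSE)
  p <- if (ref == "midpoint") xy[floor((nrow(xy) - 1) / 2) + 1, ]
       else colMeans(xy)
  abs(wall_signed_distance(p[1], p[2], wall))
}

#' Wall angle of a trajectory
#'
#' Acute angle between the trajectory's displacement line (first to last
#' spot) and the wall line, `acos(|u . w|)`, folded into `[0, pi/2]`.
#'
#' @inheritParams wall_distance
#' @return Angle in radians, or `NA` for zero displacement.
#' @export
wall_angle <- function(traj, wall) {
  xy <- traj_xy(traj)
  if (nrow(xy) < 2) stop("need at least two spots", call. = FALSE)
  disp <- xy[nrow(xy), ] - xy[1, ]
  nd <- sqrt(sum(disp^2))
  if (nd == 0) return(NA_real_)
  acos(min(1, abs(sum(disp / nd * wall$direction))))
}

#' Wall relation table for a set of trajectories
#'
#' @param spots Spot data frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param wall A [wall_model()].
#' @inheritParams wall_distance
#' @return Data frame `track_id`, `distance_um`, `angle_rad`.
#' @export
wall_relation <- function(spots, wall, ref = c("midpoint", "centroid")) {
  ref <- match.arg(ref)
  ids <- unique(spots$track_id)
  out <- lapply(ids, function(id) {
    tr <- spots[spots$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    data.frame(
      track_id = id,
      distance_um = wall_distance(tr, wall, ref),
      angle_rad = if (nrow(tr) >= 2) wall_angle(tr, wall) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Classify a wall-contact turn as pro- or anti-wall-hook
#'
#' Finds the first frame at which the trajectory enters the wall-contact
#' band (perpendicular spot-to-wall distance below `contact_threshold_um`),
#' averages the heading over `k` frames before and after contact, and
#' labels the turn `"pro"` when the post-contact along-wall direction lies
#' on the sperm's hook side of its pre-contact heading, `"anti"` when it
#' lies on the opposite side, and `"none"` when the trajectory never makes
#' wall contact.
#'
#' @param traj Trajectory data frame (`frame`, `x_um`, `y_um`).
#' @param wall A [wall_model()].
#' @param hook_side `"left"` or `"right"` of the heading direction.
#' @param contact_threshold_um Contact distance threshold (micrometres).
#' @param k Number of frames averaged on each side of contact.
#' @return `"pro"`, `"anti"` or `"none"`.
#' @export
classify_turn <- function(traj, wall, hook_side = c("left", "right"),
                          contact_threshold_um = 2, k = 3) {
  hook_side <- match.arg(hook_side)
  xy <- traj_xy(traj)
  d <- abs(wall_signed_distance(xy[, 1], xy[, 2], wall))
  hit <- which(d < contact_threshold_um)
  if (!length(hit)) return("none")
  i <- hit[1]
  if (i - k < 1 || i + k > nrow(xy)) {
    stop("trajectory too short to average ", k,
         " frames on each side of contact", call. = FALSE)
  }
  pre <- xy[i, ] - xy[i - k, ]
  post <- xy[i + k, ] - xy[i, ]
  w <- wall$direction
  along <- sign(sum(post * w))
  if (along == 0) along <- 1
  side <- cross2(pre, along * w)
  hook_sign <- if (hook_side == "left") 1 else -1
  if (sign(side) == hook_sign) "pro" else "anti"
}
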