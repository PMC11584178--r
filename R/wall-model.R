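#' Straight-line wall model
#'
#' A `wall_model` represents the uterine wall as a straight line in
#' micrometre coordinates: a point on the line plus a unit direction
#' vector. Models are produced by [fit_wall()] from boundary pixels, or
#' constructed directly (e.g. the true wall of a simulation).
#'
#' @param point Numeric length-2: a point (x, y) on the line, micrometres.
#' @param direction Numeric length-2: line direction; normalised internally.
#' @param fit_rmse_um Residual RMS of the boundary points about the line.
#' @param n_points Number of points the line was fitted to.
#'
#' @return An object of class `wall_model`.
#' @export
#' @examples
#' w <- wall_model(c(0, 100), c(1, 0))
#' w$direction
wall_model <- function(point, direction, fit_rmse_um = 0, n_points = 0L) {
  point <- as.numeric(point)
  direction <- as.numeric(direction)
  stopifnot(length(point) == 2, length(direction) == 2,
            all(is.finite(point)), all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("wall direction must be non-zero", call. = FALSE)
  structure(
    list(point = point, direction = direction / nrm,
         fit_rmse_um = fit_rmse_um, n_points = as.integer(n_points)),
    class = "wall_model"
  )
}

#' @export
print.wall_model <- function(x, ...) {
  ang <- atan2(x$direction[2], x$direction[1])
  cat(sprintf(
    "wall_model: through (%.2f, %.2f) um at %.2f deg (n = %d, rmse = %.3g um)\n",
    x$point[1], x$point[2], ang * 180 / pi, x$n_points, x$fit_rmse_um
  ))
  invisible(x)
}

# signed perpendicular distance of points to the wall line;
# positive on the +1 cross-product side of the directed line
wall_signed_distance <- function(x, y, wall) {
  vx <- x - wall$point[1]
  vy <- y - wall$point[2]
  wall$direction[1] * vy - wall$direction[2] * vx
}

# 2-D cross product z-component
cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
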