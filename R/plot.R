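#' Plot simulated or tracked trajectories
#'
#' Draws every trajectory in image coordinates (y increasing downward)
#' with the wall line overlaid, and marks turn events for simulations.
#'
#' @param x A `sperm_sim` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sperm_sim <- function(x, ...) {
  plot_tracks(x$spots, wall = x$wall,
              events = x$turn_events, ...)
  invisible(x)
}

#' @rdname plot.sperm_sim
#' @param spots Spot data frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param wall Optional [wall_model()] to overlay.
#' @param events Optional turn-event data frame (`track_id`, `frame`).
#' @export
plot_tracks <- function(spots, wall = NULL, events = NULL, ...) {
  if (!nrow(spots)) {
    graphics::plot(0, 0, type = "n", xlab = "x (um)", ylab = "y (um)", ...)
    return(invisible(NULL))
  }
  graphics::plot(range(spots$x_um), rev(range(spots$y_um)), type = "n",
                 xlab = "x (um)", ylab = "y (um)", ylim = rev(range(spots$y_um)),
                 ...)
  ids <- unique(spots$track_id)
  cols <- grDevices::hcl.colors(max(3, length(ids)), "viridis")
  for (i in seq_along(ids)) {
    tr <- spots[spots$track_id == ids[i], ]
    tr <- tr[order(tr$frame), ]
    graphics::lines(tr$x_um, tr$y_um, col = cols[i])
  }
  if (!is.null(wall)) {
    graphics::abline(
      a = wall$point[2] - wall$point[1] * wall$direction[2] /
        wall$direction[1],
      b = wall$direction[2] / wall$direction[1], lty = 2
    )
  }
  if (!is.null(events) && nrow(events)) {
    ev <- merge(events, spots, by = c("track_id", "frame"))
    graphics::points(ev$x_um, ev$y_um,
                     pch = ifelse(ev$label == "pro", 17, 4),
                     col = ifelse(ev$label == "pro", "red", "blue"))
  }
  invisible(NULL)
}
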