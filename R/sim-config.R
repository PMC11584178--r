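#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic trajectory and
#' image-stack generator. Defaults emulate the acquisition geometry used for
#' in-utero sperm imaging: 512x512-pixel frames at 30 frames/s, 60-frame
#' (2 s) windows, and a roughly linear dark wall region at one side of the
#' field. Speeds follow a log-linear model in wall distance and wall angle,
#' and wall-contact turns are pro-wall-hook with probability
#' `pro_hook_prob`.
#'
#' @param field_width_px,field_height_px Frame size in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param fps Frame rate in frames per second.
#' @param n_frames Number of frames per stack (>= 2).
#' @param n_sperm Number of simulated sperm heads.
#' @param wall 2x2 numeric matrix; rows are two points (x, y) in pixel
#'   coordinates defining the wall line.
#' @param wall_side Which side of the directed line (point 1 to point 2) is
#'   wall tissue: `+1` for the positive cross-product side (below the line
#'   for a left-to-right horizontal wall in image coordinates), `-1` for the
#'   other.
#' @param base_log_vcl Intercept of the log-speed model, log(um/s) at the
#'   wall (distance 0, angle 0).
#' @param beta_distance Slope of log speed per micrometre of wall distance.
#' @param beta_angle Slope of log speed per radian of wall angle.
#' @param speed_log_sd Frame-wise log-speed noise SD (log units).
#' @param heading_sd Angular diffusion SD per frame (radians).
#' @param noise_sd_um Positional jitter SD added per axis to reported spot
#'   positions (micrometres).
#' @param pro_hook_prob Probability in `[0, 1]` that a wall-contact turn is
#'   pro-wall-hook.
#' @param contact_threshold_um Perpendicular distance below which a sperm is
#'   in wall contact; a turn event fires on entering this band.
#' @param blob_sigma_um Gaussian SD of a rendered sperm head (micrometres).
#' @param spawn_box Optional numeric vector `c(xmin, xmax, ymin, ymax)` in
#'   micrometres restricting initial positions; default is the lumen-side
#'   part of the field.
#' @param spawn_positions Optional `n_sperm x 2` matrix of exact starting
#'   positions (micrometres); overrides `spawn_box`.
#' @param init_heading Optional initial heading(s) in radians (scalar or
#'   length `n_sperm`); default uniform random.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_sperm = 5, n_frames = 30, seed = 7)
#' cfg$fps
sim_config <- function(field_width_px = 512L,
                       field_height_px = 512L,
                       pixel_size_um = 0.75,
                       fps = 30,
                       n_frames = 60L,
                       n_sperm = 20L,
                       wall = rbind(c(0, 460), c(511, 460)),
                       wall_side = 1L,
                       base_log_vcl = log(80),
                       beta_distance = -0.004,
                       beta_angle = -0.3,
                       speed_log_sd = 0.1,
                       heading_sd = 0.2,
                       noise_sd_um = 0.1,
                       pro_hook_prob = 0.8254,
                       contact_threshold_um = 2,
                       blob_sigma_um = 1.0,
                       spawn_box = NULL,
                       spawn_positions = NULL,
                       init_heading = NULL,
                       seed = 1L) {
  cfg <- list(
    field_width_px = as.integer(field_width_px),
    field_height_px = as.integer(field_height_px),
    pixel_size_um = pixel_size_um,
    fps = fps,
    n_frames = as.integer(n_frames),
    n_sperm = as.integer(n_sperm),
    wall = as.matrix(wall),
    wall_side = sign(wall_side),
    base_log_vcl = base_log_vcl,
    beta_distance = beta_distance,
    beta_angle = beta_angle,
    speed_log_sd = speed_log_sd,
    heading_sd = heading_sd,
    noise_sd_um = noise_sd_um,
    pro_hook_prob = pro_hook_prob,
    contact_threshold_um = contact_threshold_um,
    blob_sigma_um = blob_sigma_um,
    spawn_box = if (length(spawn_box)) as.numeric(spawn_box),
    spawn_positions = if (length(spawn_positions)) as.matrix(spawn_positions),
    init_heading = if (length(init_heading)) as.numeric(init_heading),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$field_width_px >= 1, cfg$field_height_px >= 1,
    is.finite(cfg$pixel_size_um), cfg$pixel_size_um > 0,
    is.finite(cfg$fps), cfg$fps > 0,
    cfg$n_frames >= 2,
    cfg$n_sperm >= 0,
    is.matrix(cfg$wall), nrow(cfg$wall) == 2, ncol(cfg$wall) == 2,
    cfg$wall_side %in% c(-1, 1),
    is.finite(cfg$base_log_vcl),
    is.finite(cfg$beta_distance),
    is.finite(cfg$beta_angle),
    cfg$speed_log_sd >= 0,
    cfg$heading_sd >= 0,
    cfg$noise_sd_um >= 0,
    cfg$pro_hook_prob >= 0, cfg$pro_hook_prob <= 1,
    cfg$contact_threshold_um > 0,
    cfg$blob_sigma_um > 0
  )
  if (sqrt(sum((cfg$wall[2, ] - cfg$wall[1, ])^2)) == 0) {
    stop("wall line has zero length", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %dx%d px (%.3g um/px), %d frames @ %g fps, %d sperm\n",
    x$field_width_px, x$field_height_px, x$pixel_size_um,
    x$n_frames, x$fps, x$n_sperm
  ))
  cat(sprintf(
    "  log-speed: %.3f %+.3g*distance %+.3g*angle (sd %.3g)\n",
    x$base_log_vcl, x$beta_distance, x$beta_angle, x$speed_log_sd
  ))
  cat(sprintf("  pro-hook turn probability: %.4f; seed %d\n",
              x$pro_hook_prob, x$seed))
  invisible(x)
}
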