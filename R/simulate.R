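#' Simulate ground-truth sperm trajectories near a wall
#'
#' Each sperm head performs a persistent random walk whose frame-wise speed
#' follows a log-linear model in its perpendicular distance to the wall line
#' and the acute angle between its heading and the wall:
#' `log s = base_log_vcl + beta_distance * d + beta_angle * theta + eps`,
#' with `eps ~ N(0, speed_log_sd)`. The heading diffuses with SD
#' `heading_sd` per frame. When a sperm enters the wall-contact band
#' (perpendicular distance below `contact_threshold_um`) a turn event
#' fires: with probability `pro_hook_prob` the sperm turns to swim along
#' the wall on the side of its apical hook (pro-wall-hook), otherwise its
#' heading is reflected away from the wall (anti-wall-hook). Each sperm
#' carries a fixed hook side (left or right of its heading), assigned
#' 50/50 at birth.
#'
#' Reported spot positions are the true positions plus independent
#' Gaussian jitter of SD `noise_sd_um` per axis. Each sperm consumes its
#' own random sub-stream derived from the global seed by counter, so the
#' trajectory of sperm `i` does not change when `n_sperm` changes.
#'
#' @param config A [sim_config()].
#' @return An object of class `sperm_sim` with elements:
#'   \describe{
#'     \item{spots}{data frame of observed spots: `track_id`, `frame`,
#'       `t_s`, `x_um`, `y_um`, `intensity`.}
#'     \item{truth}{data frame of generative frame records: true position,
#'       the frame speed (um/s) and the wall distance (um) and angle (rad)
#'       it was drawn from.}
#'     \item{turn_events}{data frame `track_id`, `frame`,
#'       `label` (`"pro"`/`"anti"`).}
#'     \item{hook_side}{per-track hook side (`"left"`/`"right"`).}
#'     \item{wall}{the true [wall_model()].}
#'     \item{config}{the configuration used.}
#'   }
#' @seealso [render_image_stack()], [make_wall_mask()]
#' @export
#' @examples
#' sim <- simulate_trajectories(sim_config(n_sperm = 3, n_frames = 20))
#' head(sim$spots)
simulate_trajectories <- function(config) {
  validate_sim_config(config)
  ps <- config$pixel_size_um
  wall <- wall_model(config$wall[1, ] * ps,
                     (config$wall[2, ] - config$wall[1, ]) * ps)
  w <- wall$direction
  field_um <- c(config$field_width_px, config$field_height_px) * ps
  thr <- config$contact_threshold_um
  dt <- 1 / config$fps

  spawn <- config$spawn_box
  if (is.null(spawn)) spawn <- c(0, field_um[1], 0, field_um[2])

  spots <- vector("list", config$n_sperm)
  truth <- vector("list", config$n_sperm)
  events <- vector("list", config$n_sperm)
  hook <- character(config$n_sperm)
  amp <- numeric(config$n_sperm)

  # one sub-stream per sperm, derived from the global seed by counter:
  # the prefix is stable, so sperm i is reproducible when n_sperm changes
  set.seed(config$seed)
  sub_seeds <- floor(stats::runif(config$n_sperm + 1L) * 2147483646) + 1

  for (i in seq_len(config$n_sperm)) {
    set.seed(sub_seeds[i])
    hook_sign <- if (stats::runif(1) < 0.5) 1 else -1
    hook[i] <- if (hook_sign > 0) "left" else "right"
    amp[i] <- stats::runif(1, 0.7, 1)

    # spawn on the lumen side, outside the contact band
    if (!is.null(config$spawn_positions)) {
      pos <- as.numeric(config$spawn_positions[i, ])
    } else {
      pos <- NULL
      for (try in 1:200) {
        cand <- c(stats::runif(1, spawn[1], spawn[2]),
                  stats::runif(1, spawn[3], spawn[4]))
        sd0 <- wall_signed_distance(cand[1], cand[2], wall)
        if (sign(sd0) != config$wall_side && abs(sd0) > thr) {
          pos <- cand
          break
        }
      }
      if (is.null(pos)) {
        stop("could not place sperm outside the wall region; ",
             "check spawn_box and wall geometry", call. = FALSE)
      }
    }
    phi <- if (!is.null(config$init_heading)) {
      as.numeric(rep_len(config$init_heading, config$n_sperm))[i]
    } else {
      stats::runif(1, 0, 2 * pi)
    }

    nf <- config$n_frames
    eps_s <- stats::rnorm(nf - 1, 0, config$speed_log_sd)
    eps_h <- stats::rnorm(nf - 1, 0, config$heading_sd)
    u_turn <- stats::runif(nf - 1)
    jit <- matrix(stats::rnorm(2 * nf, 0, config$noise_sd_um), ncol = 2)

    xs <- ys <- sp <- dd <- th <- numeric(nf)
    xs[1] <- pos[1]; ys[1] <- pos[2]
    sp[1] <- dd[1] <- th[1] <- NA_real_
    ev_frame <- integer(0); ev_label <- character(0)
    d_prev <- abs(wall_signed_distance(pos[1], pos[2], wall))

    for (f in 2:nf) {
      h <- c(cos(phi), sin(phi))
      d <- abs(wall_signed_distance(xs[f - 1], ys[f - 1], wall))
      theta <- acos(min(1, abs(sum(h * w))))
      s <- exp(config$base_log_vcl + config$beta_distance * d +
                 config$beta_angle * theta + eps_s[f - 1])
      phi <- phi + eps_h[f - 1]
      h <- c(cos(phi), sin(phi))
      nx <- xs[f - 1] + s * dt * h[1]
      ny <- ys[f - 1] + s * dt * h[2]

      # do not penetrate the wall tissue: mirror across the line
      sd_new <- wall_signed_distance(nx, ny, wall)
      if (sign(sd_new) == config$wall_side && sd_new != 0) {
        nx <- nx - 2 * sd_new * (-w[2])
        ny <- ny - 2 * sd_new * w[1]
        hw <- sum(h * w)
        h <- 2 * hw * w - h
        phi <- atan2(h[2], h[1])
      }

      d_new <- abs(wall_signed_distance(nx, ny, wall))
      if (d_new < thr && d_prev >= thr) {
        # along-wall direction on the hook side of the current heading
        cr <- cross2(h, w)
        a_pro <- hook_sign * (if (cr != 0) sign(cr) else 1) * w
        if (u_turn[f - 1] < config$pro_hook_prob) {
          dir <- a_pro  # pro: migrate along the wall, hook toward the wall
          ev_label <- c(ev_label, "pro")
        } else {
          # anti: leave the wall, tangential drift on the non-hook side
          n_away <- -config$wall_side * c(-w[2], w[1])
          dir <- (-a_pro + n_away) / sqrt(2)
          ev_label <- c(ev_label, "anti")
        }
        phi <- atan2(dir[2], dir[1])
        ev_frame <- c(ev_frame, f - 1L)  # 0-based frame index
      }
      d_prev <- d_new

      # stay in the field of view (reflecting boundaries)
      if (nx < 0) nx <- -nx
      if (nx > field_um[1]) nx <- 2 * field_um[1] - nx
      if (ny < 0) ny <- -ny
      if (ny > field_um[2]) ny <- 2 * field_um[2] - ny

      xs[f] <- nx; ys[f] <- ny; sp[f] <- s; dd[f] <- d; th[f] <- theta
    }

    frames0 <- seq_len(nf) - 1L
    truth[[i]] <- data.frame(
      track_id = i, frame = frames0, x_um = xs, y_um = ys,
      speed_um_s = sp, wall_distance_um = dd, wall_angle_rad = th
    )
    spots[[i]] <- data.frame(
      track_id = i, frame = frames0, t_s = frames0 / config$fps,
      x_um = xs + jit[, 1], y_um = ys + jit[, 2], intensity = amp[i]
    )
    events[[i]] <- if (length(ev_frame)) {
      data.frame(track_id = i, frame = ev_frame, label = ev_label)
    } else NULL
  }

  ev <- do.call(rbind, events)
  if (is.null(ev)) {
    ev <- data.frame(track_id = integer(0), frame = integer(0),
                     label = character(0))
  }
  structure(
    list(
      spots = if (config$n_sperm) do.call(rbind, spots) else
        data.frame(track_id = integer(0), frame = integer(0),
                   t_s = numeric(0), x_um = numeric(0), y_um = numeric(0),
                   intensity = numeric(0)),
      truth = if (config$n_sperm) do.call(rbind, truth) else
        data.frame(track_id = integer(0), frame = integer(0),
                   x_um = numeric(0), y_um = numeric(0),
                   speed_um_s = numeric(0), wall_distance_um = numeric(0),
                   wall_angle_rad = numeric(0)),
      turn_events = ev,
      hook_side = hook,
      amplitude = amp,
      wall = wall,
      config = config
    ),
    class = "sperm_sim"
  )
}

#' @export
print.sperm_sim <- function(x, ...) {
  cat(sprintf(
    "sperm_sim: %d tracks, %d frames, %d turn events (%d pro / %d anti)\n",
    x$config$n_sperm, x$config$n_frames, nrow(x$turn_events),
    sum(x$turn_events$label == "pro"), sum(x$turn_events$label == "anti")
  ))
  invisible(x)
}

#' Sample wall-contact turn labels from the simulator
#'
#' Convenience wrapper for replicate-based studies of the directional
#' test: runs the trajectory simulator with a near-wall spawn band (so
#' that wall contacts are frequent) until at least `n_turns` turn events
#' have fired, and returns the first `n_turns` labels in deterministic
#' (seed batch, track, frame) order.
#'
#' @param n_turns Number of turn labels required.
#' @param pro_hook_prob Probability that a turn is pro-wall-hook.
#' @param seed Integer seed.
#' @return Character vector of length `n_turns` with values `"pro"` /
#'   `"anti"`.
#' @export
sample_turn_labels <- function(n_turns, pro_hook_prob, seed = 1L) {
  stopifnot(n_turns >= 1)
  labels <- character(0)
  batch <- 0L
  while (length(labels) < n_turns && batch < 50L) {
    cfg <- sim_config(
      n_sperm = 120L, n_frames = 25L,
      spawn_box = c(20, 360, 330, 342),
      pro_hook_prob = pro_hook_prob,
      seed = (seed %% 20000000L) * 100L + batch
    )
    sim <- simulate_trajectories(cfg)
    labels <- c(labels, sim$turn_events$label)
    batch <- batch + 1L
  }
  if (length(labels) < n_turns) {
    stop("simulator produced too few turn events", call. = FALSE)
  }
  labels[seq_len(n_turns)]
}

#' Binary wall mask for a simulation configuration
#'
#' Produces a single-frame binary image in which the wall-tissue half-plane
#' of the configured wall line is set to 1. Pixel centres use 0-based
#' coordinates (x = column, y = row).
#'
#' @param config A [sim_config()].
#' @return Integer matrix (`field_height_px` x `field_width_px`) of 0/1.
#' @export
#' @examples
#' m <- make_wall_mask(sim_config(field_width_px = 64, field_height_px = 64,
#'                                wall = rbind(c(0, 32), c(63, 32))))
#' table(m)
make_wall_mask <- function(config) {
  validate_sim_config(config)
  wall_px <- wall_model(config$wall[1, ], config$wall[2, ] - config$wall[1, ])
  xs <- seq_len(config$field_width_px) - 1
  ys <- seq_len(config$field_height_px) - 1
  sd <- outer(ys, xs, function(y, x) wall_signed_distance(x, y, wall_px))
  mask <- matrix(0L, config$field_height_px, config$field_width_px)
  mask[sd * config$wall_side >= 0] <- 1L
  mask
}

#' Render a simulation into a fluorescence image stack
#'
#' Each sperm head is drawn as an isotropic Gaussian blob in the green
#' (head) channel; an optional red (midpiece) channel carries a trailing
#' blob offset behind the direction of motion. The wall-tissue side of the
#' field is darkened, read noise is added, and pixel values are quantized
#' to 16-bit levels.
#'
#' @param sim A `sperm_sim` from [simulate_trajectories()].
#' @param channels 1 (head only) or 2 (head + midpiece).
#' @param bg Background level on the lumen side (fraction of full scale).
#' @param wall_dim Multiplier applied to the background inside the wall
#'   region (darkening).
#' @param noise `"gaussian"`, `"poisson"` or `"none"`.
#' @param read_noise_sd Gaussian read-noise SD (fraction of full scale).
#' @param photons Photon scale for Poisson noise.
#' @param amp Peak blob amplitude multiplier.
#' @return An object of class `image_stack`: a list with `frames` (list of
#'   `height x width` matrices, or `height x width x 2` arrays when
#'   `channels = 2`, values in `[0, 1]` on a 16-bit grid), plus
#'   `pixel_size_um`, `fps` and `channels`.
#' @export
render_image_stack <- function(sim, channels = 1L, bg = 0.02,
                               wall_dim = 0.25, noise = "gaussian",
                               read_noise_sd = 0.003, photons = 2000,
                               amp = 0.6) {
  stopifnot(inherits(sim, "sperm_sim"), channels %in% c(1L, 2L))
  cfg <- sim$config
  if (cfg$blob_sigma_um <= 0 || cfg$pixel_size_um <= 0) {
    stop("blob sigma and pixel size must be positive", call. = FALSE)
  }
  noise <- match.arg(noise, c("gaussian", "poisson", "none"))
  h <- cfg$field_height_px; wdt <- cfg$field_width_px
  ps <- cfg$pixel_size_um
  sigma_px <- cfg$blob_sigma_um / ps
  base <- matrix(bg, h, wdt)
  base[make_wall_mask(cfg) == 1L] <- bg * wall_dim

  # the rendering stream is the (n_sperm + 1)-th sub-stream of the seed
  set.seed(cfg$seed)
  set.seed(floor(stats::runif(cfg$n_sperm + 1L) *
                   2147483646)[cfg$n_sperm + 1L] + 1)
  frames <- vector("list", cfg$n_frames)
  tr <- sim$truth
  for (f in seq_len(cfg$n_frames) - 1L) {
    rows <- tr[tr$frame == f, , drop = FALSE]
    img <- base
    red <- if (channels == 2L) base else NULL
    for (k in seq_len(nrow(rows))) {
      a <- amp * sim$amplitude[rows$track_id[k]]
      img <- add_blob(img, rows$x_um[k] / ps, rows$y_um[k] / ps, sigma_px, a)
      if (channels == 2L) {
        # midpiece trails the head opposite to the motion direction
        prev <- tr[tr$track_id == rows$track_id[k] & tr$frame == f - 1L, ]
        dir <- if (nrow(prev)) c(rows$x_um[k] - prev$x_um,
                                 rows$y_um[k] - prev$y_um) else c(1, 0)
        nd <- sqrt(sum(dir^2)); if (nd == 0) dir <- c(1, 0) else dir <- dir / nd
        red <- add_blob(red, (rows$x_um[k] - 3 * dir[1]) / ps,
                        (rows$y_um[k] - 3 * dir[2]) / ps,
                        sigma_px * 1.3, a * 0.8)
      }
    }
    stack1 <- function(m) {
      m <- switch(noise,
        gaussian = m + matrix(stats::rnorm(length(m), 0, read_noise_sd),
                              nrow(m)),
        poisson = matrix(stats::rpois(length(m), pmax(m, 0) * photons),
                         nrow(m)) / photons,
        none = m
      )
      round(pmin(pmax(m, 0), 1) * 65535) / 65535
    }
    img <- stack1(img)
    frames[[f + 1L]] <- if (channels == 2L) {
      arr <- array(0, c(h, wdt, 2))
      arr[, , 1] <- img; arr[, , 2] <- stack1(red)
      arr
    } else img
  }
  structure(list(frames = frames, pixel_size_um = ps, fps = cfg$fps,
                 channels = channels),
            class = "image_stack")
}

# add an isotropic Gaussian blob at pixel coords (x, y), clipped to the frame
add_blob <- function(img, x, y, sigma_px, amp) {
  r <- ceiling(4 * sigma_px)
  c0 <- max(0, floor(x) - r); c1 <- min(ncol(img) - 1, ceiling(x) + r)
  r0 <- max(0, floor(y) - r); r1 <- min(nrow(img) - 1, ceiling(y) + r)
  if (c0 > c1 || r0 > r1) return(img)
  cc <- c0:c1; rr <- r0:r1
  patch <- amp * outer(exp(-(rr - y)^2 / (2 * sigma_px^2)),
                       exp(-(cc - x)^2 / (2 * sigma_px^2)))
  img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + patch
  img
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(as.matrix(if (x$channels == 2L) x$frames[[1]][, , 1] else
    x$frames[[1]]))
  cat(sprintf("image_stack: %d frames, %dx%d px, %d channel(s), %.3g um/px @ %g fps\n",
              length(x$frames), d[2], d[1], x$channels, x$pixel_size_um,
              x$fps))
  invisible(x)
}
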