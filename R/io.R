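#' Trajectory CSV input and output
#'
#' The pipeline's standard trajectory table is a plain CSV with columns
#' `track_id`, `frame`, `t_s`, `x_um`, `y_um` and optionally `radius_um`,
#' `intensity`. Coordinates are micrometres in the image frame (0-based
#' pixel centres, x = column, y = row); `frame` is authoritative and `t_s`
#' = frame / fps is stored redundantly for human inspection.
#'
#' @param spots Spot data frame.
#' @param path File path.
#' @return `read_trajectories()` returns the validated data frame;
#'   `write_trajectories()` returns `path` invisibly.
#' @name trajectory_io
NULL

#' @rdname trajectory_io
#' @export
write_trajectories <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trajectory CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("frame", "x_um", "y_um", "t_s"), names(df))) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("trajectory CSV ", path, ": non-finite ", col, " at data row ",
           bad[1], call. = FALSE)
    }
  }
  df
}

#' Image-stack TIFF input and output
#'
#' Stacks are written as multi-frame grayscale 16-bit TIFFs (two-channel
#' stacks interleave channels per frame) with a JSON sidecar
#' (`<path>.json`) recording pixel size, frame rate, channel count, seed
#' and the configuration hash.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param sidecar Extra fields to record in the sidecar.
#' @return `read_stack_tiff()` returns an `image_stack`;
#'   `write_stack_tiff()` returns `path` invisibly.
#' @name stack_io
NULL

#' @rdname stack_io
#' @export
write_stack_tiff <- function(stack, path, sidecar = list()) {
  stopifnot(inherits(stack, "image_stack"))
  planes <- list()
  for (fr in stack$frames) {
    if (length(dim(fr)) == 3) {
      for (ch in seq_len(dim(fr)[3])) planes[[length(planes) + 1]] <- fr[, , ch]
    } else planes[[length(planes) + 1]] <- fr
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  meta <- c(list(pixel_size_um = stack$pixel_size_um, fps = stack$fps,
                 channels = stack$channels, n_frames = length(stack$frames),
                 package_version = as.character(utils::packageVersion("spermwall"))),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname stack_io
#' @param pixel_size_um,fps,channels Calibration overrides; normally read
#'   from the sidecar. An error names the missing value when neither is
#'   available.
#' @export
read_stack_tiff <- function(path, pixel_size_um = NULL, fps = NULL,
                            channels = NULL) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  pick <- function(arg, name) {
    if (!is.null(arg)) return(arg)
    if (!is.null(meta[[name]])) return(as.numeric(meta[[name]]))
    stop("no ", name, " in sidecar ", side,
         "; supply the ", name, " argument", call. = FALSE)
  }
  ps <- pick(pixel_size_um, "pixel_size_um")
  fr <- pick(fps, "fps")
  ch <- as.integer(pick(channels, "channels"))
  planes <- tiff::readTIFF(path, all = TRUE)
  frames <- if (ch == 2L) {
    lapply(seq_len(length(planes) / 2), function(i) {
      arr <- array(0, c(dim(planes[[1]]), 2))
      arr[, , 1] <- planes[[2 * i - 1]]
      arr[, , 2] <- planes[[2 * i]]
      arr
    })
  } else planes
  structure(list(frames = frames, pixel_size_um = ps, fps = fr,
                 channels = ch), class = "image_stack")
}

# small polynomial rolling hash of a config, for sidecar provenance
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 4294967291
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Run the simulation stage to files
#'
#' Simulates trajectories, renders the image stack and wall mask, and
#' writes: `trajectories.csv` (observed spots), `ground_truth.json`
#' (frame records, turn events, hook sides, wall line), `stack.tif` (+
#' sidecar), `wall_mask.csv` (0/1 matrix) and `config.json`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param channels Channels to render (1 or 2).
#' @return Invisibly, the `sperm_sim` object.
#' @export
run_simulate <- function(config, out_dir, channels = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_trajectories(config)
  stack <- render_image_stack(sim, channels = channels)
  write_trajectories(sim$spots, file.path(out_dir, "trajectories.csv"))
  write_stack_tiff(stack, file.path(out_dir, "stack.tif"),
                   sidecar = list(seed = config$seed,
                                  config_hash = config_hash(unclass(config))))
  mask <- make_wall_mask(config)
  utils::write.table(mask, file.path(out_dir, "wall_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  gt <- list(
    wall = list(point = sim$wall$point, direction = sim$wall$direction),
    hook_side = sim$hook_side,
    turn_events = sim$turn_events,
    truth = sim$truth,
    seed = config$seed,
    config_hash = config_hash(unclass(config))
  )
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = I(17), dataframe = "columns")
  cfg_out <- unclass(config)
  cfg_out$wall <- as.data.frame(cfg_out$wall)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(sim)
}

#' Run the tracking stage to files
#'
#' Reads a calibrated stack, tracks it and writes `tracked.csv` plus
#' `rejected.csv` (track id and rejection reason).
#'
#' @param stack_path Path to a TIFF written by [write_stack_tiff()] (or
#'   any TIFF, with calibration supplied).
#' @param out_dir Output directory.
#' @param config A [tracking_config()].
#' @inheritParams read_stack_tiff
#' @return Invisibly, the tracking result list.
#' @export
run_track <- function(stack_path, out_dir, config = tracking_config(),
                      pixel_size_um = NULL, fps = NULL, channels = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- read_stack_tiff(stack_path, pixel_size_um, fps, channels)
  res <- track_stack(stack, config)
  write_trajectories(res$spots, file.path(out_dir, "tracked.csv"))
  utils::write.csv(res$rejected, file.path(out_dir, "rejected.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Run the analysis stage to files
#'
#' Computes the per-track kinematics table, fits the wall from a mask or
#' point list, joins the wall covariates, fits the four log-linear models
#' (VCL, VSL, LIN, SWR on distance + angle) and, when turn counts are
#' supplied, the directional binomial test. Writes `kinematics.csv` and
#' `report.json`.
#'
#' @param trajectories Path to a trajectory CSV or a spot data frame.
#' @param wall A [wall_model()], a binary mask matrix, or a data frame of
#'   boundary points (`x_um`, `y_um`).
#' @param fps Frame rate (frames/s).
#' @param out_dir Output directory.
#' @param pixel_size_um Needed when `wall` is a pixel mask.
#' @param counts Optional `c(n_pro, n_total)` for the directional test.
#' @param transform Response transform for the model fits.
#' @return Invisibly, a list with `params` (joined table), `fits`,
#'   `direction` and `dropped` counts.
#' @export
run_analyze <- function(trajectories, wall, fps, out_dir,
                        pixel_size_um = NULL, counts = NULL,
                        transform = "log") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spots <- if (is.character(trajectories)) read_trajectories(trajectories)
           else trajectories
  wm <- if (inherits(wall, "wall_model")) {
    wall
  } else if (is.matrix(wall)) {
    if (is.null(pixel_size_um)) {
      stop("pixel_size_um is required to fit a wall from a pixel mask",
           call. = FALSE)
    }
    fit_wall(extract_boundary(wall, pixel_size_um))
  } else {
    fit_wall(wall)
  }
  params <- compute_kinematics(spots, fps)
  rel <- wall_relation(spots, wm)
  tab <- merge(params, rel, by = "track_id")
  fits <- lapply(c("vcl", "vsl", "lin", "swr"), function(r) {
    tryCatch(
      fit_kinetics_model(tab, r, c("distance_um", "angle_rad"),
                         transform = transform),
      error = function(e) NULL
    )
  })
  names(fits) <- c("vcl", "vsl", "lin", "swr")
  direction <- if (!is.null(counts)) {
    binomial_direction_test(counts[1], counts[2])
  }
  utils::write.csv(tab, file.path(out_dir, "kinematics.csv"),
                   row.names = FALSE)
  report <- list(
    n_tracks = nrow(tab),
    n_undefined_swr = sum(is.na(tab$swr)),
    n_undefined_lin = sum(is.na(tab$lin)),
    wall = list(point = wm$point, direction = wm$direction,
                fit_rmse_um = wm$fit_rmse_um, n_points = wm$n_points),
    models = lapply(fits, function(f) {
      if (is.null(f)) return(NULL)
      list(response = f$response, transform = f$transform,
           n_obs = f$n_obs, n_dropped = f$n_dropped,
           coefficients = as.data.frame(f$coefficients))
    }),
    direction_test = if (!is.null(direction)) unclass(direction)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(params = tab, fits = fits, direction = direction,
                 wall = wm))
}

#' End-to-end demonstration run
#'
#' Simulates a small stack, tracks it, and analyses the tracked
#' trajectories against the wall mask, writing all artifacts under
#' `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return Invisibly, the analysis result list.
#' @export
run_demo <- function(out_dir, seed = 1L) {
  cfg <- sim_config(field_width_px = 256L, field_height_px = 256L,
                    n_sperm = 15L, n_frames = 30L,
                    wall = rbind(c(0, 220), c(255, 220)), seed = seed)
  run_simulate(cfg, out_dir)
  run_track(file.path(out_dir, "stack.tif"), out_dir)
  mask <- as.matrix(utils::read.table(file.path(out_dir, "wall_mask.csv"),
                                      sep = ","))
  res <- run_analyze(file.path(out_dir, "tracked.csv"), mask,
                     fps = cfg$fps, out_dir = out_dir,
                     pixel_size_um = cfg$pixel_size_um,
                     counts = c(52, 63))
  invisible(res)
}
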