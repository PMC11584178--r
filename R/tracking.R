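#' Tracking configuration
#'
#' Detection and linking parameters mirroring the customary
#' thresholding-detector + LAP-tracker setup for sperm-head tracking:
#' minimum head radius 0.75 um, frame-to-frame linking gate 11 um, gap
#' closing up to 2 missing frames within 11 um, at least 7 spots per kept
#' track and a minimum track displacement of 2.5 um (an immotile-debris
#' filter; see Details).
#'
#' @details The displacement gate is applied as a minimum: tracks whose
#' first-to-last displacement does not exceed `min_displacement_um` are
#' rejected. Applied as a maximum it would discard nearly every motile
#' sperm, so the minimum reading is used; the gate is configurable.
#'
#' @param detect_sigma_um Gaussian smoothing SD before thresholding (um).
#' @param detect_threshold `"otsu"` or an absolute numeric threshold on
#'   the smoothed image.
#' @param min_radius_um Discard components with equivalent radius at or
#'   below this (um).
#' @param max_link_um Frame-to-frame linking distance gate (um).
#' @param max_gap_frames Maximum frame gap bridged by gap closing.
#' @param max_gap_um Maximum end-to-start distance for gap closing (um).
#' @param min_spots Minimum number of spots in a kept track.
#' @param min_displacement_um Minimum track displacement for a kept track.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(detect_sigma_um = 1.0,
                            detect_threshold = "otsu",
                            min_radius_um = 0.75,
                            max_link_um = 11,
                            max_gap_frames = 2L,
                            max_gap_um = 11,
                            min_spots = 7L,
                            min_displacement_um = 2.5) {
  stopifnot(
    detect_sigma_um > 0, min_radius_um > 0, max_link_um > 0,
    max_gap_frames >= 0, max_gap_um > 0, min_spots >= 1,
    min_displacement_um >= 0,
    identical(detect_threshold, "otsu") ||
      (is.numeric(detect_threshold) && length(detect_threshold) == 1)
  )
  structure(list(
    detect_sigma_um = detect_sigma_um,
    detect_threshold = detect_threshold,
    min_radius_um = min_radius_um,
    max_link_um = max_link_um,
    max_gap_frames = as.integer(max_gap_frames),
    max_gap_um = max_gap_um,
    min_spots = as.integer(min_spots),
    min_displacement_um = min_displacement_um
  ), class = "tracking_config")
}

#' Detect sperm-head spots in one frame
#'
#' Gaussian-smooths the frame, thresholds it (Otsu by default), labels
#' 8-connected components and reports each component's intensity-weighted
#' centroid as a spot. The equivalent radius is `sqrt(area / pi)` scaled
#' to micrometres; components at or below `min_radius_um` are discarded.
#'
#' @param img Numeric matrix (rows = y, columns = x), values in `[0, 1]`.
#' @param pixel_size_um Pixel size (um).
#' @param config A [tracking_config()].
#' @return Data frame with columns `x_um`, `y_um`, `radius_um`,
#'   `intensity` (possibly zero rows).
#' @export
detect_spots <- function(img, pixel_size_um, config = tracking_config()) {
  stopifnot(is.matrix(img), pixel_size_um > 0)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), intensity = numeric(0))
  if (length(img) == 0) stop("empty image", call. = FALSE)
  sm <- EBImage::gblur(img, sigma = config$detect_sigma_um / pixel_size_um)
  thr <- if (identical(config$detect_threshold, "otsu")) {
    if (diff(range(sm)) == 0) return(empty)  # constant image: nothing to find
    otsu_refined(pmin(pmax(sm, 0), 1))
  } else config$detect_threshold
  mask <- sm > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.integer(lab)
  keep <- lab > 0
  w <- as.numeric(img)[keep]
  l <- lab[keep]
  idx <- which(matrix(keep, nrow(img)), arr.ind = TRUE)
  xs <- idx[, "col"] - 1  # 0-based pixel-centre coordinates
  ys <- idx[, "row"] - 1
  area <- tabulate(l)
  wsum <- tapply(w, l, sum)
  cx <- tapply(w * xs, l, sum) / wsum
  cy <- tapply(w * ys, l, sum) / wsum
  radius <- sqrt(area / pi) * pixel_size_um
  out <- data.frame(
    x_um = as.numeric(cx) * pixel_size_um,
    y_um = as.numeric(cy) * pixel_size_um,
    radius_um = radius,
    intensity = as.numeric(wsum) / area
  )
  out <- out[out$radius_um > config$min_radius_um, , drop = FALSE]
  out <- out[order(out$x_um, out$y_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Otsu threshold with iterative refinement: a multimodal background (dark
# wall region vs lumen) can capture the first Otsu split, so while the
# foreground still covers more than `max_fg` of the pixels the threshold
# is recomputed on the foreground alone.
otsu_refined <- function(v, max_fg = 0.05, max_iter = 5L) {
  v <- as.numeric(v)
  thr <- EBImage::otsu(EBImage::Image(matrix(v, 1)), range = c(0, 1))
  for (i in seq_len(max_iter)) {
    fg <- v[v > thr]
    if (length(fg) <= 2 || length(fg) / length(v) <= max_fg) break
    if (diff(range(fg)) == 0) break
    thr <- EBImage::otsu(EBImage::Image(matrix(fg, 1)), range = c(0, 1))
  }
  thr
}

#' Link spots across frames into track segments
#'
#' For each consecutive frame pair, solves the gated rectangular
#' assignment problem with squared-distance costs; links beyond
#' `max_link_um` are forbidden (each spot may take a non-link
#' alternative). Unlinked spots start new segments. Output identities are
#' deterministic: spots are processed in (frame, x, y) order.
#'
#' @param spots Data frame with columns `frame`, `x_um`, `y_um` (plus any
#'   extras, carried through).
#' @param config A [tracking_config()].
#' @return The spot data frame with an added `track_id` column.
#' @export
link_spots <- function(spots, config = tracking_config()) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(spots)))
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um), , drop = FALSE]
  rownames(spots) <- NULL
  n <- nrow(spots)
  spots$track_id <- NA_integer_
  if (n == 0) return(spots)
  dup <- duplicated(spots[, c("frame", "x_um", "y_um")])
  if (any(dup)) {
    message(sum(dup), " duplicate spot coordinate(s) within a frame")
  }
  next_id <- 1L
  frames <- sort(unique(spots$frame))
  rows_f <- split(seq_len(n), factor(spots$frame, levels = frames))
  # first frame: all spots start segments
  first <- rows_f[[1]]
  spots$track_id[first] <- seq_along(first)
  next_id <- length(first) + 1L
  for (k in seq_along(frames)[-1]) {
    ra <- rows_f[[k - 1]]; rb <- rows_f[[k]]
    m <- if (frames[k] - frames[k - 1] == 1) {
      gated_match(cbind(spots$x_um[ra], spots$y_um[ra]),
                  cbind(spots$x_um[rb], spots$y_um[rb]),
                  config$max_link_um)
    } else rep(NA_integer_, length(ra))
    linked_b <- rep(FALSE, length(rb))
    for (i in seq_along(ra)) {
      if (!is.na(m[i])) {
        spots$track_id[rb[m[i]]] <- spots$track_id[ra[i]]
        linked_b[m[i]] <- TRUE
      }
    }
    newb <- rb[!linked_b]
    if (length(newb)) {
      spots$track_id[newb] <- seq(next_id, length.out = length(newb))
      next_id <- next_id + length(newb)
    }
  }
  spots
}

#' Close gaps between track segments
#'
#' A second assignment over (segment end, segment start) pairs whose frame
#' gap is in `[1, max_gap_frames]` and whose end-to-start distance is at
#' most `max_gap_um`, with squared-distance costs. Accepted pairs are
#' concatenated under the earlier segment's identity; missing frames stay
#' absent (no interpolation).
#'
#' @param spots Linked spot data frame (with `track_id`), as returned by
#'   [link_spots()].
#' @param config A [tracking_config()].
#' @return The spot data frame with merged `track_id`s, renumbered
#'   consecutively in (first frame, x, y) order.
#' @export
close_gaps <- function(spots, config = tracking_config()) {
  stopifnot("track_id" %in% names(spots))
  if (nrow(spots) == 0 || config$max_gap_frames < 1) {
    return(renumber_tracks(spots))
  }
  ids <- unique(spots$track_id)
  segs <- lapply(ids, function(id) {
    s <- spots[spots$track_id == id, , drop = FALSE]
    s <- s[order(s$frame), , drop = FALSE]
    list(id = id,
         start = c(s$frame[1], s$x_um[1], s$y_um[1]),
         end = c(s$frame[nrow(s)], s$x_um[nrow(s)], s$y_um[nrow(s)]))
  })
  ends <- t(vapply(segs, `[[`, numeric(3), "end"))
  starts <- t(vapply(segs, `[[`, numeric(3), "start"))
  gap <- outer(starts[, 1], ends[, 1], "-")            # start - end
  d2 <- outer(starts[, 2], ends[, 2], "-")^2 +
        outer(starts[, 3], ends[, 3], "-")^2           # [start seg, end seg]
  ok <- gap >= 1 & gap <= config$max_gap_frames &
        sqrt(d2) <= config$max_gap_um
  if (!any(ok)) return(renumber_tracks(spots))
  ns <- length(segs)
  alt <- 1.05 * config$max_gap_um^2
  cost <- matrix(LAP_BIG, 2 * ns, 2 * ns)
  cost[seq_len(ns), seq_len(ns)] <- t(ifelse(ok, d2, LAP_BIG))  # [end, start]
  cost[cbind(seq_len(ns), ns + seq_len(ns))] <- alt
  cost[cbind(ns + seq_len(ns), seq_len(ns))] <- alt
  cost[ns + seq_len(ns), ns + seq_len(ns)] <- 0
  a <- lap_solve(cost)
  succ <- rep(NA_integer_, ns)
  for (e in seq_len(ns)) {
    s <- a[e]
    if (s <= ns && ok[s, e]) succ[e] <- s
  }
  # concatenate chains end -> start under the chain head's identity
  has_pred <- rep(FALSE, ns)
  has_pred[succ[!is.na(succ)]] <- TRUE
  newid <- ids
  for (h in which(!has_pred)) {
    cur <- h
    while (!is.na(succ[cur])) {
      cur <- succ[cur]
      newid[cur] <- ids[h]
    }
  }
  spots$track_id <- newid[match(spots$track_id, ids)]
  renumber_tracks(spots)
}

renumber_tracks <- function(spots) {
  if (nrow(spots) == 0) return(spots)
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um), , drop = FALSE]
  firsts <- spots[!duplicated(spots$track_id), , drop = FALSE]
  o <- order(firsts$frame, firsts$x_um, firsts$y_um)
  map <- stats::setNames(seq_along(o), firsts$track_id[o])
  spots$track_id <- as.integer(map[as.character(spots$track_id)])
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Filter tracks by spot count and displacement
#'
#' Keeps tracks with at least `min_spots` spots and first-to-last
#' displacement greater than `min_displacement_um`.
#'
#' @param spots Spot data frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param config A [tracking_config()].
#' @return List with `spots` (kept tracks) and `rejected` (data frame
#'   `track_id`, `reason`).
#' @export
filter_tracks <- function(spots, config = tracking_config()) {
  ids <- unique(spots$track_id)
  reasons <- character(0); rid <- integer(0)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    tr <- spots[spots$track_id == ids[i], , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    disp <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                 (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    if (nrow(tr) < config$min_spots) {
      rid <- c(rid, ids[i]); reasons <- c(reasons, "min_spots")
    } else if (disp <= config$min_displacement_um) {
      rid <- c(rid, ids[i]); reasons <- c(reasons, "min_displacement")
    } else {
      keep[i] <- TRUE
    }
  }
  list(
    spots = renumber_tracks(spots[spots$track_id %in% ids[keep], ,
                                  drop = FALSE]),
    rejected = data.frame(track_id = rid, reason = reasons)
  )
}

#' Compare tracked output against ground truth
#'
#' For every ground-truth track, finds the tracked track with the highest
#' Jaccard index over matched spots (same frame, within `match_dist_um`).
#'
#' @param truth_spots Ground-truth spot table (`track_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param tracked_spots Tracked spot table with the same columns.
#' @param match_dist_um Maximum distance for a spot match (um).
#' @return Data frame with one row per true track: `track_id`, `jaccard`,
#'   `rmse_um` (position RMS error over matched spots of the best track).
#' @export
track_recovery <- function(truth_spots, tracked_spots, match_dist_um = 2) {
  ids <- unique(truth_spots$track_id)
  out <- lapply(ids, function(id) {
    tt <- truth_spots[truth_spots$track_id == id, , drop = FALSE]
    best <- 0; best_rmse <- NA_real_
    for (tid in unique(tracked_spots$track_id)) {
      dd <- tracked_spots[tracked_spots$track_id == tid, , drop = FALSE]
      m <- merge(tt, dd, by = "frame")
      if (!nrow(m)) next
      d <- sqrt((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2)
      hit <- sum(d < match_dist_um)
      j <- hit / (nrow(tt) + nrow(dd) - hit)
      if (j > best) { best <- j; best_rmse <- sqrt(mean(d[d < match_dist_um]^2)) }
    }
    data.frame(track_id = id, jaccard = best, rmse_um = best_rmse)
  })
  do.call(rbind, out)
}

#' Track an image stack end to end
#'
#' Runs [detect_spots()] on every frame (channel 1 of two-channel data),
#' then [link_spots()], [close_gaps()] and [filter_tracks()].
#'
#' @param stack An `image_stack` (see [render_image_stack()]) or a list of
#'   frame matrices.
#' @param config A [tracking_config()].
#' @param pixel_size_um,fps Calibration; taken from the stack when it is
#'   an `image_stack`.
#' @return List with `spots` (tracked spot table with `track_id`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `radius_um`, `intensity`) and `rejected`.
#' @export
track_stack <- function(stack, config = tracking_config(),
                        pixel_size_um = NULL, fps = NULL) {
  if (inherits(stack, "image_stack")) {
    if (is.null(pixel_size_um)) pixel_size_um <- stack$pixel_size_um
    if (is.null(fps)) fps <- stack$fps
    frames <- stack$frames
  } else {
    frames <- stack
  }
  if (is.null(pixel_size_um) || is.null(fps)) {
    stop("pixel_size_um and fps are required (supply them or use an ",
         "image_stack with calibration)", call. = FALSE)
  }
  det <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    if (length(dim(fr)) == 3) fr <- fr[, , 1]
    s <- detect_spots(fr, pixel_size_um, config)
    if (nrow(s)) s$frame <- i - 1L
    s
  })
  det <- det[vapply(det, nrow, 1L) > 0]
  if (!length(det)) {
    empty <- data.frame(track_id = integer(0), frame = integer(0),
                        t_s = numeric(0), x_um = numeric(0),
                        y_um = numeric(0), radius_um = numeric(0),
                        intensity = numeric(0))
    return(list(spots = empty,
                rejected = data.frame(track_id = integer(0),
                                      reason = character(0))))
  }
  spots <- do.call(rbind, det)
  spots$t_s <- spots$frame / fps
  linked <- link_spots(spots, config)
  closed <- close_gaps(linked, config)
  out <- filter_tracks(closed, config)
  cols <- c("track_id", "frame", "t_s", "x_um", "y_um", "radius_um",
            "intensity")
  out$spots <- out$spots[, cols]
  out
}
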