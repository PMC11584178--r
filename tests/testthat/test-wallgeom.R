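test_that("boundary extraction finds the mask edge in um coordinates", {
  m <- matrix(0L, 50, 40)
  m[30:50, ] <- 1L  # rows 30..50 foreground; boundary = row 30 (0-based 29)
  b <- extract_boundary(m, 2)
  expect_equal(sort(unique(b$y_um)), 29 * 2)
  expect_equal(nrow(b), 40)

  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  b1 <- extract_boundary(one, 1)
  expect_equal(b1, data.frame(x_um = 4, y_um = 4))

  expect_error(extract_boundary(matrix(1L, 4, 4), 1), "foreground")
  expect_error(extract_boundary(matrix(0L, 4, 4), 1), "foreground")
})

test_that("a tilted mask boundary stays within one pixel of the true line", {
  cfg <- sim_config(field_width_px = 128, field_height_px = 128,
                    wall = rbind(c(0, 90), c(127, 110)))
  b <- extract_boundary(make_wall_mask(cfg), cfg$pixel_size_um)
  true_wall <- wall_model(cfg$wall[1, ] * cfg$pixel_size_um,
                          (cfg$wall[2, ] - cfg$wall[1, ]) * cfg$pixel_size_um)
  d <- abs(spermwall:::wall_signed_distance(b$x_um, b$y_um, true_wall))
  expect_true(all(d <= cfg$pixel_size_um))
  # and the fitted line recovers the true angle
  w <- fit_wall(b)
  ang <- function(v) atan2(v[2], v[1])
  expect_lt(abs(ang(w$direction) - ang(true_wall$direction)), 0.01)
})

test_that("wall fitting is exact on lines, handles vertical walls and noise", {
  pts <- data.frame(x_um = 0:20, y_um = 0)
  w <- fit_wall(pts)
  expect_equal(abs(w$direction), c(1, 0))
  expect_equal(w$fit_rmse_um, 0)

  vert <- data.frame(x_um = 5, y_um = 0:20)
  wv <- fit_wall(vert)
  expect_equal(abs(wv$direction), c(0, 1))
  expect_equal(wv$fit_rmse_um, 0)

  set.seed(3)
  slope <- 0.35
  x <- stats::runif(500, 0, 200)
  noisy <- data.frame(x_um = x, y_um = 10 + slope * x +
                        stats::rnorm(500, 0, 0.5))
  wn <- fit_wall(noisy)
  expect_lt(abs(atan2(wn$direction[2], wn$direction[1]) - atan(slope)), 0.01)

  expect_error(fit_wall(data.frame(x_um = 1, y_um = 1)), "two distinct")
  expect_error(fit_wall(data.frame(x_um = c(1, 1), y_um = c(2, 2))),
               "two distinct")
})

test_that("refitting points sampled from a fitted line returns that line", {
  set.seed(5)
  pts <- data.frame(x_um = stats::runif(100, 0, 50),
                    y_um = stats::rnorm(100, 20, 3))
  w1 <- fit_wall(pts)
  t <- seq(-30, 30, length.out = 50)
  online <- data.frame(x_um = w1$point[1] + t * w1$direction[1],
                       y_um = w1$point[2] + t * w1$direction[2])
  w2 <- fit_wall(online)
  expect_equal(w2$fit_rmse_um, 0, tolerance = 1e-8)
  expect_equal(abs(sum(w1$direction * w2$direction)), 1, tolerance = 1e-9)
})

test_that("wall distance uses the temporal midpoint spot", {
  w <- wall_model(c(0, 0), c(1, 0))
  tr <- data.frame(track_id = 1, frame = 0:4, x_um = 1:5,
                   y_um = c(9, 9, 3, 9, 9))
  expect_equal(wall_distance(tr, w), 3)  # midpoint index floor((5-1)/2) = 2
  on_line <- data.frame(track_id = 1, frame = 0:2, x_um = 0:2, y_um = 0)
  expect_equal(wall_distance(on_line, w), 0)
  # even-length track: index floor((4-1)/2) = 1 (0-based)
  tr4 <- data.frame(track_id = 1, frame = 0:3, x_um = 1:4,
                    y_um = c(9, 5, 7, 9))
  expect_equal(wall_distance(tr4, w), 5)
  # centroid alternative
  expect_equal(wall_distance(tr4, w, ref = "centroid"), mean(c(9, 5, 7, 9)))
})

test_that("point-to-line distance matches dense minimisation", {
  set.seed(8)
  for (i in 1:20) {
    w <- wall_model(stats::rnorm(2, 0, 10), stats::rnorm(2))
    tr <- random_traj(7)
    mid <- as.numeric(tr[floor((7 - 1) / 2) + 1, c("x_um", "y_um")])
    t <- seq(-1000, 1000, length.out = 2000001)
    px <- w$point[1] + t * w$direction[1]
    py <- w$point[2] + t * w$direction[2]
    dmin <- sqrt(min((px - mid[1])^2 + (py - mid[2])^2))
    expect_equal(wall_distance(tr, w), dmin, tolerance = 1e-6)
  }
})

test_that("wall angles fold into [0, pi/2] and respect parallels", {
  w <- wall_model(c(0, 0), c(1, 0))
  mk <- function(dx, dy) data.frame(track_id = 1, frame = 0:1,
                                    x_um = c(0, dx), y_um = c(0, dy))
  expect_equal(wall_angle(mk(1, 1), w), pi / 4)
  expect_equal(wall_angle(mk(1, -1), w), pi / 4)  # folded to acute
  expect_equal(wall_angle(mk(5, 0), w), 0)
  expect_equal(wall_angle(mk(0, 2), w), pi / 2)
  expect_true(is.na(wall_angle(data.frame(track_id = 1, frame = 0:1,
                                          x_um = c(1, 1), y_um = c(2, 2)),
                               w)))
})

test_that("wall relations are invariant under joint rigid motions", {
  set.seed(14)
  for (i in 1:30) {
    tr <- random_traj(9)
    w <- wall_model(stats::rnorm(2, 0, 5), stats::rnorm(2))
    ang <- stats::runif(1, 0, 2 * pi); sh <- stats::rnorm(2, 0, 50)
    tr2 <- rigid_transform(tr, ang, sh)
    rot <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    w2 <- wall_model(as.numeric(rot %*% w$point) + sh,
                     as.numeric(rot %*% w$direction))
    expect_equal(wall_distance(tr2, w2), wall_distance(tr, w))
    expect_equal(wall_angle(tr2, w2), wall_angle(tr, w))
  }
})

test_that("turn classification agrees with ground-truth labels", {
  cfg <- sim_config(n_sperm = 150, n_frames = 60, noise_sd_um = 0,
                    speed_log_sd = 0, heading_sd = 0,
                    spawn_box = c(30, 350, 250, 330), seed = 11)
  sim <- simulate_trajectories(cfg)
  first_ev <- sim$turn_events[!duplicated(sim$turn_events$track_id), ]
  agree <- 0; total <- 0
  for (r in seq_len(nrow(first_ev))) {
    tr <- sim$spots[sim$spots$track_id == first_ev$track_id[r], ]
    lab <- tryCatch(
      classify_turn(tr, sim$wall, sim$hook_side[first_ev$track_id[r]]),
      error = function(e) NA_character_
    )
    if (is.na(lab)) next  # contact too close to a track end to average
    total <- total + 1
    agree <- agree + (lab == first_ev$label[r])
  }
  expect_gt(total, 15)
  expect_gte(agree / total, 0.95)
})

test_that("turn labels are chirality-consistent and 'none' without contact", {
  w <- wall_model(c(0, 0), c(1, 0))
  # approach the wall from above (y decreasing), then run along +x
  tr <- data.frame(track_id = 1, frame = 0:9,
                   x_um = c(0, 1, 2, 3, 4, 6, 8, 10, 12, 14),
                   y_um = c(10, 8, 6, 4, 1.5, 1, 1, 1, 1, 1))
  lab <- classify_turn(tr, w, "left")
  mirror <- tr; mirror$y_um <- -mirror$y_um
  expect_equal(classify_turn(mirror, w, "right"), lab)
  expect_true(lab %in% c("pro", "anti"))

  far <- data.frame(track_id = 1, frame = 0:9, x_um = 0:9, y_um = 50)
  expect_equal(classify_turn(far, w, "left"), "none")
  short <- data.frame(track_id = 1, frame = 0:3, x_um = 0:3,
                      y_um = c(3, 1, 1, 1))
  expect_error(classify_turn(short, w, "left"), "too short")
})
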