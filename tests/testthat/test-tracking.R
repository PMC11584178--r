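test_that("detect_spots handles blank, single-blob and tiny components", {
  cfgT <- tracking_config()
  expect_equal(nrow(detect_spots(matrix(0, 32, 32), 1, cfgT)), 0)
  expect_equal(nrow(detect_spots(matrix(0.5, 32, 32), 1, cfgT)), 0)
  expect_error(detect_spots(matrix(numeric(0), 0, 0), 1, cfgT), "empty")

  # one clean Gaussian blob: exactly one spot, centroid within 0.5 px
  img <- matrix(0, 64, 64)
  x0 <- 20.3; y0 <- 41.7; sigma <- 2
  for (r in 1:64) for (c in 1:64) {
    img[r, c] <- 0.8 * exp(-(((c - 1) - x0)^2 + ((r - 1) - y0)^2) /
                             (2 * sigma^2))
  }
  s <- detect_spots(img, 1, cfgT)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$x_um - x0), 0.5)
  expect_lt(abs(s$y_um - y0), 0.5)

  # 1-pixel component at 1 um/px: radius sqrt(1/pi) = 0.564 <= 0.75 -> dropped
  img1 <- matrix(0, 16, 16); img1[8, 8] <- 1
  s1 <- detect_spots(img1, 1, tracking_config(detect_sigma_um = 1e-6,
                                              detect_threshold = 0.5))
  expect_equal(nrow(s1), 0)
  # but kept when the minimum radius allows it
  s2 <- detect_spots(img1, 1, tracking_config(detect_sigma_um = 1e-6,
                                              detect_threshold = 0.5,
                                              min_radius_um = 0.5))
  expect_equal(nrow(s2), 1)
  expect_equal(s2$radius_um, sqrt(1 / pi), tolerance = 1e-6)
})

test_that("frame-to-frame links respect the distance gate", {
  cfgT <- tracking_config()
  move5 <- data.frame(frame = c(0, 1), x_um = c(0, 5), y_um = 0)
  linked <- link_spots(move5, cfgT)
  expect_equal(length(unique(linked$track_id)), 1)

  jump15 <- data.frame(frame = c(0, 1), x_um = c(0, 15), y_um = 0)
  linked <- link_spots(jump15, cfgT)
  expect_equal(length(unique(linked$track_id)), 2)
})

test_that("assignment linking equals brute-force minimal-cost matching", {
  set.seed(88)
  for (rep in 1:150) {
    n <- sample(0:5, 1); m <- sample(0:5, 1)
    A <- matrix(stats::runif(2 * n, 0, 25), ncol = 2)
    B <- matrix(stats::runif(2 * m, 0, 25), ncol = 2)
    gate <- stats::runif(1, 3, 12)
    got <- spermwall:::gated_match(A, B, gate)
    if (n == 0) { expect_length(got, 0); next }
    oracle <- brute_gated_match(A, B, gate)
    expect_equal(gated_cost(got, A, B, gate), oracle$cost,
                 tolerance = 1e-9)
  }
})

test_that("multi-frame linking recovers separated tracks exactly", {
  # 3 spots per frame over 20 frames, spacing >> max step
  set.seed(1)
  rows <- list()
  for (f in 0:19) {
    for (k in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, x_um = f * 2 + stats::rnorm(1, 0, 0.1),
        y_um = k * 100 + stats::rnorm(1, 0, 0.1), true = k)
    }
  }
  spots <- do.call(rbind, rows)
  linked <- link_spots(spots, tracking_config())
  expect_equal(length(unique(linked$track_id)), 3)
  # each output track contains exactly one true identity
  for (id in unique(linked$track_id)) {
    expect_equal(length(unique(linked$true[linked$track_id == id])), 1)
  }
})

test_that("every detected spot lands in exactly one segment; gates hold", {
  set.seed(23)
  spots <- data.frame(frame = sample(0:9, 60, replace = TRUE),
                      x_um = stats::runif(60, 0, 60),
                      y_um = stats::runif(60, 0, 60))
  spots <- spots[!duplicated(spots[, c("frame", "x_um", "y_um")]), ]
  cfgT <- tracking_config()
  linked <- link_spots(spots, cfgT)
  expect_equal(nrow(linked), nrow(spots))           # conservation
  expect_true(all(!is.na(linked$track_id)))
  closed <- close_gaps(linked, cfgT)
  expect_equal(nrow(closed), nrow(spots))
  for (id in unique(closed$track_id)) {
    tr <- closed[closed$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) next
    df <- diff(tr$frame)
    dd <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    expect_true(all(df >= 1 & df <= cfgT$max_gap_frames + 1))
    expect_true(all(dd[df == 1] <= cfgT$max_link_um |
                      dd[df == 1] <= cfgT$max_gap_um))
    expect_true(all(dd[df > 1] <= cfgT$max_gap_um))
  }
})

test_that("gap closing merges within its gates and not beyond", {
  cfgT <- tracking_config()
  seg <- function(id, frames, x) {
    data.frame(frame = frames, x_um = x, y_um = 0, track_id = id)
  }
  # end at frame 10, start at frame 12, 4 um apart: merged (gap 2 <= 2)
  s <- rbind(seg(1, 8:10, c(0, 1, 2)), seg(2, 12:14, c(6, 7, 8)))
  merged <- close_gaps(s, cfgT)
  expect_equal(length(unique(merged$track_id)), 1)
  # start at frame 14: gap 4 > 2, not merged
  s2 <- rbind(seg(1, 8:10, c(0, 1, 2)), seg(2, 14:16, c(6, 7, 8)))
  expect_equal(length(unique(close_gaps(s2, cfgT)$track_id)), 2)
  # distance beyond max_gap_um: not merged
  s3 <- rbind(seg(1, 8:10, c(0, 1, 2)), seg(2, 12:14, c(20, 21, 22)))
  expect_equal(length(unique(close_gaps(s3, cfgT)$track_id)), 2)
  # chain of three compatible segments collapses to one track
  s4 <- rbind(seg(1, 0:2, c(0, 1, 2)), seg(2, 4:6, c(5, 6, 7)),
              seg(3, 8:10, c(10, 11, 12)))
  expect_equal(length(unique(close_gaps(s4, cfgT)$track_id)), 1)
})

test_that("track filters enforce spot count and displacement gates", {
  cfgT <- tracking_config()
  mk <- function(id, n, step) {
    data.frame(track_id = id, frame = 0:(n - 1),
               x_um = step * (0:(n - 1)), y_um = 0)
  }
  spots <- rbind(mk(1, 6, 5),      # 6 spots: too few
                 mk(2, 10, 0.1),   # displacement 0.9 um: too small
                 mk(3, 10, 2))     # 10 spots, 18 um: kept
  out <- filter_tracks(spots, cfgT)
  expect_equal(length(unique(out$spots$track_id)), 1)
  kept <- out$spots
  expect_equal(max(kept$x_um) - min(kept$x_um), 18)
  expect_setequal(out$rejected$reason, c("min_spots", "min_displacement"))
  # 7 spots passes the count gate
  out7 <- filter_tracks(mk(4, 7, 2), cfgT)
  expect_equal(nrow(out7$rejected), 0)
})

test_that("tracking a rendered stack recovers ground truth", {
  cfg <- separated_sim_config(seed = 21, n_frames = 30L)
  sim <- simulate_trajectories(cfg)
  st <- render_image_stack(sim)
  res <- track_stack(st)
  rec <- track_recovery(sim$spots, res$spots)
  expect_equal(nrow(rec), cfg$n_sperm)
  expect_true(all(rec$jaccard >= 0.9))
  expect_true(all(rec$rmse_um < cfg$pixel_size_um))  # within 1 px RMS
})

test_that("an empty stack tracks to an empty table without error", {
  frames <- replicate(10, matrix(0, 32, 32), simplify = FALSE)
  res <- track_stack(frames, pixel_size_um = 1, fps = 30)
  expect_equal(nrow(res$spots), 0)
})
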