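# Independent oracles used across tests. These deliberately take different
# computational routes than the package internals.

# band width oracle: rotate the trajectory so the displacement lies along
# the x-axis, then take the y-extent
band_width_oracle <- function(xy) {
  disp <- xy[nrow(xy), ] - xy[1, ]
  ang <- atan2(disp[2], disp[1])
  rot <- rbind(c(cos(-ang), -sin(-ang)), c(sin(-ang), cos(-ang)))
  ry <- (xy %*% t(rot))[, 2]
  max(ry) - min(ry)
}

# exhaustive minimal-total-cost gated matching (same cost structure as the
# LAP formulation: squared distances, non-link alternative 1.05 * gate^2)
brute_gated_match <- function(A, B, gate) {
  n <- nrow(A); m <- nrow(B); alt <- 1.05 * gate^2
  if (n == 0) return(integer(0))
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  feas <- sqrt(d2) <= gate
  best <- rep(NA_integer_, n); bestc <- Inf
  rec <- function(i, used, links, cost) {
    if (cost >= bestc) return()
    if (i > n) {
      total <- cost + alt * sum(!used)
      if (total < bestc) { bestc <<- total; best <<- links }
      return()
    }
    rec(i + 1, used, c(links, NA_integer_), cost + alt)
    if (m > 0) for (j in seq_len(m)) {
      if (!used[j] && feas[i, j]) {
        u <- used; u[j] <- TRUE
        rec(i + 1, u, c(links, j), cost + d2[i, j])
      }
    }
  }
  rec(1L, rep(FALSE, m), integer(0), 0)
  list(links = best, cost = bestc)
}

gated_cost <- function(links, A, B, gate) {
  alt <- 1.05 * gate^2
  tot <- 0
  for (i in seq_along(links)) {
    tot <- tot + if (is.na(links[i])) alt else sum((A[i, ] - B[links[i], ])^2)
  }
  tot + alt * (nrow(B) - sum(!is.na(links)))
}

# random jagged trajectory in um
random_traj <- function(n, scale = 10) {
  data.frame(track_id = 1L, frame = 0:(n - 1),
             x_um = cumsum(stats::rnorm(n, 0.5, scale / 10)),
             y_um = cumsum(stats::rnorm(n, 0, scale / 10)))
}

rigid_transform <- function(traj, angle, shift) {
  rot <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  xy <- as.matrix(traj[, c("x_um", "y_um")]) %*% t(rot)
  traj$x_um <- xy[, 1] + shift[1]
  traj$y_um <- xy[, 2] + shift[2]
  traj
}

zigzag_traj <- function() {
  data.frame(track_id = 1L, frame = 0:4, x_um = 0:4,
             y_um = c(0, 1, 0, 1, 0))
}

# well-separated parallel swimmers: the reference end-to-end fixture
separated_sim_config <- function(seed, n_frames = 60L) {
  ys <- seq(40, 320, by = 35)
  sim_config(n_sperm = length(ys), n_frames = n_frames,
             base_log_vcl = log(50), beta_distance = 0, beta_angle = 0,
             heading_sd = 0.02, noise_sd_um = 0.05,
             spawn_positions = cbind(60, ys), init_heading = 0,
             seed = seed)
}
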