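# Linear assignment via the Jonker-Volgenant shortest-augmenting-path
# algorithm (O(n^2 m)); used for gated frame-to-frame linking and gap
# closing. Costs must be finite; "forbidden" entries use LAP_BIG.

LAP_BIG <- 1e12

# cost: n x m matrix, n <= m; returns integer vector a with a[i] = column
# assigned to row i (every row is assigned)
lap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j]: row assigned to column j (0 = none)
  way <- integer(m)
  J0 <- m + 1L           # virtual start column
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(INF, m)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF; j1 <- 0L
      red <- cost[i0, ] - u[i0] - v[seq_len(m)]
      for (j in seq_len(m)) {
        if (!used[j]) {
          if (red[j] < minv[j]) { minv[j] <- red[j]; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      if (used[J0]) {
        u[p[J0]] <- u[p[J0]] + delta
        v[J0] <- v[J0] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) ans[p[j]] <- j
  ans
}

# Gated bipartite matching between point sets A (n x 2) and B (m x 2):
# cost of a link is squared distance, links beyond `gate` are forbidden,
# and every point may instead take the non-link alternative of cost
# 1.05 * gate^2 (the standard LAP-tracker augmentation). Returns an
# integer vector over rows of A: the matched row of B, or NA.
gated_match <- function(A, B, gate) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  alt <- 1.05 * gate^2
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  d2[sqrt(d2) > gate] <- LAP_BIG
  cost <- matrix(LAP_BIG, n + m, n + m)
  cost[seq_len(n), seq_len(m)] <- d2
  cost[cbind(seq_len(n), m + seq_len(n))] <- alt      # A unlinked
  cost[cbind(n + seq_len(m), seq_len(m))] <- alt      # B unlinked
  cost[n + seq_len(m), m + seq_len(n)] <- 0           # slack block
  a <- lap_solve(cost)
  out <- a[seq_len(n)]
  out[out > m | d2[cbind(seq_len(n), pmin(out, m))] >= LAP_BIG] <- NA_integer_
  out
}
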