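# Linear assignment problem, shortest augmenting path (Jonker-Volgenant
# style), O(n^3). Returns for each row the assigned column of the square
# cost matrix, minimising total cost. Used for frame-to-frame linking and
# gap closing; small instances are cross-checked against exhaustive
# enumeration in the test suite.
solve_lap <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("cost must be a square matrix")
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

# Match two point sets under a distance cap. Cost: squared distance for a
# link, cap^2 for an unmatched point on either side (the standard LAP
# tracking augmentation: an n1+n2 square matrix with birth/death
# alternatives on the diagonal blocks). Returns integer vector of length
# n1: matched index in set 2 or NA.
match_points <- function(x1, y1, x2, y2, max_dist) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  big <- 4 * max_dist^2 * (n1 + n2) + 1
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  link <- d2
  link[d2 > max_dist^2] <- big
  n <- n1 + n2
  cost <- matrix(big, n, n)
  cost[seq_len(n1), seq_len(n2)] <- link
  for (i in seq_len(n1)) cost[i, n2 + i] <- max_dist^2       # death
  for (j in seq_len(n2)) cost[n1 + j, j] <- max_dist^2       # birth
  cost[(n1 + 1):n, (n2 + 1):n] <- 0                          # fill block
  a <- solve_lap(cost)
  out <- a[seq_len(n1)]
  out[out > n2] <- NA_integer_
  # links that only exist through the `big` cost are not real
  real <- !is.na(out)
  if (any(real))
    out[real][d2[cbind(which(real), out[real])] > max_dist^2] <- NA_integer_
  out
}
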