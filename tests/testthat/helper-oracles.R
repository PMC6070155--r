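# Independent oracles, implemented without reference to the package's
# FFT/assignment code paths.

# Direct-sum evaluation of the documented space-time correlation:
# fluctuations about the per-pixel temporal mean within the voxel,
# normalised per lag by overlap counts, frame-pair counts and the
# channel-mean product (SD product when a channel mean is negligible).
direct_sum_corr <- function(a, b, tau_max) {
  R <- dim(a)[1]; T <- dim(a)[3]
  ma <- apply(a, c(1, 2), mean); mb <- apply(b, c(1, 2), mean)
  da <- a - array(ma, dim(a)); db <- b - array(mb, dim(b))
  sa <- sd(a); sb <- sd(b)
  Ia <- mean(a); Ib <- mean(b)
  dn <- if (abs(Ia) > 0.1 * sa && abs(Ib) > 0.1 * sb) Ia * Ib else sa * sb
  L <- R %/% 2
  lags <- (-L):L
  taus <- (-tau_max):tau_max
  r <- array(0, c(2 * L + 1, 2 * L + 1, 2 * tau_max + 1))
  for (ei in seq_along(lags)) for (xi in seq_along(lags)) {
    e <- lags[ei]; x <- lags[xi]
    # overlapping index ranges for the spatial shift (eta = rows, xi = cols)
    i1 <- max(1, 1 - e); i2 <- min(R, R - e)
    j1 <- max(1, 1 - x); j2 <- min(R, R - x)
    for (ti in seq_along(taus)) {
      tau <- taus[ti]
      t1 <- max(1, 1 - tau); t2 <- min(T, T - tau)
      s <- sum(da[i1:i2, j1:j2, t1:t2, drop = FALSE] *
                 db[(i1 + e):(i2 + e), (j1 + x):(j2 + x),
                    (t1 + tau):(t2 + tau), drop = FALSE])
      r[ei, xi, ti] <- s / ((T - abs(tau)) * (R - abs(e)) * (R - abs(x)) * dn)
    }
  }
  r
}

# Exhaustive capped-matching oracle: minimises sum of squared link
# distances plus cap^2 per unmatched point (both sides), enumerating all
# injective partial matchings.
brute_force_match_cost <- function(x1, y1, x2, y2, max_dist) {
  n1 <- length(x1); n2 <- length(x2)
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  best <- Inf
  recurse <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n1) {
      total <- cost + (n2 - sum(used)) * max_dist^2
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1, used, cost + max_dist^2)   # point i unmatched
    for (j in seq_len(n2)) {
      if (used[j] || d2[i, j] > max_dist^2) next
      u <- used; u[j] <- TRUE
      recurse(i + 1, u, cost + d2[i, j])
    }
  }
  recurse(1, rep(FALSE, max(n2, 1)), 0)
  best
}

# cost of a match_points() assignment under the same objective
assignment_cost <- function(x1, y1, x2, y2, m, max_dist) {
  cost <- 0
  used <- rep(FALSE, length(x2))
  for (i in seq_along(m)) {
    if (is.na(m[i])) {
      cost <- cost + max_dist^2
    } else {
      cost <- cost + (x1[i] - x2[m[i]])^2 + (y1[i] - y2[m[i]])^2
      used[m[i]] <- TRUE
    }
  }
  cost + sum(!used) * max_dist^2
}
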