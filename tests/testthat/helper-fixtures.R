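# Small in-code fixtures shared across tests.

tiny_series <- function(data, px = 0.1, dt = 0.2, lab = "test") {
  image_series(data, px, dt, lab)
}

random_series <- function(h = 16, w = 16, nt = 30, seed = 1) {
  set.seed(seed)
  tiny_series(array(runif(h * w * nt), c(h, w, nt)))
}

# noiseless movie of one Gaussian spot translating at v px/frame on a
# periodic domain
translating_spot <- function(h = 32, w = 32, nt = 30, v = c(0.5, 0),
                             sigma = 1.5, x0 = 8, y0 = 16) {
  dat <- array(0, c(h, w, nt))
  for (t in seq_len(nt)) {
    x <- (x0 + v[1] * (t - 1) - 1) %% w + 1
    y <- (y0 + v[2] * (t - 1) - 1) %% h + 1
    img <- matrix(0, h, w)
    for (dxp in -1:1) for (dyp in -1:1)   # periodic images for wrap
      img <- img + outer(exp(-((1:h) - (y + dyp * h))^2 / (2 * sigma^2)),
                         exp(-((1:w) - (x + dxp * w))^2 / (2 * sigma^2)))
    dat[, , t] <- img
  }
  tiny_series(dat)
}

# hand-built correlation_function with Gaussian peaks at prescribed
# positions per temporal lag (for exact velocity-fit checks)
synthetic_corr <- function(peaks, L = 8, tau_max = 10, sigma = 1.5,
                           px = 0.1, dt = 0.2) {
  lags <- (-L):L
  taus <- (-tau_max):tau_max
  r <- array(0, c(length(lags), length(lags), length(taus)))
  for (k in seq_along(taus)) {
    tau <- taus[k]
    key <- as.character(tau)
    if (!key %in% names(peaks)) next
    p <- peaks[[key]]   # c(xi, eta, amplitude)
    r[, , k] <- p[3] * outer(exp(-(lags - p[2])^2 / (2 * sigma^2)),
                             exp(-(lags - p[1])^2 / (2 * sigma^2)))
  }
  dimnames(r) <- list(eta = lags, xi = lags, tau = taus)
  structure(list(r = r, xi = lags, eta = lags, tau = taus,
                 channel_pair = c("synthetic", "synthetic"),
                 normalization = "mean", denom = 1,
                 roi_size_px = 2 * L, toi_len_frames = max(taus) + 2,
                 pixel_size_um = px, frame_interval_s = dt, valid = TRUE),
            class = "correlation_function")
}
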