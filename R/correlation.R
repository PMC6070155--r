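#' Spatiotemporal correlation function of one voxel
#'
#' Computes the normalised space-time correlation
#' \deqn{r_{ab}(\xi,\eta,\tau) = \frac{1}{n_t(\tau)\, N(\xi,\eta)\, D}
#'   \sum_t \sum_{x,y} \delta I_a(x,y,t)\, \delta I_b(x+\xi, y+\eta, t+\tau)}
#' where \eqn{\delta I} are fluctuations about the per-pixel temporal mean
#' within the voxel (so structure that is immobile during the TOI does not
#' correlate), \eqn{N(\xi,\eta) = (R-|\xi|)(R-|\eta|)} counts the
#' overlapping pixels of the linear (zero-padded) spatial correlation,
#' \eqn{n_t(\tau)} counts frame pairs, and the normalisation
#' \eqn{D = \langle I_a\rangle \langle I_b\rangle} is the product of the
#' voxel mean intensities. When a channel mean is negligible against its
#' fluctuation amplitude (as after the immobile filter, which zeroes
#' per-pixel temporal means), \eqn{D} falls back to the product of the
#' channel standard deviations; the mode used is recorded. A constant
#' voxel has no fluctuations and is flagged invalid (`r` all zero).
#'
#' Evaluation is by zero-padded FFT and is exactly equal (to ~1e-15) to
#' the direct sum above. Spatial lags run over
#' \eqn{|\xi|,|\eta| \le R/2} and temporal lags two-sided over
#' `-tau_max:tau_max` (negative lags correlate the first channel with the
#' second channel's past; for an autocorrelation they mirror the positive
#' lags, for a cross-correlation they extend the measurable range of an
#' offset peak).
#'
#' @param series_a,series_b [image_series()] of identical geometry
#'   (`series_b = series_a` for autocorrelation).
#' @param voxel numeric `c(x0, y0, t0)` anchor (1-based) of the voxel.
#' @param roi_size_px,toi_len_frames voxel extent (defaults 16 px, 30 frames).
#' @param tau_max largest temporal lag (default 10; must be `< toi_len_frames`).
#' @return A `correlation_function`: array `r[eta, xi, tau]` with lag
#'   dimnames, lag vectors `xi`, `eta`, `tau`, the `channel_pair`,
#'   normalisation info, calibration, and `valid` flag.
#' @export
correlation_function <- function(series_a, series_b, voxel,
                                 roi_size_px = 16, toi_len_frames = 30,
                                 tau_max = 10) {
  stopifnot(inherits(series_a, "image_series"),
            inherits(series_b, "image_series"))
  assert_same_geometry(series_a, series_b)
  if (tau_max >= toi_len_frames) stop("tau_max must be < toi_len_frames")
  x0 <- voxel[1]; y0 <- voxel[2]; t0 <- voxel[3]
  d <- dim(series_a$data)
  if (x0 < 1 || y0 < 1 || t0 < 1 ||
      x0 + roi_size_px - 1 > d[2] || y0 + roi_size_px - 1 > d[1] ||
      t0 + toi_len_frames - 1 > d[3])
    stop("voxel extends outside the image series")

  a <- series_a$data[y0:(y0 + roi_size_px - 1), x0:(x0 + roi_size_px - 1),
                     t0:(t0 + toi_len_frames - 1), drop = FALSE]
  b <- series_b$data[y0:(y0 + roi_size_px - 1), x0:(x0 + roi_size_px - 1),
                     t0:(t0 + toi_len_frames - 1), drop = FALSE]
  corr_from_blocks(a, b, tau_max,
                   channel_pair = c(series_a$channel_label,
                                    series_b$channel_label),
                   pixel_size_um = series_a$pixel_size_um,
                   frame_interval_s = series_a$frame_interval_s)
}

# smallest 2,3,5-smooth integer >= n (efficient mixed-radix FFT sizes)
next_fft_size <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# fluctuations about the per-pixel temporal mean within the voxel, so
# structure that is immobile during the TOI contributes nothing
voxel_fluctuations <- function(a) {
  m <- apply(a, c(1, 2), mean)
  a - array(m, dim(a))   # recycles the 2-d mean over frames
}

# normalisation constant D and its mode; NULL when the voxel is degenerate
corr_denominator <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(NULL)
  ma <- mean(a); mb <- mean(b)
  if (abs(ma) > 0.1 * sa && abs(mb) > 0.1 * sb)
    list(value = ma * mb, mode = "mean")
  else
    list(value = sa * sb, mode = "sd")
}

pad_fft <- function(da, P, Q) {
  d <- dim(da)
  arr <- array(0, c(P, P, Q))
  arr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- da
  fft(arr)
}

# full correlation machinery given raw voxel blocks
corr_from_blocks <- function(a, b, tau_max, channel_pair,
                             pixel_size_um, frame_interval_s) {
  R <- dim(a)[1]; T <- dim(a)[3]
  dn <- corr_denominator(a, b)
  L <- R %/% 2   # padding below keeps all lags up to +/- L wraparound-free
  lags <- (-L):L
  taus <- (-tau_max):tau_max
  if (is.null(dn)) {
    r <- array(0, c(2 * L + 1, 2 * L + 1, 2 * tau_max + 1))
  } else {
    P <- next_fft_size(R + L)
    Q <- next_fft_size(T + tau_max)
    Fa <- pad_fft(voxel_fluctuations(a), P, Q)
    Fb <- pad_fft(voxel_fluctuations(b), P, Q)
    r <- corr_from_ffts(Fa, Fb, R, T, L, tau_max, dn$value)
  }
  structure(list(r = r, xi = lags, eta = lags, tau = taus,
                 channel_pair = channel_pair,
                 normalization = if (is.null(dn)) "undefined" else dn$mode,
                 denom = if (is.null(dn)) NA_real_ else dn$value,
                 roi_size_px = R, toi_len_frames = T,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 valid = !is.null(dn)),
            class = "correlation_function")
}

# inverse-FFT product, lag extraction and per-lag normalisation; temporal
# lags are extracted two-sided (negative tau reverses the channel order)
corr_from_ffts <- function(Fa, Fb, R, T, L, tau_max, denom) {
  P <- dim(Fa)[1]; Q <- dim(Fa)[3]
  num <- Re(fft(Conj(Fa) * Fb, inverse = TRUE)) / (P * P * Q)
  lags <- (-L):L
  taus <- (-tau_max):tau_max
  idx <- (lags %% P) + 1L
  idt <- (taus %% Q) + 1L
  r <- num[idx, idx, idt, drop = FALSE]
  n_ov <- outer(R - abs(lags), R - abs(lags))  # [eta, xi] overlap counts
  n_t <- T - abs(taus)
  for (k in seq_along(taus))
    r[, , k] <- r[, , k] / (n_ov * n_t[k] * denom)
  dimnames(r) <- list(eta = lags, xi = lags, tau = taus)
  r
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("correlation_function %s x %s: lags |xi|,|eta| <= %d, tau 0..%d (%s)\n",
              x$channel_pair[1], x$channel_pair[2], max(x$xi), max(x$tau),
              if (x$valid) paste0("normalization: ", x$normalization)
              else "invalid (no fluctuations)"))
  invisible(x)
}
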