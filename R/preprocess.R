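#' Correct monoexponential photobleaching
#'
#' Fits a monoexponential decay `a * exp(-b t)` to the per-frame mean
#' intensity (over the mask, if given) and divides each frame by the
#' fitted decay factor `exp(-b t)`, so the corrected per-frame means are
#' constant up to fit residuals. A series whose fitted decay is
#' non-positive (no bleaching) passes through unchanged.
#'
#' @param series an [image_series()] with at least 5 frames.
#' @param mask optional [cell_mask()]; the fit uses masked pixels only.
#' @return The corrected [image_series()]; calibration unchanged.
#' @export
correct_photobleaching <- function(series, mask = NULL) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (nt < 5) stop("photobleaching fit needs at least 5 frames")
  sel <- if (is.null(mask)) NULL else which(mask$mask)
  m <- vapply(seq_len(nt), function(t) {
    fr <- series$data[, , t]
    if (is.null(sel)) mean(fr) else mean(fr[sel])
  }, numeric(1))
  tt <- seq_len(nt) - 1

  b <- 0
  if (all(m > 0)) {
    # log-linear start values, then least squares on the original scale
    lf <- lm(log(m) ~ tt)
    start <- list(a = exp(coef(lf)[1]), b = -coef(lf)[2])
    fit <- tryCatch(
      nls(m ~ a * exp(-b * tt), start = start,
          control = list(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) b <- coef(fit)[["b"]]
    else b <- start$b
  }
  if (!is.finite(b) || b <= 0) return(series)  # non-decaying: gain ~ 1
  gain <- exp(b * tt)
  out <- series$data
  for (t in seq_len(nt)) out[, , t] <- out[, , t] * gain[t]
  series_like(series, out)
}

#' Subtract large-scale background and denoise
#'
#' Removes slowly varying background by grayscale morphological opening
#' (rolling-ball equivalent) with a disc of radius `bg_radius_px`, then
#' applies a Gaussian denoising filter of width `denoise_sigma_px`
#' (`0` skips denoising). Output intensities are clipped at 0.
#'
#' @param series an [image_series()].
#' @param bg_radius_px opening radius in px; must exceed the PSF sigma so
#'   diffraction-limited structures survive. Default 15.
#' @param denoise_sigma_px Gaussian sigma in px (default 0.75).
#' @return The filtered [image_series()].
#' @export
subtract_background_and_denoise <- function(series, bg_radius_px = 15,
                                            denoise_sigma_px = 0.75) {
  stopifnot(inherits(series, "image_series"))
  if (bg_radius_px <= 0) stop("bg_radius_px must be > 0")
  brush <- EBImage::makeBrush(2 * ceiling(bg_radius_px) + 1, shape = "disc")
  out <- series$data
  for (t in seq_len(n_frames(series))) {
    fr <- out[, , t]
    lo <- min(fr)
    bg <- EBImage::opening(fr - lo, brush) + lo
    fr <- fr - bg
    if (denoise_sigma_px > 0) fr <- EBImage::gblur(fr, denoise_sigma_px)
    out[, , t] <- pmax(fr, 0)
  }
  series_like(series, out)
}

#' Temporal Fourier immobile filter
#'
#' Removes immobile structures before correlation analysis: for every
#' pixel, the temporal Fourier transform of its intensity trace is
#' computed, the `n_low_freq` lowest-frequency bins (including DC) are
#' zeroed symmetrically, and the trace is inverse-transformed. With the
#' default `n_low_freq = 1` only the DC component is removed, so every
#' pixel's temporal mean becomes exactly zero while frame-to-frame motion
#' signals are preserved. The filter is linear and idempotent.
#'
#' @param series an [image_series()].
#' @param n_low_freq number of low-frequency components to remove;
#'   must satisfy `1 <= n_low_freq < n_frames / 2`.
#' @return The filtered [image_series()] (values may be negative).
#' @export
immobile_filter <- function(series, n_low_freq = 1) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (n_low_freq < 1 || n_low_freq >= nt / 2)
    stop("n_low_freq must satisfy 1 <= n_low_freq < n_frames/2")
  d <- dim(series$data)
  x <- matrix(aperm(series$data, c(3, 1, 2)), nrow = nt)  # frames x pixels
  f <- mvfft(x)
  kill <- 1L  # DC
  if (n_low_freq > 1) {
    k <- seq_len(n_low_freq - 1)
    kill <- c(1L, 1L + k, nt + 1L - k)  # symmetric low-frequency bins
  }
  f[kill, ] <- 0
  x <- Re(mvfft(f, inverse = TRUE)) / nt
  out <- aperm(array(x, c(nt, d[1], d[2])), c(2, 3, 1))
  series_like(series, out)
}
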