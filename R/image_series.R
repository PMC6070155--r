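#' Calibrated fluorescence time-lapse stack
#'
#' Container for a single-channel time-lapse movie together with its
#' physical calibration. Frames are stored as a numeric array indexed
#' `[row, col, frame]` (y, x, t); intensities are detector counts (or
#' arbitrary units after preprocessing).
#'
#' @param data numeric array `[row, col, frame]` with at least 2 frames.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param channel_label free-text channel name, e.g. `"tubulin-GFP"`.
#'
#' @return An object of class `image_series`.
#' @examples
#' s <- image_series(array(runif(16 * 16 * 4), c(16, 16, 4)), 0.1, 0.2, "demo")
#' dim(s$data)
#' @export
image_series <- function(data, pixel_size_um, frame_interval_s,
                         channel_label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [row, col, frame]")
  if (dim(data)[3] < 2L)
    stop("an image series needs at least 2 frames")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be > 0")
  structure(
    list(data = data,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s),
         channel_label = as.character(channel_label)),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_series '%s': %d x %d px, %d frames, %.4g um/px, %.4g s/frame\n",
              x$channel_label, d[1], d[2], d[3],
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[3]

# replace the data array, keeping calibration
series_like <- function(series, data) {
  image_series(data, series$pixel_size_um, series$frame_interval_s,
               series$channel_label)
}

assert_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("image series have different dimensions")
  if (abs(a$pixel_size_um - b$pixel_size_um) > 1e-12 ||
      abs(a$frame_interval_s - b$frame_interval_s) > 1e-12)
    stop("image series have different calibrations")
  invisible(TRUE)
}

#' Cell region-of-interest mask
#'
#' @param mask logical matrix, same spatial shape as the series it masks;
#'   must contain at least one `TRUE` pixel.
#' @param cell_id identifier for the cell.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(mask, cell_id = "cell") {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  structure(list(mask = mask, cell_id = as.character(cell_id)),
            class = "cell_mask")
}

#' Read a multi-page TIFF movie as an image series
#'
#' Frames are read in page order. Calibration is taken from a JSON sidecar
#' written by [write_movie()] (same path with extension `.json`) unless
#' explicitly overridden; a movie without any calibration source is an error.
#'
#' @param path path to a multi-page TIFF file.
#' @param pixel_size_um,frame_interval_s optional calibration overrides.
#' @param channel_label optional channel label override.
#' @return An [image_series()].
#' @export
read_movie <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       channel_label = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("movie at '", path, "' has fewer than 2 frames")
  data <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]

  sidecar <- paste0(sub("\\.tiff?$", "", path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  px <- pixel_size_um %||% meta$pixel_size_um
  dt <- frame_interval_s %||% meta$frame_interval_s
  lab <- channel_label %||% meta$channel_label %||% basename(path)
  if (is.null(px) || is.null(dt))
    stop("no calibration for '", path,
         "': provide a sidecar JSON or explicit pixel_size_um/frame_interval_s")
  if (!is.null(meta$intensity_scale))
    data <- data * as.numeric(meta$intensity_scale) +
      as.numeric(meta$intensity_offset %||% 0)
  image_series(data, as.numeric(px), as.numeric(dt), lab)
}

#' Write an image series as a multi-page TIFF with JSON sidecar
#'
#' TIFF samples are stored min-max scaled to \[0, 1\] at 32-bit depth;
#' the offset and scale are recorded in the sidecar so [read_movie()]
#' restores the original intensities (to 32-bit float precision).
#'
#' @param series an [image_series()].
#' @param path output TIFF path; a calibration sidecar `<path>.json`
#'   (extension replaced) is written alongside.
#' @return `path`, invisibly.
#' @export
write_movie <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  off <- min(series$data)
  scl <- max(series$data) - off
  if (scl <= 0) scl <- 1
  frames <- lapply(seq_len(n_frames(series)),
                   function(i) (series$data[, , i] - off) / scl)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(sub("\\.tiff?$", "", path), ".json")
  jsonlite::write_json(
    list(pixel_size_um = series$pixel_size_um,
         frame_interval_s = series$frame_interval_s,
         channel_label = series$channel_label,
         intensity_offset = off, intensity_scale = scl),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
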