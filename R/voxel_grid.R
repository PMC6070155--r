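#' Tile a movie into an overlapping ROI/TOI voxel grid
#'
#' Divides the field of view into `roi_size_px` square regions of interest
#' shifted by `roi_shift_px` in x and y (oversampling in space) and the
#' time series into `toi_len_frames`-frame subsets shifted by
#' `toi_shift_frames` (oversampling in time). When the shifts do not tile
#' an axis exactly, an extra end-anchored window is appended so the grid
#' covers the full extent. Voxels whose ROI covers less than
#' `min_mask_frac` of the cell mask are excluded.
#'
#' @param image_shape c(height, width) in px.
#' @param n_frames number of frames.
#' @param mask optional [cell_mask()].
#' @param roi_size_px,roi_shift_px spatial window and shift (defaults 16, 4).
#' @param toi_len_frames,toi_shift_frames temporal window and shift
#'   (defaults 30, 15).
#' @param min_mask_frac minimum in-mask fraction for a voxel (default 0.5).
#' @return A `voxel_grid`: anchors data.frame (`x0`, `y0`, `t0`, 1-based,
#'   plus lattice indices `ix`, `iy`, `it`) and the grid parameters.
#' @examples
#' g <- tile_voxels(c(32, 32), 30)
#' nrow(g$anchors)  # 5 x 5 x 1 = 25
#' @export
tile_voxels <- function(image_shape, n_frames, mask = NULL,
                        roi_size_px = 16, roi_shift_px = 4,
                        toi_len_frames = 30, toi_shift_frames = 15,
                        min_mask_frac = 0.5) {
  h <- image_shape[1]; w <- image_shape[2]
  if (roi_size_px > min(h, w))
    stop("roi_size_px exceeds image dimensions")
  if (toi_len_frames > n_frames)
    stop("toi_len_frames exceeds the number of frames")

  axis_anchors <- function(n, win, shift) {
    a <- seq(1L, n - win + 1L, by = shift)
    if (a[length(a)] != n - win + 1L) a <- c(a, n - win + 1L)
    a
  }
  ys <- axis_anchors(h, roi_size_px, roi_shift_px)
  xs <- axis_anchors(w, roi_size_px, roi_shift_px)
  ts <- axis_anchors(n_frames, toi_len_frames, toi_shift_frames)

  anchors <- expand.grid(iy = seq_along(ys), ix = seq_along(xs),
                         it = seq_along(ts))
  anchors$y0 <- ys[anchors$iy]
  anchors$x0 <- xs[anchors$ix]
  anchors$t0 <- ts[anchors$it]

  if (!is.null(mask)) {
    stopifnot(inherits(mask, "cell_mask"))
    if (!identical(dim(mask$mask), as.integer(c(h, w))))
      stop("mask shape does not match image_shape")
    frac <- vapply(seq_len(nrow(anchors)), function(i) {
      r <- anchors$y0[i]; c0 <- anchors$x0[i]
      mean(mask$mask[r:(r + roi_size_px - 1), c0:(c0 + roi_size_px - 1)])
    }, numeric(1))
    anchors <- anchors[frac >= min_mask_frac, , drop = FALSE]
    rownames(anchors) <- NULL
  }
  if (nrow(anchors) == 0)
    warning("voxel grid is empty (mask coverage below threshold everywhere)")

  structure(list(anchors = anchors[, c("x0", "y0", "t0", "ix", "iy", "it")],
                 roi_size_px = roi_size_px, roi_shift_px = roi_shift_px,
                 toi_len_frames = toi_len_frames,
                 toi_shift_frames = toi_shift_frames,
                 image_shape = c(h, w), n_frames = n_frames),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d voxels (ROI %d/%d px, TOI %d/%d frames) on %dx%dx%d\n",
              nrow(x$anchors), x$roi_size_px, x$roi_shift_px,
              x$toi_len_frames, x$toi_shift_frames,
              x$image_shape[1], x$image_shape[2], x$n_frames))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("roi_size_px", "roi_shift_px", "toi_len_frames",
                       "toi_shift_frames", "image_shape", "n_frames")],
                   b[c("roi_size_px", "roi_shift_px", "toi_len_frames",
                       "toi_shift_frames", "image_shape", "n_frames")]))
}
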