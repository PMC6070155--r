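#' Detect EB3 comets in one frame by Laplacian-of-Gaussian filtering
#'
#' Convolves the frame with a scale-normalised LoG kernel matched to the
#' comet size, takes 8-connected local maxima of the (sign-flipped, so
#' bright blobs are positive) response above `quality_min`, refines each
#' to sub-pixel precision by quadratic interpolation, and merges
#' detections closer than `sigma_px` (keeping the higher quality).
#'
#' @param frame numeric matrix (one movie frame).
#' @param sigma_px LoG scale in px, matched to the comet radius.
#' @param quality_min detection threshold on the LoG response.
#' @return data.frame of detections: `x`, `y` (sub-pixel, 1-based px),
#'   `quality`.
#' @export
detect_comets <- function(frame, sigma_px = 1.5, quality_min = 0.3) {
  stopifnot(is.matrix(frame))
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  resp <- log_response(frame, sigma_px)
  h <- nrow(resp); w <- ncol(resp)
  # 8-connected local maxima (interior pixels only)
  ctr <- resp[2:(h - 1), 2:(w - 1)]
  ismax <- ctr >= quality_min &
    ctr > resp[1:(h - 2), 2:(w - 1)] & ctr > resp[3:h, 2:(w - 1)] &
    ctr > resp[2:(h - 1), 1:(w - 2)] & ctr > resp[2:(h - 1), 3:w] &
    ctr > resp[1:(h - 2), 1:(w - 2)] & ctr > resp[1:(h - 2), 3:w] &
    ctr > resp[3:h, 1:(w - 2)] & ctr > resp[3:h, 3:w]
  pk <- which(ismax, arr.ind = TRUE)
  if (nrow(pk) == 0)
    return(data.frame(x = numeric(), y = numeric(), quality = numeric()))
  ys <- pk[, 1] + 1L; xs <- pk[, 2] + 1L
  # sub-pixel quadratic refinement along each axis
  dy <- dx <- numeric(length(ys))
  for (k in seq_along(ys)) {
    i <- ys[k]; j <- xs[k]
    dy[k] <- quad_offset(resp[i - 1, j], resp[i, j], resp[i + 1, j])
    dx[k] <- quad_offset(resp[i, j - 1], resp[i, j], resp[i, j + 1])
  }
  det <- data.frame(x = xs + dx, y = ys + dy,
                    quality = resp[cbind(ys, xs)])
  det <- det[order(-det$quality), ]
  # merge duplicates closer than sigma (greedy, by quality)
  keep <- rep(TRUE, nrow(det))
  for (k in seq_len(nrow(det))) {
    if (!keep[k]) next
    if (k < nrow(det)) {
      later <- (k + 1):nrow(det)
      d2 <- (det$x[later] - det$x[k])^2 + (det$y[later] - det$y[k])^2
      keep[later][d2 < sigma_px^2] <- FALSE
    }
  }
  det <- det[keep, ]
  rownames(det) <- NULL
  det
}

# parabolic sub-pixel offset from 3 samples; clamped to (-0.5, 0.5)
quad_offset <- function(a, b, c) {
  den <- a - 2 * b + c
  if (den >= 0) return(0)
  max(min(0.5 * (a - c) / den, 0.5), -0.5)
}

# scale-normalised LoG response (positive for bright blobs), FFT convolution
log_response <- function(frame, sigma) {
  r <- ceiling(4 * sigma)
  z <- (-r):r
  g <- exp(-z^2 / (2 * sigma^2))
  # separable construction of sigma^2 * laplacian-of-gaussian
  xx <- matrix(z, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  yy <- t(xx)
  k <- exp(-(xx^2 + yy^2) / (2 * sigma^2)) *
    ((xx^2 + yy^2) / sigma^2 - 2) / (2 * pi * sigma^2)
  k <- k - mean(k)          # zero net response to flat background
  -sigma^2 * EBImage::filter2(frame, k)
}

#' Detect comets in every frame of a movie
#'
#' @param series an [image_series()] (preprocessed EB3 channel).
#' @param sigma_px,quality_min see [detect_comets()].
#' @return data.frame `t`, `x`, `y`, `quality`, sorted by frame.
#' @export
detect_comets_movie <- function(series, sigma_px = 1.5, quality_min = 0.3) {
  stopifnot(inherits(series, "image_series"))
  out <- lapply(seq_len(n_frames(series)), function(t) {
    d <- detect_comets(series$data[, , t], sigma_px, quality_min)
    if (nrow(d)) cbind(t = t, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(t = integer(), x = numeric(), y = numeric(),
                      quality = numeric())
  out
}

#' Link detections into comet tracks (LAP, two passes)
#'
#' First pass: frame-to-frame links by a globally minimal squared-distance
#' assignment (Jonker-Volgenant) under the `max_link_px` cap. Second pass:
#' gap closing joins track ends to later track starts across at most
#' `max_gap_frames` missing frames within `max_gap_px`, again as a minimal
#' assignment. Every detection belongs to at most one track.
#'
#' @param detections data.frame `t`, `x`, `y`, `quality` (sorted or not).
#' @param max_link_px frame-to-frame linking radius in px.
#' @param max_gap_frames largest closable gap in frames (0 disables gap
#'   closing).
#' @param max_gap_px gap-closing radius in px (default 2.5: the distance
#'   a comet travels across a closable gap, plus localisation noise).
#' @return List of tracks, each a data.frame `t`, `x`, `y`, `quality` with
#'   strictly increasing frames.
#' @export
link_tracks <- function(detections, max_link_px = 3, max_gap_frames = 2,
                        max_gap_px = NULL) {
  if (is.null(max_gap_px)) max_gap_px <- 2.5
  det <- detections[order(detections$t), , drop = FALSE]
  if (nrow(det) == 0) return(list())
  det$id <- seq_len(nrow(det))
  frames <- sort(unique(det$t))
  nxt <- rep(NA_integer_, nrow(det))   # successor detection id

  by_frame <- split(det, det$t)
  for (fi in seq_len(length(frames) - 1)) {
    a <- by_frame[[as.character(frames[fi])]]
    b <- by_frame[[as.character(frames[fi + 1])]]
    if (frames[fi + 1] != frames[fi] + 1) next  # not consecutive
    m <- match_points(a$x, a$y, b$x, b$y, max_link_px)
    ok <- !is.na(m)
    nxt[a$id[ok]] <- b$id[m[ok]]
  }

  # assemble segments from the successor chains
  has_pred <- rep(FALSE, nrow(det))
  has_pred[nxt[!is.na(nxt)]] <- TRUE
  starts <- det$id[!has_pred]
  segs <- lapply(starts, function(s) {
    ids <- s
    while (!is.na(nxt[ids[length(ids)]])) ids <- c(ids, nxt[ids[length(ids)]])
    ids
  })

  # gap closing: ends of segments to starts of later segments
  if (max_gap_frames > 0 && length(segs) > 1) {
    ends <- t(vapply(segs, function(ids) {
      i <- ids[length(ids)]
      c(det$t[det$id == i], det$x[det$id == i], det$y[det$id == i])
    }, numeric(3)))
    heads <- t(vapply(segs, function(ids) {
      i <- ids[1]
      c(det$t[det$id == i], det$x[det$id == i], det$y[det$id == i])
    }, numeric(3)))
    ns <- length(segs)
    big <- 4 * max_gap_px^2 * (2 * ns) + 1
    cost <- matrix(big, 2 * ns, 2 * ns)
    feasible <- FALSE
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (i == j) next
      dt <- heads[j, 1] - ends[i, 1]
      if (dt < 2 || dt > max_gap_frames + 1) next
      d2 <- (heads[j, 2] - ends[i, 2])^2 + (heads[j, 3] - ends[i, 3])^2
      if (d2 > max_gap_px^2) next
      cost[i, j] <- d2
      feasible <- TRUE
    }
    if (feasible) {
      for (i in seq_len(ns)) cost[i, ns + i] <- max_gap_px^2
      for (j in seq_len(ns)) cost[ns + j, j] <- max_gap_px^2
      cost[(ns + 1):(2 * ns), (ns + 1):(2 * ns)] <- 0
      a <- solve_lap(cost)
      jointo <- rep(NA_integer_, ns)
      for (i in seq_len(ns)) {
        j <- a[i]
        if (j <= ns && j != i && cost[i, j] < big) jointo[i] <- j
      }
      is_target <- rep(FALSE, ns)
      is_target[jointo[!is.na(jointo)]] <- TRUE
      out <- list()
      for (i in seq_len(ns)) {
        if (is_target[i]) next         # continuation of an earlier segment
        chain <- segs[[i]]
        k <- i
        while (!is.na(jointo[k])) {
          k <- jointo[k]
          chain <- c(chain, segs[[k]])
        }
        out[[length(out) + 1]] <- chain
      }
      segs <- out
    }
  }

  lapply(segs, function(ids) {
    tr <- det[match(ids, det$id), c("t", "x", "y", "quality")]
    tr <- tr[order(tr$t), ]
    rownames(tr) <- NULL
    tr
  })
}

#' Per-track growth metrics
#'
#' @param track data.frame `t`, `x`, `y`, `quality` with >= 2 detections.
#' @param pixel_size_um,frame_interval_s calibration.
#' @return List of class `track_metrics`: `mean_speed_um_min` (net
#'   displacement over duration — robust to detection localisation
#'   noise, which inflates frame-to-frame link speeds for slow comets),
#'   `mean_link_speed_um_min` (mean over consecutive links of step
#'   length over step interval), `path_length_um` (summed step lengths),
#'   `net_displacement_um`, `duration_s`, `n_detections`,
#'   `mean_quality`.
#' @export
track_metrics <- function(track, pixel_size_um, frame_interval_s) {
  if (nrow(track) < 2) stop("track metrics need at least 2 detections")
  if (any(diff(track$t) <= 0)) stop("track frames must strictly increase")
  step_px <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  step_dt <- diff(track$t)
  link_speed <- (step_px * pixel_size_um) / (step_dt * frame_interval_s) * 60
  n <- nrow(track)
  net_px <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  dur_s <- (track$t[n] - track$t[1]) * frame_interval_s
  structure(list(
    mean_speed_um_min = net_px * pixel_size_um / dur_s * 60,
    mean_link_speed_um_min = mean(link_speed),
    path_length_um = sum(step_px) * pixel_size_um,
    net_displacement_um = sqrt((track$x[nrow(track)] - track$x[1])^2 +
                                 (track$y[nrow(track)] - track$y[1])^2) *
      pixel_size_um,
    duration_s = (track$t[nrow(track)] - track$t[1]) * frame_interval_s,
    n_detections = nrow(track),
    mean_quality = mean(track$quality)), class = "track_metrics")
}

#' Filter tracks on quality, displacement and length
#'
#' @param tracks list of track data.frames.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param min_quality minimum mean detection quality.
#' @param min_displacement_um minimum net displacement in um.
#' @param min_frames minimum number of detections.
#' @return The surviving tracks, each with its metrics attached as
#'   attribute `"metrics"`.
#' @export
filter_tracks <- function(tracks, pixel_size_um, frame_interval_s,
                          min_quality = 0, min_displacement_um = 0.1,
                          min_frames = 3) {
  out <- list()
  for (tr in tracks) {
    if (nrow(tr) < max(2, min_frames)) next
    m <- track_metrics(tr, pixel_size_um, frame_interval_s)
    if (m$mean_quality < min_quality) next
    if (m$net_displacement_um < min_displacement_um) next
    attr(tr, "metrics") <- m
    out[[length(out) + 1]] <- tr
  }
  out
}

#' Track EB3 comets across a whole cell movie
#'
#' Detection, linking, filtering and metrics in one call.
#'
#' @param series preprocessed EB3 [image_series()].
#' @param mask optional [cell_mask()]; detections outside are dropped.
#' @param sigma_px,quality_min detector settings (see [detect_comets()]).
#' @param max_link_px,max_gap_frames,max_gap_px linker settings
#'   (see [link_tracks()]).
#' @param min_quality,min_displacement_um,min_frames filter settings
#'   (see [filter_tracks()]).
#' @return List with `tracks` (filtered, with metrics), `detections`, and
#'   `metrics` (data.frame, one row per track).
#' @export
track_cell <- function(series, mask = NULL, sigma_px = 1.5,
                       quality_min = 0.3, max_link_px = 3,
                       max_gap_frames = 2, max_gap_px = NULL,
                       min_quality = 0, min_displacement_um = 0.1,
                       min_frames = 3) {
  det <- detect_comets_movie(series, sigma_px, quality_min)
  if (!is.null(mask) && nrow(det)) {
    inb <- mask$mask[cbind(pmin(pmax(round(det$y), 1), nrow(mask$mask)),
                           pmin(pmax(round(det$x), 1), ncol(mask$mask)))]
    det <- det[inb, , drop = FALSE]
  }
  tracks <- link_tracks(det, max_link_px, max_gap_frames, max_gap_px)
  tracks <- filter_tracks(tracks, series$pixel_size_um,
                          series$frame_interval_s, min_quality,
                          min_displacement_um, min_frames)
  metrics <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    m <- attr(tracks[[i]], "metrics")
    data.frame(track_id = i, mean_speed_um_min = m$mean_speed_um_min,
               path_length_um = m$path_length_um,
               net_displacement_um = m$net_displacement_um,
               duration_s = m$duration_s, n_detections = m$n_detections,
               mean_quality = m$mean_quality)
  }))
  if (is.null(metrics))
    metrics <- data.frame(track_id = integer(), mean_speed_um_min = numeric(),
                          path_length_um = numeric(),
                          net_displacement_um = numeric(),
                          duration_s = numeric(), n_detections = integer(),
                          mean_quality = numeric())
  list(tracks = tracks, detections = det, metrics = metrics)
}
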