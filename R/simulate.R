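#' Simulation parameters for synthetic two-channel microtubule movies
#'
#' Bundles every knob of the synthetic movie generator. The defaults emulate
#' the acquisition regime the analysis is designed for: 100 frames at a
#' 200-ms frame interval, 0.1 um pixels (typical 63x confocal sampling),
#' EB3 comets moving at 5-45 um/min along or away from a radial
#' interphase fiber network.
#'
#' @param image_shape integer c(height, width) in pixels (>= 32 per side).
#' @param n_frames number of frames (>= 2).
#' @param pixel_size_um,frame_interval_s physical calibration.
#' @param n_fibers number of fibers radiating from the nucleation point.
#' @param fiber_persistence persistence length of fiber curvature in px.
#' @param comet_rate expected growth-event initiations per frame; ignored
#'   when `n_events` is given.
#' @param n_events optional exact number of growth events (otherwise
#'   Poisson with mean `comet_rate * n_frames`).
#' @param growth_speed_mean,growth_speed_sd comet speed law in um/min
#'   (normal truncated at 0).
#' @param explorative_fraction probability in \[0,1\] that an event grows
#'   explorative (off-fiber, into new territory) rather than fiber-guided.
#' @param catastrophe_prob per-frame probability that a growth event ends
#'   once past `min_duration_frames`.
#' @param min_duration_frames shortest growth episode generated; comets
#'   briefer than this are not resolvable as events.
#' @param psf_sigma_px Gaussian point-spread sigma in px.
#' @param fiber_amplitude peak intensity of the static fiber bundles (AU).
#' @param mt_amplitude intensity of newly laid polymer for explorative
#'   growth (a single microtubule, dimmer than a bundle).
#' @param guided_amplitude intensity increment of polymer laid on top of an
#'   existing fiber (low contrast against the bundle).
#' @param comet_amplitude peak intensity of an EB3 comet.
#' @param photon_scale photons per intensity unit for Poisson shot noise;
#'   `Inf` disables noise.
#' @param read_noise Gaussian camera read noise, in photons.
#' @param bleach_rate monoexponential photobleaching rate per frame.
#' @param static_bg_amplitude amplitude of a smooth immobile background
#'   structure added to both channels.
#' @param seed integer seed; fixed seed gives bit-identical movies.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(image_shape = c(64, 64),
                       n_frames = 100,
                       pixel_size_um = 0.1,
                       frame_interval_s = 0.2,
                       n_fibers = 24,
                       fiber_persistence = 40,
                       comet_rate = 0.5,
                       n_events = NULL,
                       growth_speed_mean = 20,
                       growth_speed_sd = 5,
                       explorative_fraction = 0.3,
                       catastrophe_prob = 0.05,
                       min_duration_frames = 3,
                       psf_sigma_px = 1.5,
                       fiber_amplitude = 1,
                       mt_amplitude = 0.6,
                       guided_amplitude = 0.18,
                       comet_amplitude = 1.2,
                       photon_scale = 100,
                       read_noise = 2,
                       bleach_rate = 0.005,
                       static_bg_amplitude = 0.3,
                       seed = NULL) {
  p <- as.list(environment())
  if (length(p$image_shape) != 2L || any(p$image_shape < 32))
    stop("image_shape must be c(height, width) with >= 32 px per side")
  if (p$n_frames < 2) stop("n_frames must be >= 2")
  if (p$explorative_fraction < 0 || p$explorative_fraction > 1)
    stop("explorative_fraction must be in [0, 1]")
  if (p$growth_speed_mean <= 0) stop("growth_speed_mean must be > 0")
  if (p$psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (p$pixel_size_um <= 0 || p$frame_interval_s <= 0)
    stop("calibration must be > 0")
  class(p) <- "sim_params"
  p
}

# um/min -> px/frame under a calibration
um_min_to_px_frame <- function(v_um_min, pixel_size_um, frame_interval_s) {
  v_um_min * frame_interval_s / (60 * pixel_size_um)
}

#' Build a radial fiber network for one simulated cell
#'
#' Fibers radiate from a nucleation point near the image centre as
#' persistent random walks (bounded curvature set by `fiber_persistence`)
#' and are clipped to an elliptical cell mask.
#'
#' @param params a [sim_params()] object; the `seed` field (if non-NULL)
#'   makes the map deterministic.
#' @return A list of class `fiber_map` with elements `fibers` (list of
#'   two-column `x`,`y` polyline matrices, 1-based pixel coordinates),
#'   `cell_mask` (logical matrix) and `center`.
#' @export
build_fiber_map <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_fibers < 1) stop("need at least one fiber")
  h <- params$image_shape[1]; w <- params$image_shape[2]

  with_seed(derive_seed(params$seed, "fibers"), {
    cy <- h / 2 + runif(1, -2, 2)
    cx <- w / 2 + runif(1, -2, 2)
    ry <- 0.42 * h; rx <- 0.42 * w
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1

    step <- 1
    ang_sd <- sqrt(step / params$fiber_persistence)
    fibers <- vector("list", params$n_fibers)
    for (i in seq_len(params$n_fibers)) {
      theta <- 2 * pi * (i - 1) / params$n_fibers + runif(1, -0.1, 0.1)
      # fibers end at a random fraction of the cell radius, leaving
      # unoccupied cytoplasm beyond their tips for explorative growth
      r_dir <- 1 / sqrt((cos(theta) / rx)^2 + (sin(theta) / ry)^2)
      max_len <- runif(1, 0.35, 0.9) * r_dir
      x <- cx; y <- cy
      pts <- matrix(c(x, y), 1, 2)
      repeat {
        theta <- theta + rnorm(1, 0, ang_sd)
        x2 <- x + step * cos(theta); y2 <- y + step * sin(theta)
        ix <- round(y2); jx <- round(x2)
        if (ix < 1 || ix > h || jx < 1 || jx > w || !mask[ix, jx]) break
        x <- x2; y <- y2
        pts <- rbind(pts, c(x, y))
        if (nrow(pts) - 1 >= max_len) break
        if (nrow(pts) > 4 * max(h, w)) break
      }
      fibers[[i]] <- pts
    }
    structure(list(fibers = fibers, cell_mask = mask, center = c(cx, cy)),
              class = "fiber_map")
  })
}

# cumulative arclength of a polyline
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# point on polyline at arclength s (clamped)
polyline_point <- function(pts, arc, s) {
  s <- max(0, min(s, arc[length(arc)]))
  i <- findInterval(s, arc, all.inside = TRUE)
  f <- if (arc[i + 1] > arc[i]) (s - arc[i]) / (arc[i + 1] - arc[i]) else 0
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

#' Sample microtubule growth events on a fiber map
#'
#' Each event is explorative with probability `explorative_fraction`.
#' Fiber-guided events travel along an existing fiber polyline;
#' explorative events extend a straight path from a fiber tip outward
#' into unoccupied space. The network evolves dynamically: the polymer an
#' explorative event lays down extends its parent fiber, so later
#' explorative events from the same tip continue into genuinely new
#' territory. Guided events follow the original bundles only — a single
#' microtubule laid seconds earlier has not yet matured into a guide
#' track. Events are sampled in order of start frame to keep the network
#' state temporally consistent. Speeds are drawn from a normal law
#' truncated at zero; durations are geometric (`catastrophe_prob`) with a
#' floor of `min_duration_frames`.
#'
#' @param fibers a [build_fiber_map()] result.
#' @param params a [sim_params()] object.
#' @return List of `growth_event` records: `trajectory` (data.frame `t`,
#'   `x`, `y`; one row per frame), `speed_um_min`, `explorative`,
#'   `parent_fiber`.
#' @export
sample_growth_events <- function(fibers, params) {
  stopifnot(inherits(fibers, "fiber_map"), inherits(params, "sim_params"))
  if (length(fibers$fibers) == 0) stop("fiber map is empty")
  h <- params$image_shape[1]; w <- params$image_shape[2]

  with_seed(derive_seed(params$seed, "events"), {
    n <- if (!is.null(params$n_events)) params$n_events
         else rpois(1, params$comet_rate * params$n_frames)
    if (n == 0) return(list())
    t0s <- sort(sample.int(max(1, params$n_frames -
                                 params$min_duration_frames),
                           n, replace = TRUE))
    fib_now <- fibers$fibers          # network state, grows over time
    arcs_now <- lapply(fib_now, polyline_arclength)
    arcs_orig <- arcs_now
    n_orig <- length(fib_now)         # guided growth follows the original
                                      # bundles; single-MT extensions laid
                                      # during the movie are not yet
                                      # re-used as guide tracks
    events <- vector("list", n)
    i <- 0
    for (t0 in t0s) {
      explorative <- runif(1) < params$explorative_fraction
      v <- -1
      while (v <= 0)
        v <- rnorm(1, params$growth_speed_mean, params$growth_speed_sd)
      v_px <- um_min_to_px_frame(v, params$pixel_size_um,
                                 params$frame_interval_s)
      dur <- params$min_duration_frames + rgeom_one(params$catastrophe_prob)
      nt <- min(dur, params$n_frames - t0 + 1)
      if (nt < params$min_duration_frames) next
      ev <- NULL
      for (try in 1:50) {
        fi <- if (explorative) sample.int(length(fib_now), 1)
              else sample.int(n_orig, 1)
        pts <- if (explorative) fib_now[[fi]] else fibers$fibers[[fi]]
        arc <- if (explorative) arcs_now[[fi]] else arcs_orig[[fi]]
        L <- arc[length(arc)]
        if (explorative) {
          if (nrow(pts) < 2) next
          tip <- pts[nrow(pts), ]
          d <- pts[nrow(pts), ] - pts[max(1, nrow(pts) - 5), ]
          # the direction search widens over retries, so a tip blocked by
          # the cell boundary can still grow sideways into free space
          th <- atan2(d[2], d[1]) + rnorm(1, 0, 0.2 + 0.08 * (try - 1))
          tt <- seq_len(nt) - 1
          x <- tip[1] + v_px * tt * cos(th)
          y <- tip[2] + v_px * tt * sin(th)
        } else {
          if (L < v_px * params$min_duration_frames) next
          s0 <- runif(1, 0, max(0, L - v_px * nt) * 0.999)
          # the event ends when the tip reaches the end of the fiber
          nt_run <- min(nt, 1 + floor((L - s0) / v_px))
          if (nt_run < params$min_duration_frames) next
          tt <- seq_len(nt_run) - 1
          p <- t(vapply(s0 + v_px * tt,
                        function(s) polyline_point(pts, arc, s),
                        numeric(2)))
          x <- p[, 1]; y <- p[, 2]
        }
        ix <- pmin(pmax(round(y), 1), h); jx <- pmin(pmax(round(x), 1), w)
        inb <- x >= 2 & x <= w - 1 & y >= 2 & y <= h - 1 &
          fibers$cell_mask[cbind(ix, jx)]
        keep <- cumprod(inb) > 0  # stop at first exit from the cell
        if (sum(keep) < params$min_duration_frames) next
        ev <- list(trajectory = data.frame(t = t0 + which(keep) - 1,
                                           x = x[keep], y = y[keep]),
                   speed_um_min = v,
                   explorative = explorative,
                   parent_fiber = if (explorative) NA_integer_ else fi)
        class(ev) <- "growth_event"
        if (explorative) {
          # the new polymer becomes part of the network
          fib_now[[fi]] <- rbind(pts, cbind(x[keep], y[keep]))
          arcs_now[[fi]] <- polyline_arclength(fib_now[[fi]])
        }
        break
      }
      if (is.null(ev)) next  # no room for this event; drop it
      i <- i + 1
      events[[i]] <- ev
    }
    events[seq_len(i)]
  })
}

rgeom_one <- function(p) {
  if (p <= 0) return(1e9)
  stats::rgeom(1, p)
}

# add an isotropic Gaussian of peak `amp` to img (in place semantics via return)
add_gaussian <- function(img, x, y, sigma, amp) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3.5 * sigma)
  i0 <- max(1, floor(y) - r); i1 <- min(h, ceiling(y) + r)
  j0 <- max(1, floor(x) - r); j1 <- min(w, ceiling(x) + r)
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  gy <- exp(-((ii - y)^2) / (2 * sigma^2))
  gx <- exp(-((jj - x)^2) / (2 * sigma^2))
  img[ii, jj] <- img[ii, jj] + amp * outer(gy, gx)
  img
}

# splat a polyline segment as a chain of Gaussians approximating a
# PSF-convolved line of peak intensity `amp`
splat_line <- function(img, x0, y0, x1, y1, sigma, amp, spacing = 0.5) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  nseg <- max(1L, ceiling(len / spacing))
  a <- amp * (len / nseg) / (sigma * sqrt(2 * pi))
  if (len == 0) return(add_gaussian(img, x0, y0, sigma, amp))
  for (k in 0:nseg) {
    f <- k / nseg
    img <- add_gaussian(img, x0 + f * (x1 - x0), y0 + f * (y1 - y0),
                        sigma, a)
  }
  img
}

# smooth immobile background structure (low-pass filtered noise, peak-normalised)
static_structure <- function(h, w, amp) {
  z <- matrix(rnorm(h * w), h, w)
  z <- EBImage::gblur(z, sigma = 6)
  z <- z - min(z)
  if (max(z) > 0) z <- z / max(z)
  amp * z
}

#' Render a two-channel movie from a fiber map and growth events
#'
#' The GFP channel holds the static fiber skeleton plus polymer laid down
#' behind each growing tip (full-contrast for explorative events, a small
#' increment on top of the parent bundle for fiber-guided events). The EB3
#' channel holds a Gaussian comet at each event's current tip. Both
#' channels share a static background structure, monoexponential
#' photobleaching, Poisson shot noise at `photon_scale` and Gaussian read
#' noise; both carry the same calibration.
#'
#' @param fibers a [build_fiber_map()] result.
#' @param events list from [sample_growth_events()] (may be empty).
#' @param params a [sim_params()] object.
#' @return `list(gfp = image_series, eb3 = image_series)`.
#' @export
render_movie <- function(fibers, events, params) {
  stopifnot(inherits(fibers, "fiber_map"), inherits(params, "sim_params"))
  h <- params$image_shape[1]; w <- params$image_shape[2]
  nt <- params$n_frames
  s <- params$psf_sigma_px

  with_seed(derive_seed(params$seed, "render"), {
    base <- matrix(0, h, w)
    for (pts in fibers$fibers) {
      if (nrow(pts) < 2) next
      for (k in seq_len(nrow(pts) - 1))
        base <- splat_line(base, pts[k, 1], pts[k, 2],
                           pts[k + 1, 1], pts[k + 1, 2],
                           s, params$fiber_amplitude)
    }
    bg <- static_structure(h, w, params$static_bg_amplitude)

    # per-frame event state
    gfp <- array(0, c(h, w, nt))
    eb3 <- array(0, c(h, w, nt))
    poly <- base          # cumulative GFP polymer image
    for (t in seq_len(nt)) {
      for (ev in events) {
        tr <- ev$trajectory
        i <- match(t, tr$t)
        if (is.na(i)) next
        amp <- if (ev$explorative) params$mt_amplitude
               else params$guided_amplitude
        if (i > 1) {
          poly <- splat_line(poly, tr$x[i - 1], tr$y[i - 1],
                             tr$x[i], tr$y[i], s, amp)
        } else {
          poly <- add_gaussian(poly, tr$x[i], tr$y[i], s, amp)
        }
        eb3[, , t] <- add_gaussian(eb3[, , t], tr$x[i], tr$y[i],
                                   s, params$comet_amplitude)
      }
      gfp[, , t] <- poly
    }

    bleach <- exp(-params$bleach_rate * (seq_len(nt) - 1))
    for (t in seq_len(nt)) {
      gfp[, , t] <- (gfp[, , t] + bg) * bleach[t]
      eb3[, , t] <- (eb3[, , t] + bg) * bleach[t]
    }
    if (is.finite(params$photon_scale)) {
      ps <- params$photon_scale
      noisy <- function(a) {
        v <- rpois(length(a), pmax(a, 0) * ps) +
          rnorm(length(a), 0, params$read_noise)
        array(v / ps, dim(a))
      }
      gfp <- noisy(gfp)
      eb3 <- noisy(eb3)
    }
    list(gfp = image_series(gfp, params$pixel_size_um,
                            params$frame_interval_s, "tubulin-GFP"),
         eb3 = image_series(eb3, params$pixel_size_um,
                            params$frame_interval_s, "EB3"))
  })
}

#' Ground-truth summary of a simulated event set
#'
#' @param events list from [sample_growth_events()].
#' @param params the [sim_params()] used.
#' @return List with `true_mean_speed_um_min`, `true_event_count`,
#'   `true_explorative_fraction`.
#' @export
ground_truth <- function(events, params) {
  n <- length(events)
  list(true_mean_speed_um_min =
         if (n) mean(vapply(events, `[[`, numeric(1), "speed_um_min"))
         else NA_real_,
       true_event_count = n,
       true_explorative_fraction =
         if (n) mean(vapply(events, `[[`, logical(1), "explorative"))
         else NA_real_)
}

#' Simulate one complete two-channel cell movie
#'
#' Convenience wrapper: fiber map, growth events, rendered channels and
#' ground truth in one call, fully determined by `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return List with `gfp`, `eb3` ([image_series()]), `fibers`, `events`,
#'   `mask` ([cell_mask()]) and `truth`.
#' @export
simulate_cell <- function(params = sim_params()) {
  fibers <- build_fiber_map(params)
  events <- sample_growth_events(fibers, params)
  movie <- render_movie(fibers, events, params)
  list(gfp = movie$gfp, eb3 = movie$eb3, fibers = fibers, events = events,
       mask = cell_mask(fibers$cell_mask, "sim"),
       truth = ground_truth(events, params))
}

#' Simulate a uniform-flow calibration movie
#'
#' A field of Gaussian particles all translating at a fixed velocity on a
#' periodic domain (density constant over time), with the same camera model
#' as [render_movie()]. Used to validate velocity recovery.
#'
#' @param image_shape c(height, width) px.
#' @param n_frames number of frames.
#' @param v velocity `c(vx, vy)` in px/frame.
#' @param n_particles number of particles.
#' @param psf_sigma_px,photon_scale,read_noise camera model (see
#'   [sim_params()]).
#' @param amplitude particle peak intensity.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param seed integer seed.
#' @return An [image_series()] with attribute `true_v` (px/frame).
#' @export
simulate_uniform_flow <- function(image_shape = c(64, 64), n_frames = 60,
                                  v = c(0.5, 0), n_particles = 60,
                                  psf_sigma_px = 1.5, photon_scale = 100,
                                  read_noise = 2, amplitude = 1,
                                  pixel_size_um = 0.1,
                                  frame_interval_s = 0.2, seed = NULL) {
  h <- image_shape[1]; w <- image_shape[2]
  with_seed(seed, {
    x0 <- runif(n_particles, 1, w)
    y0 <- runif(n_particles, 1, h)
    dat <- array(0, c(h, w, n_frames))
    for (t in seq_len(n_frames)) {
      img <- matrix(0, h, w)
      x <- (x0 + v[1] * (t - 1) - 1) %% w + 1
      y <- (y0 + v[2] * (t - 1) - 1) %% h + 1
      for (k in seq_len(n_particles))
        img <- add_gaussian(img, x[k], y[k], psf_sigma_px, amplitude)
      if (is.finite(photon_scale))
        img <- matrix((rpois(length(img), img * photon_scale) +
                         rnorm(length(img), 0, read_noise)) / photon_scale,
                      h, w)
      dat[, , t] <- img
    }
    out <- image_series(dat, pixel_size_um, frame_interval_s, "uniform-flow")
    attr(out, "true_v") <- v
    out
  })
}

#' Write a simulated cell to disk
#'
#' Writes paired multi-page TIFF stacks (one per channel, with calibration
#' sidecars), a ground-truth CSV (event id, frame, x, y, speed, explorative
#' flag) and a JSON copy of the simulation parameters.
#'
#' @param sim result of [simulate_cell()].
#' @param params the [sim_params()] used.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, params, dir, prefix = "cell") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_movie(sim$gfp, file.path(dir, paste0(prefix, "_gfp.tif")))
  write_movie(sim$eb3, file.path(dir, paste0(prefix, "_eb3.tif")))
  rows <- do.call(rbind, lapply(seq_along(sim$events), function(i) {
    ev <- sim$events[[i]]
    data.frame(event = i, frame = ev$trajectory$t,
               x = ev$trajectory$x, y = ev$trajectory$y,
               speed_um_min = ev$speed_um_min,
               explorative = ev$explorative)
  }))
  if (is.null(rows))
    rows <- data.frame(event = integer(), frame = integer(), x = numeric(),
                       y = numeric(), speed_um_min = numeric(),
                       explorative = logical())
  write.csv(rows, file.path(dir, paste0(prefix, "_truth.csv")),
            row.names = FALSE)
  jsonlite::write_json(unclass(params),
                       file.path(dir, paste0(prefix, "_params.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
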