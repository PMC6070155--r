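#' Sub-pixel location of a correlation peak
#'
#' Finds the maximum of one temporal-lag slice of a correlation function
#' and refines it to sub-pixel precision by a 2-d Gaussian fit (quadratic
#' fit to the log-values in a 5x5 window; a plain paraboloid when the
#' window contains non-positive values; an intensity-weighted centroid
#' when the curvature fit is not peak-like). The search is restricted to
#' `|xi|, |eta| <= roi/2 - 2` to keep clear of FFT padding edges.
#'
#' @param corr a [correlation_function()].
#' @param tau temporal lag (one of `corr$tau`).
#' @param center optional `c(xi, eta)`: restrict the search to a
#'   neighbourhood of this position (peak tracking across lags).
#' @param radius search radius around `center` in px (default 3).
#' @return List with `ok` (logical), `xi`, `eta` (sub-pixel lag of the
#'   peak), and `amplitude` (peak height). A flat or invalid slice
#'   returns `ok = FALSE`.
#' @export
locate_peak <- function(corr, tau, center = NULL, radius = 3) {
  stopifnot(inherits(corr, "correlation_function"))
  k <- match(tau, corr$tau)
  if (is.na(k)) stop("tau outside the computed lag range")
  if (!corr$valid) return(list(ok = FALSE, xi = NA_real_, eta = NA_real_,
                               amplitude = NA_real_))
  slice <- corr$r[, , k]
  Ls <- max(corr$xi) - 1L  # search limit
  seli <- selj <- abs(corr$xi) <= Ls
  if (!is.null(center)) {
    selj <- selj & abs(corr$xi - center[1]) <= radius
    seli <- seli & abs(corr$eta - center[2]) <= radius
  }
  sub <- slice[seli, selj, drop = FALSE]
  if (length(sub) == 0 || max(sub) <= 0 || !all(is.finite(sub)))
    return(list(ok = FALSE, xi = NA_real_, eta = NA_real_,
                amplitude = NA_real_))
  amx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  eta_c <- corr$eta[seli][amx[1]]; xi_c <- corr$xi[selj][amx[2]]

  # 5x5 fitting window, clipped to the stored lag range
  full <- corr$xi
  wi <- which(full >= eta_c - 2 & full <= eta_c + 2)
  wj <- which(full >= xi_c - 2 & full <= xi_c + 2)
  vals <- slice[wi, wj, drop = FALSE]
  dy <- full[wi] - eta_c
  dx <- full[wj] - xi_c
  DX <- matrix(dx, length(dy), length(dx), byrow = TRUE)
  DY <- matrix(dy, length(dy), length(dx))

  fit <- fit_quad_peak(vals, DX, DY)
  de <- fit$dy; dxi <- fit$dx
  # clamp the refinement to the window
  de <- max(min(de, 2), -2); dxi <- max(min(dxi, 2), -2)
  list(ok = TRUE, xi = xi_c + dxi, eta = eta_c + de,
       amplitude = fit$amplitude)
}

# quadratic / log-Gaussian peak interpolation with centroid fallback
fit_quad_peak <- function(vals, DX, DY) {
  v <- as.vector(vals)
  logfit <- all(v > 0)
  y <- if (logfit) log(v) else v
  X <- cbind(1, as.vector(DX), as.vector(DY),
             as.vector(DX)^2, as.vector(DY)^2, as.vector(DX * DY))
  beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
  if (!is.null(beta)) {
    H <- matrix(c(2 * beta[4], beta[6], beta[6], 2 * beta[5]), 2)
    if (H[1, 1] < 0 && det(H) > 0) {   # negative definite: a real peak
      sol <- -solve(H, c(beta[2], beta[3]))
      val <- drop(beta[1] + beta[2] * sol[1] + beta[3] * sol[2] +
                    beta[4] * sol[1]^2 + beta[5] * sol[2]^2 +
                    beta[6] * sol[1] * sol[2])
      return(list(dx = sol[1], dy = sol[2],
                  amplitude = if (logfit) exp(val) else val))
    }
  }
  w <- v - min(v)
  if (sum(w) == 0) return(list(dx = 0, dy = 0, amplitude = max(v)))
  list(dx = sum(w * as.vector(DX)) / sum(w),
       dy = sum(w * as.vector(DY)) / sum(w), amplitude = max(v))
}

#' Fit a flow vector from correlation-peak translation
#'
#' Tracks the correlation peak over temporal lags and fits the velocity as
#' the amplitude-weighted least-squares slope of peak position against
#' lag, anchored at the `tau = 0` peak. Lags are usable when a peak is
#' found with amplitude at least `amp_min_frac` of the zero-lag peak; at
#' least 3 usable lags are required, otherwise no vector is returned.
#'
#' @param corr a [correlation_function()].
#' @param tau_fit_range lags used for the fit (default all positive lags;
#'   include negative lags to extend the measurable range for an offset
#'   cross-correlation peak).
#' @param amp_min_frac minimum peak amplitude relative to the zero-lag
#'   peak for a lag to be usable (default 0.1).
#' @param min_lags usable lags required for a vector (default 3, the
#'   hard minimum). Raising it suppresses vectors from signals present
#'   for only a small part of the time window; a peak that leaves the
#'   measurable lag range while being tracked (fast genuine flow) is
#'   exempt down to 3 lags.
#' @param p0_radius optional restriction of the zero-lag peak search to
#'   within this distance of zero lag. For a cross-correlation the
#'   physical zero-lag offset between the two channels' signals is
#'   bounded, so anchoring the search prevents a weak true peak losing
#'   the argmax to a far-out noise excursion.
#' @return List of class `flow_vector`: `ok`, `vx`, `vy` (px/frame),
#'   `speed_um_min`, `quality` (weighted fit R-squared), `peak_amplitude`
#'   (mean usable peak amplitude), `n_lags`.
#' @export
fit_velocity <- function(corr, tau_fit_range = NULL, amp_min_frac = 0.1,
                         min_lags = 3, p0_radius = NULL) {
  stopifnot(inherits(corr, "correlation_function"))
  no_vec <- list(ok = FALSE, vx = NA_real_, vy = NA_real_,
                 speed_um_min = NA_real_, quality = NA_real_,
                 peak_amplitude = NA_real_, n_lags = 0L)
  class(no_vec) <- "flow_vector"
  if (!corr$valid) return(no_vec)
  if (is.null(tau_fit_range)) tau_fit_range <- corr$tau[corr$tau >= 1]

  p0 <- if (is.null(p0_radius)) locate_peak(corr, 0)
        else locate_peak(corr, 0, center = c(0, 0), radius = p0_radius)
  if (!p0$ok) return(no_vec)
  ref <- p0$amplitude

  # track the peak outward from the zero-lag position in each temporal
  # direction: each lag's search is restricted to a neighbourhood of the
  # previous peak (flow continuity), and tracking stops once the peak
  # reaches the edge of the measurable lag range
  edge <- max(corr$xi) - 2
  edge_exit <- FALSE
  tt <- c(); dxs <- c(); dys <- c(); ww <- c()
  for (sgn in c(1, -1)) {
    rng <- sort(abs(tau_fit_range[sign(tau_fit_range) == sgn]))
    prev <- c(p0$xi, p0$eta)
    for (atau in rng) {
      p <- locate_peak(corr, sgn * atau, center = prev)
      if (!p$ok || !is.finite(p$amplitude)) next
      if (abs(p$xi) > edge || abs(p$eta) > edge) { edge_exit <- TRUE; break }
      prev <- c(p$xi, p$eta)
      if (p$amplitude < amp_min_frac * ref) next
      tt <- c(tt, sgn * atau)
      dxs <- c(dxs, p$xi - p0$xi)
      dys <- c(dys, p$eta - p0$eta)
      ww <- c(ww, max(p$amplitude, 0))
    }
  }
  need <- if (edge_exit) 3 else max(3, min_lags)
  if (length(tt) < need || sum(ww) <= 0) return(no_vec)

  s2 <- sum(ww * tt^2)
  vx <- sum(ww * tt * dxs) / s2
  vy <- sum(ww * tt * dys) / s2
  ss_res <- sum(ww * ((dxs - vx * tt)^2 + (dys - vy * tt)^2))
  ss_tot <- sum(ww * (dxs^2 + dys^2))
  quality <- if (ss_tot <= .Machine$double.eps) 1
             else max(0, 1 - ss_res / ss_tot)
  out <- list(ok = TRUE, vx = vx, vy = vy,
              speed_um_min = velocity_to_physical(
                sqrt(vx^2 + vy^2), corr$pixel_size_um,
                corr$frame_interval_s),
              quality = quality,
              peak_amplitude = mean(ww), n_lags = length(tt))
  class(out) <- "flow_vector"
  out
}

#' Compute a STICCS vector field over a voxel grid
#'
#' Runs the full single-cell STICCS computation: for every voxel of the
#' grid, correlation functions are computed for the requested channel
#' pairs (GFP autocorrelation, EB3 autocorrelation, GFP-to-EB3
#' cross-correlation) and a flow vector is extracted from the translation
#' of each correlation peak. Vectors with fit quality at least
#' `quality_min` are marked retained; apply [similarity_filter()]
#' afterwards to remove isolated noise vectors.
#'
#' @param gfp,eb3 [image_series()] for the two channels (either may be
#'   omitted when its modes are not requested); should already be
#'   immobile-filtered (see [immobile_filter()]).
#' @param mask optional [cell_mask()].
#' @param grid optional [tile_voxels()] result; built from defaults
#'   otherwise.
#' @param modes subset of `"gfp_auto"`, `"eb3_auto"`, `"cross"`.
#' @param tau_max largest temporal lag (default 10); the cross mode is
#'   fitted over both positive and negative lags.
#' @param quality_min retention threshold on fit R-squared (default 0.7).
#' @param amp_min_frac see [fit_velocity()].
#' @param min_lags usable lags required for the autocorrelation modes
#'   (default 6): signals present for only a small part of the TOI do not
#'   produce a vector, so the EB3 event census counts sustained transits;
#'   fast flows whose peak leaves the lag range are exempt (see
#'   [fit_velocity()]).
#' @param cross_tau_max,cross_min_lags,cross_p0_radius,cross_quality_min
#'   cross-mode fit settings. The cross peak of a growing microtubule
#'   trail is broader, offset and noisier than an autocorrelation peak:
#'   it is fitted over short two-sided lags (default +/-4), anchored near
#'   zero lag (radius 4 px), and retained at a lower quality threshold
#'   (default 0.3) because classification applies its own contrast,
#'   direction and speed gates afterwards.
#' @param gfp_mean_src,eb3_mean_src optional [image_series()] (typically
#'   the preprocessed series before the immobile filter) whose voxel mean
#'   intensities provide the correlation normalisation denominators. The
#'   immobile filter zeroes the filtered series' means, so without a mean
#'   source amplitudes are SD-normalised; with it they are on the
#'   mean-normalised scale, where the amplitude of a cross peak reflects
#'   the relative contrast of the co-moving signal against the local
#'   structure (the quantity that separates explorative growth from
#'   assembly along a bright existing fiber).
#' @return A `vector_field`: data.frame of flow vectors (`mode`, voxel
#'   lattice indices, centre `x`, `y` px and `t` frames, `vx`, `vy`
#'   px/frame, `speed_um_min`, `quality`, `peak_amplitude`, `retained`)
#'   with the grid attached.
#' @export
sticcs_vector_field <- function(gfp = NULL, eb3 = NULL, mask = NULL,
                                grid = NULL,
                                modes = c("gfp_auto", "eb3_auto", "cross"),
                                tau_max = 10, quality_min = 0.7,
                                amp_min_frac = 0.1, min_lags = 6,
                                cross_tau_max = 4, cross_min_lags = 3,
                                cross_p0_radius = 4,
                                cross_quality_min = 0.3,
                                gfp_mean_src = NULL, eb3_mean_src = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  need_gfp <- any(modes %in% c("gfp_auto", "cross"))
  need_eb3 <- any(modes %in% c("eb3_auto", "cross"))
  if (need_gfp && is.null(gfp)) stop("gfp series required for these modes")
  if (need_eb3 && is.null(eb3)) stop("eb3 series required for these modes")
  ref <- if (!is.null(gfp)) gfp else eb3
  if (!is.null(gfp) && !is.null(eb3)) assert_same_geometry(gfp, eb3)
  d <- dim(ref$data)
  if (is.null(grid))
    grid <- tile_voxels(d[1:2], d[3], mask = mask)
  R <- grid$roi_size_px; T <- grid$toi_len_frames
  if (tau_max >= T) stop("tau_max must be < toi_len_frames")
  L <- R %/% 2
  P <- next_fft_size(R + L)
  Q <- next_fft_size(T + tau_max)

  an <- grid$anchors
  rows <- vector("list", nrow(an) * length(modes))
  nr <- 0
  for (i in seq_len(nrow(an))) {
    x0 <- an$x0[i]; y0 <- an$y0[i]; t0 <- an$t0[i]
    blk <- function(s) s$data[y0:(y0 + R - 1), x0:(x0 + R - 1),
                              t0:(t0 + T - 1), drop = FALSE]
    ga <- if (need_gfp) blk(gfp) else NULL
    ea <- if (need_eb3) blk(eb3) else NULL
    # the GFP channel and the cross pair correlate fluctuations about the
    # per-pixel temporal mean within the voxel, so polymer laid earlier in
    # the movie (static within this TOI) cannot correlate; the EB3
    # autocorrelation uses the immobile-filtered series directly — comets
    # are transient, and the within-TOI mean subtraction would bias the
    # recovered speed of slow flows
    Fg <- if (need_gfp) pad_fft(voxel_fluctuations(ga), P, Q) else NULL
    Fe_raw <- if ("eb3_auto" %in% modes) pad_fft(ea, P, Q) else NULL
    Fe <- if ("cross" %in% modes) pad_fft(voxel_fluctuations(ea), P, Q)
          else NULL
    mg <- if (!is.null(gfp_mean_src)) mean(blk(gfp_mean_src)) else NA_real_
    me <- if (!is.null(eb3_mean_src)) mean(blk(eb3_mean_src)) else NA_real_

    for (mode in modes) {
      ab <- switch(mode,
                   gfp_auto = list(ga, ga, Fg, Fg),
                   eb3_auto = list(ea, ea, Fe_raw, Fe_raw),
                   cross = list(ga, ea, Fg, Fe))
      dn <- corr_denominator(ab[[1]], ab[[2]])
      if (is.null(dn)) next
      mean_dn <- switch(mode, gfp_auto = mg * mg, eb3_auto = me * me,
                        cross = mg * me)
      if (is.finite(mean_dn) && mean_dn > 0)
        dn <- list(value = mean_dn, mode = "mean_src")
      r <- corr_from_ffts(ab[[3]], ab[[4]], R, T, L, tau_max, dn$value)
      cf <- structure(list(r = r, xi = (-L):L, eta = (-L):L,
                           tau = (-tau_max):tau_max,
                           channel_pair = mode, normalization = dn$mode,
                           denom = dn$value, roi_size_px = R,
                           toi_len_frames = T,
                           pixel_size_um = ref$pixel_size_um,
                           frame_interval_s = ref$frame_interval_s,
                           valid = TRUE),
                      class = "correlation_function")
      cross <- mode == "cross"
      fv <- fit_velocity(
        cf,
        tau_fit_range = if (cross) setdiff((-cross_tau_max):cross_tau_max, 0)
                        else 1:tau_max,
        amp_min_frac = amp_min_frac,
        min_lags = if (cross) cross_min_lags else min_lags,
        p0_radius = if (cross) cross_p0_radius else NULL)
      if (!fv$ok) next
      nr <- nr + 1
      rows[[nr]] <- data.frame(
        mode = mode, ix = an$ix[i], iy = an$iy[i], it = an$it[i],
        x = x0 + R / 2 - 0.5, y = y0 + R / 2 - 0.5,
        t = t0 + T / 2 - 0.5,
        vx = fv$vx, vy = fv$vy, speed_um_min = fv$speed_um_min,
        quality = fv$quality, peak_amplitude = fv$peak_amplitude,
        mean_gfp = mg, mean_eb3 = me,
        retained = fv$quality >=
          if (cross) cross_quality_min else quality_min)
    }
  }
  vecs <- if (nr) do.call(rbind, rows[seq_len(nr)])
          else data.frame(mode = character(), ix = integer(), iy = integer(),
                          it = integer(), x = numeric(), y = numeric(),
                          t = numeric(), vx = numeric(), vy = numeric(),
                          speed_um_min = numeric(), quality = numeric(),
                          peak_amplitude = numeric(), mean_gfp = numeric(),
                          mean_eb3 = numeric(), retained = logical())
  structure(list(vectors = vecs, grid = grid,
                 pixel_size_um = ref$pixel_size_um,
                 frame_interval_s = ref$frame_interval_s),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  v <- x$vectors
  cat(sprintf("vector_field: %d vectors (%d retained) over %d voxels\n",
              nrow(v), sum(v$retained), nrow(x$grid$anchors)))
  for (m in unique(v$mode))
    cat(sprintf("  %s: %d retained, median speed %.2f um/min\n", m,
                sum(v$retained[v$mode == m]),
                median(v$speed_um_min[v$retained & v$mode == m])))
  invisible(x)
}

# angle (deg) between two vectors; NA when either is (numerically) zero
vector_angle_deg <- function(ax, ay, bx, by) {
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  ifelse(na < 1e-12 | nb < 1e-12, NA_real_,
         acos(pmin(pmax((ax * bx + ay * by) / (na * nb), -1), 1)) * 180 / pi)
}



#' Reject noise vectors by neighbourhood similarity
#'
#' A retained vector is kept only if at least `min_similar_neighbors` of
#' its 8-connected grid neighbours (same TOI, same mode, themselves
#' quality-retained) agree with it within `angle_max_deg` in direction and
#' within a factor `mag_ratio_max` in magnitude. Rejected vectors stay in
#' the field with `retained = FALSE` for audit, and are excluded from all
#' summaries. In an isotropic noise field almost all vectors fail this
#' criterion, while coherent flow patches survive.
#'
#' @param field a [sticcs_vector_field()] result.
#' @param angle_max_deg direction tolerance (default 45).
#' @param mag_ratio_max magnitude ratio tolerance (default 2).
#' @param min_similar_neighbors required number of agreeing neighbours
#'   (default 2).
#' @param cross_min_similar neighbour requirement for the sparser cross
#'   mode (default 1).
#' @return The filtered `vector_field`.
#' @export
similarity_filter <- function(field, angle_max_deg = 45, mag_ratio_max = 2,
                              min_similar_neighbors = 2,
                              cross_min_similar = 1) {
  stopifnot(inherits(field, "vector_field"))
  v <- field$vectors
  if (nrow(v) == 0) return(field)
  keep <- v$retained
  for (m in unique(v$mode)) {
    req <- if (m == "cross") cross_min_similar else min_similar_neighbors
    idx <- which(v$mode == m & v$retained)
    if (!length(idx)) next
    sub <- v[idx, ]
    key <- paste(sub$ix, sub$iy, sub$it)
    pos <- split(seq_along(idx), key)
    for (k in seq_along(idx)) {
      i <- idx[k]
      nsim <- 0
      for (dxg in -1:1) for (dyg in -1:1) {
        if (dxg == 0 && dyg == 0) next
        nb <- pos[[paste(v$ix[i] + dxg, v$iy[i] + dyg, v$it[i])]]
        if (is.null(nb)) next
        for (j2 in nb) {
          j <- idx[j2]
          ang <- vector_angle_deg(v$vx[i], v$vy[i], v$vx[j], v$vy[j])
          si <- sqrt(v$vx[i]^2 + v$vy[i]^2)
          sj <- sqrt(v$vx[j]^2 + v$vy[j]^2)
          similar <-
            if (si < 1e-12 && sj < 1e-12) TRUE
            else if (is.na(ang)) FALSE
            else ang <= angle_max_deg &&
                 max(si, sj) <= mag_ratio_max * min(si, sj)
          if (similar) nsim <- nsim + 1
        }
      }
      if (nsim < req) keep[i] <- FALSE
    }
  }
  field$vectors$retained <- keep
  field
}

#' Label explorative (cross-correlated) growth events
#'
#' Every retained EB3 autocorrelation vector is labelled
#' `cross_correlated = TRUE` when a retained cross-correlation vector of
#' sufficient contrast, similar speed (within a factor `speed_ratio_max`)
#' and direction (within `angle_max_deg`) sits in its voxel or — because
#' the cross peak of a growing microtubule localises slightly behind the
#' comet, often in a neighbouring overlapping voxel — in an adjacent
#' voxel of the same TOI. The contrast gate is evaluated at the cross
#' vector's own voxel, so a weak far-away EB3 vector cannot promote a
#' low-contrast cross vector. Explorative growth — GFP and EB3 signals advancing together
#' into new territory — produces such matched pairs; assembly along an
#' existing fiber leaves the cross channel silent and is labelled `FALSE`
#' (fiber-guided).
#'
#' @param eb3_auto a `vector_field` holding the `eb3_auto` mode (it may
#'   also hold the cross mode, in which case `cross` can be omitted).
#' @param cross optional `vector_field` holding the `cross` mode, on the
#'   same grid.
#' @param speed_ratio_max speed-ratio window (default 3; the cross peak of
#'   a growing trail translates somewhat slower than the comet itself, so
#'   the window is looser than the similarity filter's).
#' @param angle_max_deg direction window in degrees (default 45).
#' @param min_polymer minimum reconstructed brightness of the co-moving
#'   GFP polymer (image intensity units; see Details in the source
#'   comment): a value between the brightness of a single microtubule
#'   laid on an existing bundle and that of a new fiber entering empty
#'   territory. Set 0 to disable.
#' @param neighborhood where candidate cross vectors may sit relative to
#'   the EB3 vector's voxel: `"adjacent"` (default) — the voxel plus all
#'   8 neighbours, matched exclusively in two passes (own voxel first);
#'   `"trailing"` — the voxel plus the adjacent voxels behind it along
#'   its direction of motion; `"back"` — the voxel plus the single voxel
#'   straight back.
#' @param min_contrast minimum ratio of the cross vector's peak amplitude
#'   to the EB3 vector's peak amplitude. On the mean-normalised amplitude
#'   scale (see [sticcs_vector_field()]) this ratio measures the relative
#'   contrast of co-moving GFP signal against the local microtubule
#'   structure: explorative growth into empty territory scores high,
#'   a faint increment on a bright existing bundle scores low.
#' @return The `eb3_auto` field with a `cross_correlated` column on its
#'   vectors (NA for non-retained or non-EB3 vectors).
#' @export
classify_cross_events <- function(eb3_auto, cross = NULL,
                                  speed_ratio_max = 3, angle_max_deg = 45,
                                  min_contrast = 0.05,
                                  min_polymer = 0.14,
                                  neighborhood = c("adjacent", "trailing",
                                                   "back")) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(inherits(eb3_auto, "vector_field"))
  v <- eb3_auto$vectors
  if (is.null(cross)) {
    cv <- v[v$mode == "cross" & v$retained, ]
  } else {
    stopifnot(inherits(cross, "vector_field"))
    if (!same_grid(eb3_auto$grid, cross$grid))
      stop("eb3_auto and cross fields are on different grids")
    cv <- cross$vectors[cross$vectors$mode == "cross" &
                          cross$vectors$retained, ]
  }
  ckey <- paste(cv$ix, cv$iy, cv$it)
  cpos <- split(seq_len(nrow(cv)), ckey)
  lab <- rep(NA, nrow(v))
  tgt <- which(v$mode == "eb3_auto" & v$retained)

  # contrast score of each cross vector: its amplitude relative to the
  # EB3 amplitude of the comet that produced it — the EB3 vector in its
  # own voxel when there is one (transit geometry cancels), otherwise
  # the largest retained EB3 amplitude among the adjacent voxels
  # (conservative for stray low-contrast cross vectors). From the score
  # the brightness of the co-moving GFP polymer is reconstructed:
  # r_cross ~ ampG*ampE/(<G><E>) and r_eb3 ~ ampE^2/<E>^2, so
  # ampG ~ (r_cross/r_eb3) * <G> * sqrt(r_eb3) / <E> up to a shape
  # factor — independent of the local structure brightness <G>, which
  # makes one polymer-brightness threshold valid across dense and sparse
  # regions of the network.
  eb_all <- v[v$mode == "eb3_auto" & v$retained, ]
  ebkey <- paste(eb_all$ix, eb_all$iy, eb_all$it)
  epos <- split(seq_len(nrow(eb_all)), ebkey)
  cscore <- ampG <- rep(NA_real_, nrow(cv))
  for (j in seq_len(nrow(cv))) {
    ref <- NA_real_
    own <- epos[[ckey[j]]]
    if (!is.null(own)) {
      ref <- max(eb_all$peak_amplitude[own])
    } else {
      amps <- c()
      for (dxg in -1:1) for (dyg in -1:1) {
        nb <- epos[[paste(cv$ix[j] + dxg, cv$iy[j] + dyg, cv$it[j])]]
        if (!is.null(nb)) amps <- c(amps, eb_all$peak_amplitude[nb])
      }
      if (length(amps)) ref <- max(amps)
    }
    if (!is.finite(ref) || ref <= 0) next
    cscore[j] <- cv$peak_amplitude[j] / ref
    if (all(c("mean_gfp", "mean_eb3") %in% names(cv)) &&
        is.finite(cv$mean_gfp[j]) && is.finite(cv$mean_eb3[j]) &&
        cv$mean_eb3[j] > 0)
      ampG[j] <- cscore[j] * cv$mean_gfp[j] * sqrt(ref) / cv$mean_eb3[j]
  }

  gates_ok <- function(i, j) {
    se <- v$speed_um_min[i]; sc <- cv$speed_um_min[j]
    if (se <= 0 || sc <= 0) return(FALSE)
    if (is.na(cscore[j]) || cscore[j] < min_contrast) return(FALSE)
    if (min_polymer > 0 && is.finite(ampG[j]) && ampG[j] < min_polymer)
      return(FALSE)

    ang <- vector_angle_deg(v$vx[i], v$vy[i], cv$vx[j], cv$vy[j])
    !is.na(ang) && ang <= angle_max_deg &&
      max(se, sc) <= speed_ratio_max * min(se, sc)
  }
  neighbour_offsets <- function(i) {
    out <- list()
    sp <- sqrt(v$vx[i]^2 + v$vy[i]^2)
    if (neighborhood == "adjacent") {
      for (dxg in -1:1) for (dyg in -1:1)
        if (dxg || dyg) out[[length(out) + 1]] <- c(dxg, dyg)
    } else if (sp > 1e-12) {
      ux <- v$vx[i] / sp; uy <- v$vy[i] / sp
      if (neighborhood == "back") {
        out[[1]] <- c(-round(ux), -round(uy))
      } else {  # trailing: neighbours with negative projection on motion
        for (dxg in -1:1) for (dyg in -1:1)
          if ((dxg || dyg) && dxg * ux + dyg * uy < -0.3)
            out[[length(out) + 1]] <- c(dxg, dyg)
      }
    }
    out
  }

  for (i in tgt) {
    lab[i] <- FALSE
    hits <- cpos[[paste(v$ix[i], v$iy[i], v$it[i])]]
    nbh <- integer(0)
    for (d in neighbour_offsets(i)) {
      nb <- cpos[[paste(v$ix[i] + d[1], v$iy[i] + d[2], v$it[i])]]
      if (!is.null(nb)) nbh <- c(nbh, nb)
    }
    # a neighbourhood contributes at most its best-scoring candidate
    nbh <- setdiff(nbh, hits)
    if (length(nbh))
      hits <- c(hits, nbh[which.max(cscore[nbh])])
    for (j in hits) {
      if (gates_ok(i, j)) { lab[i] <- TRUE; break }
    }
  }
  eb3_auto$vectors$cross_correlated <- lab
  eb3_auto
}

#' Render a quiver map of a vector field
#'
#' Writes (or draws) a velocity vector map for one mode and TOI: arrows at
#' voxel centres, coloured by speed, over the voxel grid extent.
#'
#' @param field a `vector_field`.
#' @param mode which mode to draw.
#' @param it which TOI (lattice index, default 1).
#' @param file optional PNG path; when given the plot is written there.
#' @param scale arrow length per px/frame of velocity (default 8).
#' @return Invisibly, the plotted subset of vectors.
#' @export
plot_vector_field <- function(field, mode = "eb3_auto", it = 1,
                              file = NULL, scale = 8) {
  v <- field$vectors
  v <- v[v$mode == mode & v$retained & v$it == it, ]
  if (!is.null(file)) {
    png(file, width = 600, height = 600)
    on.exit(dev.off())
  }
  sh <- field$grid$image_shape
  plot(NA, xlim = c(1, sh[2]), ylim = c(sh[1], 1), asp = 1,
       xlab = "x (px)", ylab = "y (px)",
       main = sprintf("%s vectors, TOI %d", mode, it))
  if (nrow(v)) {
    cols <- hcl.colors(64, "viridis")
    ci <- pmin(64L, 1L + floor(63 * v$speed_um_min /
                                 max(v$speed_um_min, 1e-9)))
    arrows(v$x, v$y, v$x + scale * v$vx, v$y + scale * v$vy,
           length = 0.05, col = cols[ci])
  }
  invisible(v)
}
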