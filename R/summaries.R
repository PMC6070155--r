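#' Convert a velocity from px/frame to um/min
#'
#' @param v_px_per_frame velocity magnitude in px/frame.
#' @param pixel_size_um pixel size in um/px (> 0).
#' @param frame_interval_s frame interval in s (> 0).
#' @return Velocity in um/min: `v * pixel_size_um / frame_interval_s * 60`.
#' @examples
#' velocity_to_physical(1, 0.1, 0.2)  # 30 um/min
#' @export
velocity_to_physical <- function(v_px_per_frame, pixel_size_um,
                                 frame_interval_s) {
  if (pixel_size_um <= 0 || frame_interval_s <= 0)
    stop("calibration must be > 0")
  v_px_per_frame * pixel_size_um / frame_interval_s * 60
}

#' Per-cell microtubule dynamics summary
#'
#' Aggregates a cell's filtered STICCS vector fields and comet tracks into
#' the per-cell metrics reported per condition:
#' * `mt_speed_um_min` — mean speed of retained GFP autocorrelation
#'   vectors (microtubule movement);
#' * `assembly_speed_um_min` — mean speed of retained EB3 autocorrelation
#'   vectors (microtubule assembly);
#' * `n_growth_events` — number of retained EB3 autocorrelation vectors,
#'   averaged across TOIs;
#' * `cross_speed_um_min` — mean speed of retained cross-correlation
#'   vectors;
#' * `cross_fraction_pct` — cross-labelled EB3 vectors as a percentage of
#'   all retained EB3 vectors (the explorative-growth proportion; `NA`
#'   when the cell has no retained EB3 vectors);
#' * `track_*` — per-cell means of the comet-track growth metrics, plus
#'   the number of filtered tracks.
#'
#' @param field a [sticcs_vector_field()] result, similarity-filtered and
#'   (if the cross mode is present) passed through
#'   [classify_cross_events()].
#' @param tracking optional [track_cell()] result.
#' @param cell_id,condition identifiers carried into the summary row.
#' @return One-row data.frame (class `cell_summary`).
#' @export
per_cell_summary <- function(field, tracking = NULL, cell_id = "cell",
                             condition = "") {
  stopifnot(inherits(field, "vector_field"))
  v <- field$vectors
  ret <- v[v$retained, , drop = FALSE]
  msel <- function(m) ret[ret$mode == m, , drop = FALSE]
  gfp <- msel("gfp_auto"); eb3 <- msel("eb3_auto"); cro <- msel("cross")

  n_toi <- length(unique(field$grid$anchors$it))
  cross_frac <- NA_real_
  if (nrow(eb3) > 0 && "cross_correlated" %in% names(eb3))
    cross_frac <- 100 * sum(eb3$cross_correlated, na.rm = TRUE) / nrow(eb3)

  tm <- if (!is.null(tracking)) tracking$metrics else NULL
  out <- data.frame(
    cell_id = cell_id, condition = condition,
    mt_speed_um_min = if (nrow(gfp)) mean(gfp$speed_um_min) else NA_real_,
    assembly_speed_um_min = if (nrow(eb3)) mean(eb3$speed_um_min)
                            else NA_real_,
    n_growth_events = nrow(eb3) / n_toi,
    cross_speed_um_min = if (nrow(cro)) mean(cro$speed_um_min) else NA_real_,
    cross_fraction_pct = cross_frac,
    track_assembly_rate_um_min =
      if (!is.null(tm) && nrow(tm)) mean(tm$mean_speed_um_min) else NA_real_,
    track_growth_length_um =
      if (!is.null(tm) && nrow(tm)) mean(tm$path_length_um) else NA_real_,
    track_growth_duration_s =
      if (!is.null(tm) && nrow(tm)) mean(tm$duration_s) else NA_real_,
    track_n_events = if (!is.null(tm)) nrow(tm) else NA_integer_)
  class(out) <- c("cell_summary", class(out))
  out
}

#' Compare a per-cell metric between conditions
#'
#' Reports mean +/- SEM per condition and tests for a condition effect:
#' a two-sided t test for two groups, or a one-way ANOVA with
#' Dunnett-style pairwise comparisons against the reference condition for
#' more. A nonparametric switch substitutes Wilcoxon / Kruskal-Wallis
#' (with Holm-adjusted pairwise Wilcoxon tests against the reference).
#'
#' @param summaries data.frame of [per_cell_summary()] rows (one per cell).
#' @param metric name of the summary column to compare.
#' @param reference reference condition (default: first level in order of
#'   appearance).
#' @param nonparametric use rank-based tests (default FALSE).
#' @return List of class `group_result`: `metric`, `groups` (data.frame
#'   `condition`, `n`, `mean`, `sem`), `omnibus` (test name, statistic,
#'   p.value), `pairwise` (data.frame vs. reference with `estimate` and
#'   `p.value`).
#' @export
group_compare <- function(summaries, metric, reference = NULL,
                          nonparametric = FALSE) {
  if (!metric %in% names(summaries)) stop("unknown metric: ", metric)
  dat <- summaries[!is.na(summaries[[metric]]), , drop = FALSE]
  dat$condition <- factor(dat$condition,
                          levels = unique(summaries$condition))
  if (!is.null(reference))
    dat$condition <- stats::relevel(dat$condition, ref = reference)
  ns <- table(dat$condition)
  if (length(ns) < 2) stop("group_compare needs at least 2 conditions")
  if (any(ns < 3)) stop("each condition needs at least 3 cells")
  y <- dat[[metric]]

  groups <- do.call(rbind, lapply(levels(dat$condition), function(g) {
    yy <- y[dat$condition == g]
    data.frame(condition = g, n = length(yy), mean = mean(yy),
               sem = sd(yy) / sqrt(length(yy)))
  }))

  lv <- levels(dat$condition)
  if (length(lv) == 2) {
    if (nonparametric) {
      tst <- stats::wilcox.test(y ~ dat$condition, exact = FALSE)
      omni <- list(test = "wilcoxon", statistic = unname(tst$statistic),
                   p.value = tst$p.value)
    } else {
      tst <- t.test(y ~ dat$condition)
      omni <- list(test = "t", statistic = unname(tst$statistic),
                   p.value = tst$p.value)
    }
    pair <- data.frame(condition = lv[2],
                       estimate = groups$mean[2] - groups$mean[1],
                       p.value = omni$p.value)
  } else if (nonparametric) {
    kw <- stats::kruskal.test(y ~ dat$condition)
    omni <- list(test = "kruskal-wallis",
                 statistic = unname(kw$statistic), p.value = kw$p.value)
    pv <- vapply(lv[-1], function(g) {
      stats::wilcox.test(y[dat$condition == g],
                         y[dat$condition == lv[1]], exact = FALSE)$p.value
    }, numeric(1))
    pair <- data.frame(condition = lv[-1],
                       estimate = groups$mean[-1] - groups$mean[1],
                       p.value = p.adjust(pv, "holm"))
  } else {
    fit <- aov(y ~ condition, data = data.frame(y = y,
                                                condition = dat$condition))
    sm <- summary(fit)[[1]]
    omni <- list(test = "anova", statistic = sm[["F value"]][1],
                 p.value = sm[["Pr(>F)"]][1])
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
    sg <- summary(glt)
    pair <- data.frame(condition = lv[-1],
                       estimate = unname(sg$test$coefficients),
                       p.value = unname(sg$test$pvalues))
  }
  structure(list(metric = metric, groups = groups, omnibus = omni,
                 pairwise = pair, nonparametric = nonparametric),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("group_result for '%s' (%s test, P = %.3g)\n", x$metric,
              x$omnibus$test, x$omnibus$p.value))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %.3g +/- %.3g (n = %d)\n", x$groups$condition[i],
                x$groups$mean[i], x$groups$sem[i], x$groups$n[i]))
  invisible(x)
}

#' MCAK microtubule-depolymerisation activity index
#'
#' Quantifies MCAK-mediated depolymerisation from fixed-cell fluorescence:
#' the cell's integrated polymerised alpha-tubulin density is normalised
#' to the mean density of untransfected reference cells, and corrected for
#' MCAK expression level by the ratio of the control-group mean MCAK
#' intensity to the cell's MCAK intensity:
#' `index = (tubulin / mean(ref_tubulin)) * (control_mcak_mean / mcak)`.
#' A lower index means more depolymerisation.
#'
#' @param cell_tubulin_density integrated alpha-tubulin density of the
#'   MCAK-transfected cell (AU).
#' @param ref_tubulin_densities densities of untransfected reference cells.
#' @param cell_mcak_intensity the cell's mean MCAK fluorescence (> 0).
#' @param control_group_mcak_mean mean MCAK fluorescence of the control
#'   group (default 1: no expression correction).
#' @return The activity index (AU), vectorised over cells.
#' @export
mcak_activity_index <- function(cell_tubulin_density, ref_tubulin_densities,
                                cell_mcak_intensity,
                                control_group_mcak_mean = 1) {
  if (length(ref_tubulin_densities) == 0)
    stop("reference tubulin densities must be non-empty")
  if (any(cell_mcak_intensity <= 0))
    stop("MCAK intensity must be > 0")
  (cell_tubulin_density / mean(ref_tubulin_densities)) *
    (control_group_mcak_mean / cell_mcak_intensity)
}
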