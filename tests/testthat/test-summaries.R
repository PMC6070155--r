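test_that("velocity conversion follows the closed form", {
  expect_equal(velocity_to_physical(1, 0.1, 0.2), 30)
  expect_equal(velocity_to_physical(0, 0.1, 0.2), 0)
  expect_equal(velocity_to_physical(0.5, 0.2, 0.5), 12)
  expect_error(velocity_to_physical(1, 0, 0.2), "calibration")
})

make_field <- function(vecs, n_toi = 1) {
  grid <- tile_voxels(c(32, 32), 30 * n_toi,
                      toi_len_frames = 30, toi_shift_frames = 30)
  structure(list(vectors = vecs, grid = grid, pixel_size_um = 0.1,
                 frame_interval_s = 0.2), class = "vector_field")
}

test_that("per-cell summary counts and fractions are exact", {
  n <- 10
  vecs <- data.frame(
    mode = "eb3_auto", ix = 1:n, iy = 1, it = 1, x = 4 * (1:n), y = 4,
    t = 15, vx = 0.6667, vy = 0, speed_um_min = 20, quality = 1,
    peak_amplitude = 1, mean_gfp = 1, mean_eb3 = 1, retained = TRUE,
    cross_correlated = c(rep(TRUE, 3), rep(FALSE, 7)))
  s <- per_cell_summary(make_field(vecs))
  expect_equal(s$cross_fraction_pct, 30)
  expect_equal(s$assembly_speed_um_min, 20)
  expect_equal(s$n_growth_events, 10)

  # only retained vectors count; no EB3 vectors means undefined fraction
  vecs$retained <- FALSE
  s0 <- per_cell_summary(make_field(vecs))
  expect_true(is.na(s0$cross_fraction_pct))
  expect_equal(s0$n_growth_events, 0)
})

test_that("cross fraction is invariant to duplicating every vector", {
  n <- 8
  base <- data.frame(
    mode = "eb3_auto", ix = 1:n, iy = 1, it = 1, x = 4 * (1:n), y = 4,
    t = 15, vx = 1, vy = 0, speed_um_min = 30, quality = 1,
    peak_amplitude = 1, mean_gfp = 1, mean_eb3 = 1, retained = TRUE,
    cross_correlated = rep(c(TRUE, FALSE), each = 4))
  tripled <- do.call(rbind, list(base, base, base))
  tripled$iy <- rep(1:3, each = n)
  expect_equal(per_cell_summary(make_field(base))$cross_fraction_pct,
               per_cell_summary(make_field(tripled))$cross_fraction_pct)
})

test_that("events per TOI are averaged across TOIs", {
  two_toi <- data.frame(
    mode = "eb3_auto", ix = c(1:4, 1:2), iy = 1, it = c(rep(1, 4), 2, 2),
    x = 4, y = 4, t = 15, vx = 1, vy = 0, speed_um_min = 30, quality = 1,
    peak_amplitude = 1, mean_gfp = 1, mean_eb3 = 1, retained = TRUE,
    cross_correlated = FALSE)
  s <- per_cell_summary(make_field(two_toi, n_toi = 2))
  expect_equal(s$n_growth_events, 3)   # (4 + 2) / 2 TOIs
})

test_that("group comparison reports means, SEMs and sensible P values", {
  same <- data.frame(condition = rep(c("a", "b"), each = 4),
                     m = rep(c(1, 2, 3, 4), 2))
  g <- group_compare(same, "m")
  expect_equal(g$groups$mean, c(2.5, 2.5))
  expect_gt(g$omnibus$p.value, 0.99)
  expect_equal(g$groups$sem, rep(sd(1:4) / 2, 2))

  set.seed(41)
  far <- data.frame(condition = rep(c("lo", "hi"), each = 30),
                    m = c(rnorm(30, 20, 1), rnorm(30, 30, 1)))
  expect_lt(group_compare(far, "m")$omnibus$p.value, 1e-4)

  expect_equal(group_compare(same, "m")$groups$sem[1],
               sd(1:4) / sqrt(4))
  expect_error(group_compare(same[same$condition == "a", ], "m"),
               "2 conditions")
  expect_error(group_compare(same[c(1, 2, 5:8), ], "m"), "3 cells")
})

test_that("three-group comparison runs Dunnett contrasts vs the reference", {
  set.seed(42)
  dat <- data.frame(condition = rep(c("ref", "mid", "far"), each = 10),
                    m = c(rnorm(10, 10), rnorm(10, 11), rnorm(10, 16)))
  g <- group_compare(dat, "m", reference = "ref")
  expect_equal(g$omnibus$test, "anova")
  expect_equal(nrow(g$pairwise), 2)
  far_p <- g$pairwise$p.value[g$pairwise$condition == "far"]
  mid_p <- g$pairwise$p.value[g$pairwise$condition == "mid"]
  expect_lt(far_p, 0.001)
  expect_gt(mid_p, far_p)

  gn <- group_compare(dat, "m", reference = "ref", nonparametric = TRUE)
  expect_equal(gn$omnibus$test, "kruskal-wallis")
  expect_lt(gn$pairwise$p.value[gn$pairwise$condition == "far"], 0.01)
})

test_that("the MCAK activity index follows its normalisation", {
  expect_equal(mcak_activity_index(100, c(90, 110), 5, 5), 1)
  expect_equal(mcak_activity_index(50, c(90, 110), 5, 5), 0.5)
  expect_error(mcak_activity_index(100, numeric(), 5), "non-empty")
  expect_error(mcak_activity_index(100, 100, 0), "MCAK")

  # 40% depolymerisation with 2x spread in MCAK expression recovers 0.6
  set.seed(43)
  n <- 200
  mcak <- runif(n, 0.7, 1.4)
  ref <- rnorm(n, 100, 5)
  depol <- 0.6 * rnorm(n, 100, 5) * 1        # 40% loss of polymer
  idx <- mcak_activity_index(depol, ref, mcak, mean(mcak))
  expect_lt(abs(mean(idx) - 0.6), 3 * sd(idx) / sqrt(n) + 0.02)
})
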