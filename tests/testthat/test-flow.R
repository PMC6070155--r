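test_that("peak location recovers sub-pixel Gaussian centres", {
  cf <- synthetic_corr(list(`1` = c(1.5, -0.5, 1)))
  pk <- locate_peak(cf, 1)
  expect_true(pk$ok)
  expect_lt(abs(pk$xi - 1.5), 0.05)
  expect_lt(abs(pk$eta + 0.5), 0.05)

  # delta peak exactly on a grid point
  cfd <- synthetic_corr(list(`1` = c(3, 0, 1)), sigma = 0.35)
  pkd <- locate_peak(cfd, 1)
  expect_equal(pkd$xi, 3, tolerance = 0.02)
  expect_equal(pkd$eta, 0, tolerance = 0.02)

  # flat slice is flagged
  cf0 <- synthetic_corr(list(`1` = c(0, 0, 1)))
  expect_false(locate_peak(cf0, 5)$ok)
  expect_error(locate_peak(cf0, 99), "tau")
})

test_that("velocity fit recovers exact linear peak translation", {
  pk <- list(`0` = c(0, 0, 1))
  for (tau in 1:6) pk[[as.character(tau)]] <- c(0.5 * tau, 0, 1)
  fv <- fit_velocity(synthetic_corr(pk), tau_fit_range = 1:6)
  expect_true(fv$ok)
  expect_equal(fv$vx, 0.5, tolerance = 1e-6)
  expect_equal(fv$vy, 0, tolerance = 1e-6)
  expect_equal(fv$quality, 1, tolerance = 1e-9)
  # 0.5 px/frame at 0.1 um and 0.2 s is 15 um/min
  expect_equal(fv$speed_um_min, 15, tolerance = 1e-6)

  # peaks fixed at the origin give zero velocity
  pk0 <- list(`0` = c(0, 0, 1))
  for (tau in 1:6) pk0[[as.character(tau)]] <- c(0, 0, 1)
  fv0 <- fit_velocity(synthetic_corr(pk0), tau_fit_range = 1:6)
  expect_equal(fv0$vx, 0, tolerance = 1e-9)
  expect_equal(fv0$speed_um_min, 0, tolerance = 1e-9)

  # fewer than 3 usable lags yields no vector
  few <- synthetic_corr(list(`0` = c(0, 0, 1), `1` = c(0.5, 0, 1),
                             `2` = c(1, 0, 1)))
  expect_false(fit_velocity(few, tau_fit_range = 1:2)$ok)
})

test_that("uniform image translation is recovered by the full chain", {
  s <- translating_spot(48, 48, 40, v = c(0.8, 0.4), x0 = 10, y0 = 12)
  # add more texture so several voxels hold signal
  s2 <- translating_spot(48, 48, 40, v = c(0.8, 0.4), x0 = 30, y0 = 30)
  ser <- tiny_series(s$data + s2$data)
  f <- sticcs_vector_field(eb3 = ser, modes = "eb3_auto",
                           grid = tile_voxels(c(48, 48), 40,
                                              toi_len_frames = 40,
                                              toi_shift_frames = 40))
  v <- f$vectors[f$vectors$retained, ]
  expect_gt(nrow(v), 5)
  expect_lt(abs(median(v$vx) - 0.8), 0.05)
  expect_lt(abs(median(v$vy) - 0.4), 0.05)
})

test_that("similarity filter keeps coherent fields and rejects outliers", {
  grid <- tile_voxels(c(32, 32), 30)
  mkfield <- function(vecs) {
    structure(list(vectors = vecs, grid = grid, pixel_size_um = 0.1,
                   frame_interval_s = 0.2), class = "vector_field")
  }
  base <- expand.grid(ix = 1:5, iy = 1:5)
  uni <- data.frame(mode = "eb3_auto", ix = base$ix, iy = base$iy, it = 1,
                    x = 4 * base$ix, y = 4 * base$iy, t = 15,
                    vx = 0.5, vy = 0, speed_um_min = 15, quality = 1,
                    peak_amplitude = 1, mean_gfp = 1, mean_eb3 = 1,
                    retained = TRUE)
  out <- similarity_filter(mkfield(uni))
  expect_true(all(out$vectors$retained))

  anti <- uni
  anti$vx[13] <- -0.5          # one antiparallel vector mid-field
  out2 <- similarity_filter(mkfield(anti))
  expect_false(out2$vectors$retained[13])
  expect_true(all(out2$vectors$retained[-13]))
})

test_that("isotropic random vector fields are mostly rejected", {
  set.seed(21)
  grid <- tile_voxels(c(140, 140), 30)
  base <- expand.grid(ix = 1:20, iy = 1:20)
  n <- nrow(base)
  th <- runif(n, 0, 2 * pi)
  sp <- runif(n, 0.1, 1.5)
  rnd <- data.frame(mode = "eb3_auto", ix = base$ix, iy = base$iy, it = 1,
                    x = 4 * base$ix, y = 4 * base$iy, t = 15,
                    vx = sp * cos(th), vy = sp * sin(th),
                    speed_um_min = sp * 30, quality = 1,
                    peak_amplitude = 1, mean_gfp = 1, mean_eb3 = 1,
                    retained = TRUE)
  f <- structure(list(vectors = rnd, grid = grid, pixel_size_um = 0.1,
                      frame_interval_s = 0.2), class = "vector_field")
  out <- similarity_filter(f)
  expect_lt(mean(out$vectors$retained), 0.35)
})

test_that("cross classification labels per-voxel matches and respects coupling", {
  grid <- tile_voxels(c(32, 32), 30)
  vecs <- data.frame(
    mode = c("eb3_auto", "eb3_auto", "cross"),
    ix = c(2, 4, 2), iy = c(2, 4, 2), it = 1,
    x = c(8, 16, 8), y = c(8, 16, 8), t = 15,
    vx = c(0.5, 0.5, 0.45), vy = 0,
    speed_um_min = c(15, 15, 13.5), quality = 1,
    peak_amplitude = c(1, 1, 0.5), mean_gfp = 0.5, mean_eb3 = 0.5,
    retained = TRUE)
  f <- structure(list(vectors = vecs, grid = grid, pixel_size_um = 0.1,
                      frame_interval_s = 0.2), class = "vector_field")
  out <- classify_cross_events(f)
  lab <- out$vectors$cross_correlated
  expect_true(lab[1])          # matching cross vector in the same voxel
  expect_false(lab[2])         # no cross vector anywhere nearby
  expect_true(is.na(lab[3]))   # labels only EB3 vectors

  # non-retained EB3 vectors are never labelled (cross-auto coupling)
  vecs$retained[1] <- FALSE
  f2 <- structure(list(vectors = vecs, grid = grid, pixel_size_um = 0.1,
                       frame_interval_s = 0.2), class = "vector_field")
  expect_true(is.na(classify_cross_events(f2)$vectors$cross_correlated[1]))

  # mismatched grids are rejected when passed as two fields
  other <- structure(list(vectors = vecs[vecs$mode == "cross", ],
                          grid = tile_voxels(c(48, 48), 30),
                          pixel_size_um = 0.1, frame_interval_s = 0.2),
                     class = "vector_field")
  expect_error(classify_cross_events(f, other), "different grids")
})
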