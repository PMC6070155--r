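test_that("photobleaching correction is identity on flat series and undoes decay", {
  flat <- tiny_series(array(5, c(8, 8, 20)))
  out <- correct_photobleaching(flat)
  expect_equal(out$data, flat$data, tolerance = 1e-9)

  set.seed(1)
  base <- array(runif(8 * 8, 1, 2), c(8, 8, 50))
  dec <- sweep(base, 3, exp(-(0:49) / 50), "*")
  corr <- correct_photobleaching(tiny_series(dec))
  m <- apply(corr$data, 3, mean)
  expect_lt(max(abs(m / m[1] - 1)), 0.01)

  expect_error(correct_photobleaching(tiny_series(array(1, c(4, 4, 3)))),
               "5 frames")
})

test_that("background subtraction removes offsets but keeps spots", {
  img <- array(2, c(48, 48, 3))              # flat offset
  spot <- matrix(0, 48, 48)
  spot[24, 24] <- 5
  spot <- EBImage::gblur(spot, 1.5)
  for (t in 1:3) img[, , t] <- img[, , t] + spot
  out <- subtract_background_and_denoise(tiny_series(img),
                                         bg_radius_px = 20,
                                         denoise_sigma_px = 0)
  expect_lt(median(out$data[, , 1]), 0.05)   # offset removed
  expect_gt(max(out$data[24 + (-1:1), 24 + (-1:1), 1]),
            0.8 * max(spot))                 # peak preserved within 20%
  expect_error(subtract_background_and_denoise(tiny_series(img), -1),
               "bg_radius_px")

  zero <- subtract_background_and_denoise(
    tiny_series(array(0, c(32, 32, 3))), 10, 0.5)
  expect_true(all(zero$data == 0))
})

test_that("immobile filter removes static structure and zeroes pixel means", {
  set.seed(2)
  static <- array(rep(matrix(runif(256, 1, 3), 16), 20), c(16, 16, 20))
  filt <- immobile_filter(tiny_series(static))
  expect_lt(sum(filt$data^2), 1e-6 * sum((static - mean(static))^2) + 1e-12)

  noisy <- random_series(16, 16, 30, seed = 3)
  f1 <- immobile_filter(noisy, 1)
  pixel_means <- apply(f1$data, c(1, 2), mean)
  expect_lt(max(abs(pixel_means)), 1e-9 * max(noisy$data))

  expect_error(immobile_filter(noisy, 0), "n_low_freq")
  expect_error(immobile_filter(noisy, 15), "n_low_freq")
})

test_that("immobile filter is linear and idempotent", {
  a <- random_series(12, 12, 24, seed = 4)
  b <- random_series(12, 12, 24, seed = 5)
  lin <- immobile_filter(tiny_series(2 * a$data + 3 * b$data), 2)
  sep <- 2 * immobile_filter(a, 2)$data + 3 * immobile_filter(b, 2)$data
  expect_equal(lin$data, sep, tolerance = 1e-10)

  once <- immobile_filter(a, 2)
  twice <- immobile_filter(once, 2)
  expect_equal(twice$data, once$data, tolerance = 1e-10)
})

test_that("immobile filter preserves a moving spot's displacement signal", {
  sp <- translating_spot(32, 32, 30, v = c(1, 0))
  static <- array(rep(matrix(2, 32, 32), 30), c(32, 32, 30))
  mixed <- tiny_series(sp$data + static)
  filt <- immobile_filter(mixed)
  cf <- correlation_function(filt, filt, c(9, 9, 1), tau_max = 5)
  pk <- locate_peak(cf, 3)
  expect_true(pk$ok)
  expect_lt(abs(pk$xi - 3), 0.5)   # peak still tracks the 1 px/frame motion
})
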