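test_that("FFT correlation equals the direct-sum definition", {
  for (seed in 1:5) {
    a <- random_series(16, 16, 30, seed = seed)
    b <- random_series(16, 16, 30, seed = seed + 100)
    cf <- correlation_function(a, b, c(1, 1, 1), tau_max = 5)
    ro <- direct_sum_corr(a$data, b$data, 5)
    expect_lt(max(abs(cf$r - ro)), 1e-10)
  }
})

test_that("a pure spatial shift puts the zero-lag peak at the shift", {
  a <- random_series(16, 16, 10, seed = 9)
  shifted <- a$data * 0
  shifted[, 3:16, ] <- a$data[, 1:14, ]      # b(x+2) = a(x)
  b <- tiny_series(shifted)
  cf <- correlation_function(a, b, c(1, 1, 1), toi_len_frames = 10,
                             tau_max = 2)
  slice <- cf$r[, , match(0, cf$tau)]
  amx <- which(slice == max(slice), arr.ind = TRUE)[1, ]
  expect_equal(cf$xi[amx[2]], 2)
  expect_equal(cf$eta[amx[1]], 0)
})

test_that("degenerate voxels are flagged, autocorrelation is symmetric", {
  const <- tiny_series(array(3, c(16, 16, 30)))
  cf <- correlation_function(const, const, c(1, 1, 1))
  expect_false(cf$valid)
  expect_true(all(cf$r == 0))

  a <- random_series(16, 16, 30, seed = 11)
  auto <- correlation_function(a, a, c(1, 1, 1), tau_max = 3)
  s0 <- auto$r[, , match(0, auto$tau)]
  expect_equal(unname(s0),
               unname(s0[rev(seq_len(nrow(s0))), rev(seq_len(ncol(s0)))]),
               tolerance = 1e-12)
  # zero-lag maximum of an autocorrelation sits at zero lag
  amx <- which(s0 == max(s0), arr.ind = TRUE)[1, ]
  expect_equal(auto$eta[amx[1]], 0)
  expect_equal(auto$xi[amx[2]], 0)

  expect_error(correlation_function(a, a, c(60, 1, 1)), "outside")
  expect_error(correlation_function(a, a, c(1, 1, 1), tau_max = 40),
               "tau_max")
})

test_that("normalisation falls back to SDs for zero-mean series", {
  a <- random_series(16, 16, 30, seed = 12)
  za <- immobile_filter(a)    # per-pixel temporal means are ~0
  cf <- correlation_function(za, za, c(1, 1, 1))
  expect_equal(cf$normalization, "sd")
  expect_true(cf$valid)
})
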