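test_that("simulation is deterministic and validates its parameters", {
  expect_error(sim_params(image_shape = c(16, 64)), "32 px")
  expect_error(sim_params(explorative_fraction = 1.5), "explorative_fraction")
  expect_error(sim_params(growth_speed_mean = -1), "growth_speed_mean")
  expect_error(build_fiber_map(sim_params(n_fibers = 0)), "fiber")

  p <- sim_params(n_events = 10, seed = 1)
  s1 <- simulate_cell(p)
  s2 <- simulate_cell(p)
  expect_identical(s1$gfp$data, s2$gfp$data)
  expect_identical(s1$eb3$data, s2$eb3$data)
  expect_identical(s1$truth, s2$truth)
})

test_that("fiber map vertices lie inside the cell mask", {
  p <- sim_params(image_shape = c(256, 256), n_fibers = 20, seed = 1)
  fm <- build_fiber_map(p)
  expect_length(fm$fibers, 20)
  for (pts in fm$fibers) {
    ij <- cbind(pmin(pmax(round(pts[, 2]), 1), 256),
                pmin(pmax(round(pts[, 1]), 1), 256))
    expect_true(all(fm$cell_mask[ij]))
  }
})

test_that("explorative flags follow the requested fraction", {
  p0 <- sim_params(explorative_fraction = 0, n_events = 40, seed = 2)
  fm <- build_fiber_map(p0)
  ev0 <- sample_growth_events(fm, p0)
  expect_true(all(!vapply(ev0, `[[`, logical(1), "explorative")))

  p1 <- sim_params(explorative_fraction = 1, n_events = 40, seed = 2)
  ev1 <- sample_growth_events(build_fiber_map(p1), p1)
  expect_true(all(vapply(ev1, `[[`, logical(1), "explorative")))

  # binomial sampling check at f = 0.5 over a large event sample
  p <- sim_params(explorative_fraction = 0.5, n_events = 2000,
                  catastrophe_prob = 0.2, seed = 3)
  ev <- sample_growth_events(build_fiber_map(p), p)
  frac <- mean(vapply(ev, `[[`, logical(1), "explorative"))
  expect_gt(length(ev), 1000)
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("event trajectories are monotone in time and inside the cell", {
  p <- sim_params(n_events = 30, seed = 4)
  fm <- build_fiber_map(p)
  for (ev in sample_growth_events(fm, p)) {
    expect_true(all(diff(ev$trajectory$t) == 1))
    expect_gte(nrow(ev$trajectory), p$min_duration_frames)
    ij <- cbind(pmin(pmax(round(ev$trajectory$y), 1), 64),
                pmin(pmax(round(ev$trajectory$x), 1), 64))
    expect_true(all(fm$cell_mask[ij]))
  }
})

test_that("noiseless static render repeats frames; bleaching decays means", {
  p <- sim_params(n_events = 0, photon_scale = Inf, bleach_rate = 0,
                  n_frames = 10, seed = 5)
  mv <- render_movie(build_fiber_map(p), list(), p)
  for (t in 2:10)
    expect_equal(mv$gfp$data[, , t], mv$gfp$data[, , 1], tolerance = 1e-12)

  pb <- sim_params(n_events = 0, bleach_rate = 0.02, n_frames = 100, seed = 5)
  mvb <- render_movie(build_fiber_map(pb), list(), pb)
  m <- apply(mvb$gfp$data, 3, mean)
  expect_lt(abs(m[100] / m[1] - exp(-0.02 * 99)) / exp(-0.02 * 99), 0.1)
})

test_that("comet displacement follows the unit arithmetic", {
  # 30 um/min at 0.1 um/px and 0.2 s/frame is 1 px/frame
  p <- sim_params(growth_speed_mean = 30, growth_speed_sd = 1e-9,
                  explorative_fraction = 1, n_events = 5,
                  catastrophe_prob = 0, seed = 6)
  ev <- sample_growth_events(build_fiber_map(p), p)
  for (e in ev) {
    step <- sqrt(diff(e$trajectory$x)^2 + diff(e$trajectory$y)^2)
    expect_equal(step, rep(1, length(step)), tolerance = 1e-6)
  }
})

test_that("EB3 comets stay on the GFP growth trace (co-registration)", {
  p <- sim_params(n_events = 6, photon_scale = Inf, read_noise = 0,
                  static_bg_amplitude = 0, bleach_rate = 0, seed = 7)
  sim <- simulate_cell(p)
  for (ev in sim$events) {
    tr <- ev$trajectory
    for (k in c(1, nrow(tr))) {
      fr <- sim$eb3$data[, , tr$t[k]]
      # brightest EB3 pixel within 3 px of the tip must be within 1 px
      i0 <- pmin(pmax(round(tr$y[k]) + (-3:3), 1), 64)
      j0 <- pmin(pmax(round(tr$x[k]) + (-3:3), 1), 64)
      sub <- fr[i0, j0]
      amx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      expect_lt(sqrt((i0[amx[1]] - tr$y[k])^2 + (j0[amx[2]] - tr$x[k])^2),
                1 + 1e-9)
    }
  }
})

test_that("ground truth reports exact counts, fractions and means", {
  fake <- function(speed, expl) {
    structure(list(trajectory = data.frame(t = 1:3, x = 1:3, y = 1:3),
                   speed_um_min = speed, explorative = expl,
                   parent_fiber = NA), class = "growth_event")
  }
  ev <- c(lapply(1:7, function(i) fake(20, FALSE)),
          lapply(1:3, function(i) fake(20, TRUE)))
  gt <- ground_truth(ev, sim_params())
  expect_equal(gt$true_event_count, 10)
  expect_equal(gt$true_explorative_fraction, 0.3)
  expect_equal(gt$true_mean_speed_um_min, 20)

  speeds <- c(5, 10, 40)
  ev2 <- lapply(speeds, function(s) fake(s, FALSE))
  expect_equal(ground_truth(ev2, sim_params())$true_mean_speed_um_min,
               mean(speeds))
})

test_that("written simulations round-trip through TIFF and CSV", {
  dir <- tempfile("simout")
  p <- sim_params(n_events = 5, n_frames = 12, seed = 8)
  sim <- simulate_cell(p)
  write_simulation(sim, p, dir, "cellA")
  back <- read_movie(file.path(dir, "cellA_gfp.tif"))
  expect_equal(back$pixel_size_um, 0.1)
  expect_equal(dim(back$data), dim(sim$gfp$data))
  truth <- read.csv(file.path(dir, "cellA_truth.csv"))
  expect_equal(length(unique(truth$event)), 5)
  prm <- jsonlite::read_json(file.path(dir, "cellA_params.json"))
  expect_equal(prm$n_frames, 12)
  unlink(dir, recursive = TRUE)
})
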