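test_that("the assignment solver matches brute force on small instances", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    a <- solve_lap(cost)
    expect_equal(sort(a), 1:n)
    got <- sum(cost[cbind(1:n, a)])
    perms <- NULL
    best <- Inf
    for (p in asplit(as.matrix(expand.grid(rep(list(1:n), n))), 1)) {
      if (length(unique(p)) < n) next
      best <- min(best, sum(cost[cbind(1:n, p)]))
    }
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("capped matching equals the exhaustive matching oracle", {
  set.seed(32)
  for (rep in 1:100) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x1 <- runif(n1, 0, 10); y1 <- runif(n1, 0, 10)
    x2 <- runif(n2, 0, 10); y2 <- runif(n2, 0, 10)
    cap <- runif(1, 1, 5)
    m <- match_points(x1, y1, x2, y2, cap)
    expect_equal(assignment_cost(x1, y1, x2, y2, m, cap),
                 brute_force_match_cost(x1, y1, x2, y2, cap),
                 tolerance = 1e-9)
  }
})

test_that("a single moving particle yields one track; gaps close on request", {
  det <- data.frame(t = 1:10, x = 1:10, y = 5, quality = 1)
  tr <- link_tracks(det, max_link_px = 3)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 10)

  gap <- det[det$t != 5, ]
  expect_length(link_tracks(gap, max_link_px = 3, max_gap_frames = 2), 1)
  expect_length(link_tracks(gap, max_link_px = 3, max_gap_frames = 0), 2)
})

test_that("no detection is used by two tracks", {
  set.seed(33)
  det <- data.frame(t = rep(1:12, each = 5),
                    x = runif(60, 1, 30), y = runif(60, 1, 30),
                    quality = 1)
  tracks <- link_tracks(det, max_link_px = 4)
  used <- do.call(rbind, tracks)
  expect_equal(nrow(used), nrow(unique(used[, c("t", "x", "y")])))
  expect_lte(nrow(used), nrow(det))
})

test_that("track metrics follow the stated arithmetic", {
  tr <- data.frame(t = 1:5, x = 1:5, y = 2, quality = 1)
  m <- track_metrics(tr, pixel_size_um = 0.1, frame_interval_s = 0.2)
  expect_equal(m$mean_speed_um_min, 30)         # 1 px/frame straight
  expect_equal(m$mean_link_speed_um_min, 30)
  expect_equal(m$path_length_um, 0.4)
  expect_equal(m$duration_s, 0.8)
  expect_equal(m$net_displacement_um, 0.4)

  still <- data.frame(t = 1:4, x = 2, y = 2, quality = 1)
  expect_equal(track_metrics(still, 0.1, 0.2)$mean_speed_um_min, 0)
  expect_error(track_metrics(still[1, , drop = FALSE], 0.1, 0.2),
               "2 detections")
})

test_that("track filters keep exactly the qualifying tracks", {
  mk <- function(n, step, q) {
    data.frame(t = seq_len(n), x = cumsum(rep(step, n)), y = 1, quality = q)
  }
  tracks <- list(mk(10, 1, 1),      # long, fast, good
                 mk(10, 0.05, 1),   # short displacement
                 mk(2, 1, 1),       # too few frames
                 mk(10, 1, 0.1),    # low quality
                 mk(6, 0.5, 0.8))
  out <- filter_tracks(tracks, 0.1, 0.2, min_quality = 0.5,
                       min_displacement_um = 0.2, min_frames = 3)
  expect_length(out, 2)
  ident <- filter_tracks(tracks[c(1, 2, 4, 5)], 0.1, 0.2,
                         min_quality = 0, min_displacement_um = 0,
                         min_frames = 0)
  expect_length(ident, 4)
})

test_that("LoG detection finds separated spots with sub-pixel accuracy", {
  mk_spot <- function(img, x, y, amp = 1, sigma = 1.5) {
    img + amp * outer(exp(-((1:nrow(img)) - y)^2 / (2 * sigma^2)),
                      exp(-((1:ncol(img)) - x)^2 / (2 * sigma^2)))
  }
  img <- mk_spot(mk_spot(matrix(0, 48, 48), 12, 12), 32, 36)
  det <- detect_comets(img, 1.5, quality_min = 0.1)
  expect_equal(nrow(det), 2)

  set.seed(34)
  one <- mk_spot(matrix(0, 48, 48), 20.3, 11.7)
  noisy <- one + matrix(rnorm(48 * 48, 0, 0.1), 48)   # SNR ~ 10
  d <- detect_comets(noisy, 1.5, quality_min = 0.1)
  i <- which.min((d$x - 20.3)^2 + (d$y - 11.7)^2)
  expect_lt(sqrt((d$x[i] - 20.3)^2 + (d$y[i] - 11.7)^2), 0.5)
})

test_that("pure noise rarely produces detections at the default threshold", {
  set.seed(35)
  false_pos <- 0
  for (t in 1:60) {
    fr <- matrix((rpois(64 * 64, 0.3 * 100) +
                    rnorm(64 * 64, 0, 2)) / 100, 64)
    fr <- fr - median(fr)
    false_pos <- false_pos + nrow(detect_comets(fr, 1.5))
  }
  expect_lt(false_pos / 60, 0.5)
})
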