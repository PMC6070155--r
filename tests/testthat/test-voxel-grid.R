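test_that("voxel tiling matches the stated anchor rules", {
  g <- tile_voxels(c(32, 32), 30)
  expect_equal(nrow(g$anchors), 25)          # 5 x 5 anchors, 1 TOI
  expect_equal(sort(unique(g$anchors$x0)), c(1, 5, 9, 13, 17))

  g2 <- tile_voxels(c(64, 64), 100)
  expect_equal(sort(unique(g2$anchors$x0)), seq(1, 49, by = 4))
  expect_equal(sort(unique(g2$anchors$t0)), c(1, 16, 31, 46, 61, 71))
  expect_equal(nrow(g2$anchors), 13 * 13 * 6)  # 1014 voxels
})

test_that("tiling validates sizes and respects the mask", {
  expect_error(tile_voxels(c(12, 12), 30), "roi_size")
  expect_error(tile_voxels(c(64, 64), 20), "toi_len")

  m <- matrix(FALSE, 64, 64)
  m[1:20, 1:20] <- TRUE
  g <- tile_voxels(c(64, 64), 30, mask = cell_mask(m))
  expect_true(all(g$anchors$x0 <= 16 & g$anchors$y0 <= 16))

  m2 <- matrix(FALSE, 64, 64)
  m2[1, 1] <- TRUE   # < 50% coverage everywhere
  expect_warning(g0 <- tile_voxels(c(64, 64), 30, mask = cell_mask(m2)),
                 "empty")
  expect_equal(nrow(g0$anchors), 0)
})
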