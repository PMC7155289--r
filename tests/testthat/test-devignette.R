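test_that("average projection is the pixelwise mean", {
  t1 <- fix_texture_scene()[1:16, 1:16]
  expect_identical(average_projection(list(t1)), t1)
  expect_equal(average_projection(list(t1, 2 - t1)), matrix(1, 16, 16))
  expect_error(average_projection(list()), "at least one")
  expect_error(average_projection(list(t1, t1[1:8, 1:8])), "mismatch")
})

test_that("border limited mean matches a brute-force clipped-window mean", {
  ramp <- matrix(seq_len(25), 5, 5)
  blm <- border_limited_mean(ramp, 1)
  # brute force at a corner: only the 4 in-bounds neighbours + self
  expect_equal(blm[1, 1], mean(ramp[1:2, 1:2]))
  expect_equal(blm[5, 5], mean(ramp[4:5, 4:5]))
  expect_equal(blm[3, 3], mean(ramp[2:4, 2:4]))
  # full brute-force oracle on a random image, several radii
  img <- fix_texture_scene()[1:11, 1:13]
  for (r in c(0, 1, 3, 20)) {
    got <- border_limited_mean(img, r)
    want <- img * 0
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
      want[i, j] <- mean(img[max(1, i - r):min(nrow(img), i + r),
                             max(1, j - r):min(ncol(img), j + r)])
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("border limited mean never brightens edges of a constant image", {
  for (r in c(0, 1, 5, 50))
    expect_equal(border_limited_mean(matrix(4.2, 20, 20), r),
                 matrix(4.2, 20, 20))
})

test_that("vignette profile is recovered from constant-scene tiles", {
  # at the camera-tile scale (2048 px, blur radius 200) the estimate is
  # dominated only by the filter's own smoothing bias; run scaled by 1/2
  v <- make_vignette(1024, 0.4)
  pr <- estimate_vignette(list(v * 7), 100)
  expect_equal(mean(pr$profile), 1, tolerance = 1e-12)
  expect_lt(rel_rms(pr$profile, v / mean(v)), 0.02)
  # single constant tile -> profile of ones
  expect_equal(estimate_vignette(list(matrix(2, 64, 64)), 10)$profile,
               matrix(1, 64, 64))
})

test_that("flat-field recovery on many textured tiles", {
  # low-contrast dense texture so 121 tiles average to a clean projection
  scene <- make_scene("texture", 1300, seed = 21, contrast = 0.05)
  tile <- 96
  vig <- make_vignette(tile, 0.4)
  pos <- expand.grid(y = seq(0, by = tile, length.out = 13),
                     x = seq(0, by = tile, length.out = 13))
  tiles <- lapply(seq_len(nrow(pos)), function(i)
    scene[pos$y[i] + 1:tile, pos$x[i] + 1:tile] * vig)
  pr <- estimate_vignette(tiles, 3)
  expect_lt(rel_rms(pr$profile, vig / mean(vig)), 0.02)
  corr <- lapply(tiles, apply_devignette, profile = pr)
  # correction preserves the overall mean within 1%
  expect_lt(abs(mean(average_projection(corr)) /
                  mean(average_projection(tiles)) - 1), 0.01)
  # corrected projection is spatially uniform
  proj <- average_projection(corr)
  expect_lt((max(proj) - min(proj)) / mean(proj), 0.05)
  expect_gt(cv(average_projection(tiles)) / cv(proj), 10)
})

test_that("devignetting by a known profile is an exact inverse", {
  v <- make_vignette(32, 0.3)
  flat <- matrix(5, 32, 32)
  tile <- v * flat
  out <- apply_devignette(tile, v / mean(v))
  expect_equal(out / mean(out), flat / mean(flat), tolerance = 1e-12)
  expect_identical(apply_devignette(tile, matrix(1, 32, 32)), tile)
  expect_error(apply_devignette(tile, matrix(1, 16, 16)), "mismatch")
})

test_that("bright-field empty-field correction follows the additive rule", {
  empty <- array(200, c(8, 8, 3)); tile <- array(150, c(8, 8, 3))
  # tile == empty maps to uniform white
  expect_equal(devignette_brightfield(empty, empty, 255),
               array(255, c(8, 8, 3)))
  # empty at white level: no correction
  white <- array(255, c(8, 8, 3))
  expect_equal(devignette_brightfield(tile, white, 255), tile)
  # corner falloff 30, tile 100 -> 130
  empty2 <- array(255, c(4, 4, 3)); empty2[1, 1, ] <- 225
  tile2 <- array(90, c(4, 4, 3)); tile2[1, 1, ] <- 100
  out <- devignette_brightfield(tile2, empty2, 255)
  expect_equal(out[1, 1, 1], 130)
  expect_error(devignette_brightfield(tile2, empty2[, , 1:2]), "shape")
})
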