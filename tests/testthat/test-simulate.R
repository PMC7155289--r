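test_that("identity forward model: no PSF, no vignette, all-on pattern", {
  scene <- fix_texture_scene()
  layout <- make_mosaic_layout(2, 2, 32, 0.2, origin = c(3, 7))
  truth <- scene_truth(scene, psf_sigma_px = 0, seed = 1)
  stacks <- simulate_mosaic(truth, layout, make_uniform_pattern(32, 2))
  for (s in stacks) {
    off <- layout$offsets[(s$position[1] - 1) * layout$cols + s$position[2], ]
    crop <- scene[off[1] + 1:32, off[2] + 1:32]
    expect_equal(s$data[, , 1], crop)
    expect_equal(s$data[, , 2], crop)
  }
})

test_that("noise-free phase average equals duty x vignette x blurred crop", {
  fx <- fix_noiseless_mosaic()
  # oracle RHS via the trivially-correct all-on path (duty-1 pattern,
  # no vignette), which reduces the forward model to plain blurred crops
  truth_plain <- scene_truth(fx$scene, psf_sigma_px = 1.5, seed = 5)
  plain <- simulate_mosaic(truth_plain, fx$layout,
                           make_uniform_pattern(64, 1))
  for (i in seq_along(fx$stacks)) {
    lhs <- reconstruct_widefield(fx$stacks[[i]])
    rhs <- fx$pattern$duty * fx$vig * plain[[i]]$data[, , 1]
    expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
  }
})

test_that("seeded mosaics are bit-identical on repeat runs", {
  scene <- fix_texture_scene()
  layout <- make_mosaic_layout(2, 2, 32, 0.2)
  truth <- scene_truth(scene, 1, make_vignette(32, 0.3),
                       poisson_scale = 100, read_noise_sd = 0.02, seed = 9)
  pat <- make_line_patterns(32, 4, 4)
  s1 <- simulate_mosaic(truth, layout, pat)
  s2 <- simulate_mosaic(truth, layout, pat)
  expect_identical(lapply(s1, `[[`, "data"), lapply(s2, `[[`, "data"))
  expect_true(all(vapply(s1, function(s) all(s$data >= 0), logical(1))))
})

test_that("layouts exceeding the scene are rejected", {
  truth <- scene_truth(matrix(1, 100, 100), seed = 1)
  layout <- make_mosaic_layout(3, 3, 64, 0.2)
  expect_error(simulate_mosaic(truth, layout, make_uniform_pattern(64, 1)),
               "bounds")
})

test_that("layout offsets step by round(l(1-r)) and cover the grid hull", {
  lay <- make_mosaic_layout(3, 4, 64, 0.2)
  expect_equal(lay$step, round(64 * 0.8))
  # adjacent offsets step by exactly `step` along both axes
  expect_true(all(diff(lay$offsets[1:lay$cols, 2]) == lay$step))
  expect_true(all(diff(lay$offsets[seq(1, lay$rows * lay$cols,
                                       by = lay$cols), 1]) == lay$step))
  # coverage: every scene pixel in the hull is inside >= 1 tile
  span_y <- (lay$rows - 1) * lay$step + 64
  span_x <- (lay$cols - 1) * lay$step + 64
  cov <- matrix(0L, span_y, span_x)
  for (t in seq_len(nrow(lay$offsets))) {
    o <- lay$offsets[t, ]
    cov[o[1] + 1:64, o[2] + 1:64] <- cov[o[1] + 1:64, o[2] + 1:64] + 1L
  }
  expect_true(all(cov >= 1))
})

test_that("gaussian blur preserves constants and total intensity", {
  img <- fix_texture_scene()[1:64, 1:64]
  b <- gaussian_blur(img, 2)
  expect_equal(mean(b), mean(img), tolerance = 1e-12)
  expect_equal(gaussian_blur(matrix(3, 16, 16), 5), matrix(3, 16, 16))
  expect_lt(stats::sd(b), stats::sd(img))
})
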