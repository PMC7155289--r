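test_that("phase correlation recovers circular shifts to sub-pixel accuracy", {
  a <- fix_texture_scene()[1:64, 1:64]
  expect_equal(as.numeric(phase_correlate(a, a)), c(0, 0), tolerance = 1e-9)
  cs <- function(x, dy, dx)
    x[((seq_len(nrow(x)) - 1 - dy) %% nrow(x)) + 1,
      ((seq_len(ncol(x)) - 1 - dx) %% ncol(x)) + 1]
  for (s in list(c(3, -2), c(0, 5), c(-7, -1))) {
    est <- phase_correlate(a, cs(a, s[1], s[2]))
    expect_equal(as.numeric(est), s, tolerance = 0.05)
  }
  # antisymmetry on a non-circular (cropped) pair
  b <- fix_texture_scene()[3:66, 4:67]
  expect_equal(as.numeric(phase_correlate(a, b)) +
                 as.numeric(phase_correlate(b, a)), c(0, 0),
               tolerance = 0.1)
  expect_error(phase_correlate(a, matrix(1, 64, 64)), "variance")
})

test_that("a 1x1 grid stitches to the single tile", {
  tile <- fix_texture_scene()[1:32, 1:32]
  lay <- make_mosaic_layout(1, 1, 32, 0.2)
  for (bl in c("feather", "average", "overwrite"))
    expect_equal(stitch_grid(list(tile), lay, blend = bl)$mosaic, tile)
})

test_that("consistent tiles stitch to the exact scene crop in every blend", {
  scene <- fix_texture_scene()
  lay <- make_mosaic_layout(3, 3, 64, 0.2, origin = c(5, 5))
  truth <- scene_truth(scene, 0, NULL, seed = 3)
  stacks <- simulate_mosaic(truth, lay, make_uniform_pattern(64, 1))
  tiles <- lapply(stacks, reconstruct_widefield)
  oracle <- scene_crop(scene, lay)
  for (bl in c("feather", "average", "overwrite")) {
    sr <- stitch_grid(tiles, lay, blend = bl)
    expect_equal(sr$mosaic, oracle, tolerance = 1e-12,
                 info = paste("blend", bl))
  }
  # mosaic dimensions: (R-1) s + l per axis
  expect_equal(dim(stitch_grid(tiles, lay)$mosaic),
               c(2 * lay$step + 64, 2 * lay$step + 64))
})

test_that("injected integer jitter is recovered exactly by refinement", {
  scene <- fix_texture_scene()
  lay <- make_mosaic_layout(3, 3, 64, 0.2, origin = c(10, 10))
  for (sd_ in c(1, 4)) {
    layj <- jitter_layout(lay, 3, seed = sd_)
    truth <- scene_truth(scene, 1.5, NULL, poisson_scale = 500,
                         read_noise_sd = 0.005, seed = 3)
    stacks <- simulate_mosaic(truth, layj, make_line_patterns(64, 5, 5))
    sr <- stitch_grid(lapply(stacks, reconstruct_widefield), layj,
                      refine = TRUE)
    expect_identical(sr$refinement_shifts, layj$jitter + 0)
    expect_true(all(abs(sr$refinement_shifts) <= 0.1 * 64))
  }
})

test_that("tile count mismatches are rejected", {
  lay <- make_mosaic_layout(2, 2, 16, 0.2)
  expect_error(stitch_grid(list(matrix(1, 16, 16)), lay), "expected 4")
})
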