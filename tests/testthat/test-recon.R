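test_that("wide-field reconstruction is the exact arithmetic mean", {
  a <- array(0, c(2, 2, 2))
  a[, , 1] <- matrix(c(0, 2, 2, 0), 2, 2)
  a[, , 2] <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_equal(reconstruct_widefield(a), matrix(1, 2, 2))
  # idempotent on identical slices, machine precision for any N
  img <- fix_texture_scene()[1:16, 1:16]
  for (N in c(1, 3, 5, 8)) {
    st <- array(rep(img, N), c(16, 16, N))
    expect_identical(reconstruct_widefield(st), img)
  }
})

test_that("OS-SIM demodulation recovers the modulation amplitude", {
  # closed-form oracle: I_n = c + a cos(2 pi n / N) has first-harmonic
  # DFT magnitude a N / 2, so OS = (2/N)|.| = a
  N <- 5; cc <- 10; a <- 4
  st <- array(0, c(3, 3, N))
  for (n in seq_len(N)) st[, , n] <- cc + a * cos(2 * pi * (n - 1) / N)
  expect_equal(reconstruct_ossim(st), matrix(a, 3, 3), tolerance = 1e-12)

  # unmodulated stack -> exactly zero
  st0 <- array(rep(fix_texture_scene()[1:8, 1:8], 4), c(8, 8, 4))
  expect_equal(max(reconstruct_ossim(st0)), 0, tolerance = 1e-12)

  # [1,0,1,0] alternates at the N/2 harmonic, not the fundamental
  st2 <- array(0, c(2, 2, 4))
  for (n in 1:4) st2[, , n] <- c(1, 0, 1, 0)[n]
  expect_equal(max(reconstruct_ossim(st2)), 0, tolerance = 1e-12)

  expect_error(reconstruct_ossim(array(1, c(4, 4, 2))), "N >= 3")
})

test_that("MAP solver satisfies its descent and fixed-point contracts", {
  fx <- fix_star_stack()
  rp <- recon_params(map_iterations = 8, upsample_factor = 1,
                     psf_sigma_px = 1.5)
  est <- map_estimate(fx$stack, params = rp)
  expect_true(all(est >= 0))
  expect_true(all(diff(attr(est, "objective")) <= 1e-9))

  # all-on pattern, no PSF, lambda 0: objective is minimized by the WF mean
  img <- fx$stack$data
  pu <- make_uniform_pattern(128, dim(img)[3])
  stku <- tile_stack(img, pu)
  rpu <- recon_params(map_iterations = 5, map_lambda = 0,
                      upsample_factor = 1, psf_sigma_px = 0)
  expect_equal(map_estimate(stku, pu, rpu), reconstruct_widefield(stku),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("noiseless objective is lower at the true scene than at the init", {
  fx <- fix_star_stack()
  truth_noiseless <- scene_truth(fx$scene, 1.5, NULL, seed = 2)
  stk <- simulate_mosaic(truth_noiseless, fx$layout, fx$pattern)[[1]]
  rp <- recon_params(map_iterations = 1, map_lambda = 0,
                     upsample_factor = 1, psf_sigma_px = 1.5)
  truth_crop <- fx$scene[81:208, 81:208]
  init <- reconstruct_widefield(stk) / fx$pattern$duty
  expect_lt(map_objective(truth_crop, stk, fx$pattern, rp),
            map_objective(init, stk, fx$pattern, rp))
})

test_that("spectral merge is an identity on equal inputs and scales DC", {
  img <- fix_texture_scene()[1:64, 1:64]
  for (cutoff in c(0.2, 0.4, 0.8)) {
    out <- spectral_merge(img, img, cutoff)
    expect_equal(out, img, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(attr(out, "scale"), 1, tolerance = 1e-10)
  }
  # DC of output = s x DC of low input (w(0) = 1): with hi = 2 * img the
  # spectra are proportional, s = 2, and no clipping occurs
  out <- spectral_merge(img, 2 * img, 0.4)
  expect_equal(attr(out, "scale"), 2, tolerance = 1e-10)
  expect_equal(mean(out), 2 * mean(img), tolerance = 1e-10)
  expect_error(spectral_merge(img, img[1:32, 1:32]), "shape")
})

test_that("full MAP-SIM pipeline improves the measured cut-off over WF", {
  fx <- fix_star_stack()
  rp <- recon_params(map_iterations = 12, upsample_factor = 1,
                     psf_sigma_px = 1.5)
  rr <- reconstruct_mapsim(fx$stack, params = rp)
  expect_true(all(rr$wf >= 0) && all(rr$os >= 0) && all(rr$mapsim >= 0))
  expect_gt(psd_ca(rr$mapsim)$cutoff_freq, psd_ca(rr$wf)$cutoff_freq)
  # merge scale contract: mean intensity preserved within 20% of OS-SIM
  expect_lt(abs(mean(rr$mapsim) - mean(rr$os)) / mean(rr$os), 0.2)
  # determinism
  rr2 <- reconstruct_mapsim(fx$stack, params = rp)
  expect_identical(rr$mapsim, rr2$mapsim)
})

test_that("upsampled MAP-SIM output has the upsampled shape", {
  fx <- fix_noiseless_mosaic()
  rp <- recon_params(map_iterations = 3, upsample_factor = 2,
                     psf_sigma_px = 1.5)
  rr <- reconstruct_mapsim(fx$stacks[[1]], params = rp)
  expect_equal(dim(rr$mapsim), 2 * dim(rr$wf))
  expect_equal(mean(upsample_fourier(rr$wf, 2)), mean(rr$wf),
               tolerance = 1e-10)
})
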