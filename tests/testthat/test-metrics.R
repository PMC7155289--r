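test_that("stitching-artifact period follows l(1-r)", {
  expect_equal(t_stitch(2048, 0.2), 1638.4)
  expect_equal(round(t_stitch(2048, 0.2)), 1638)
  expect_equal(t_stitch(100, 0), 100)
  # linear in l, decreasing in r
  expect_equal(t_stitch(4096, 0.2), 2 * t_stitch(2048, 0.2))
  expect_gt(t_stitch(2048, 0.1), t_stitch(2048, 0.3))
  expect_error(t_stitch(2048, 1), "r must be")
  expect_error(t_stitch(0, 0.2), "positive")
})

test_that("radially averaged PSD localizes a pure tone and flags noise as flat", {
  set.seed(4)
  n <- 128
  f0 <- 10 / n  # cycles per pixel
  tone <- outer(rep(1, n), cos(2 * pi * f0 * seq_len(n))) +
    matrix(rnorm(n * n, sd = 0.01), n, n)
  curve <- psd_ca(tone)
  peak_bin <- which.max(curve$psd[-1]) + 1  # skip DC-dominated first bin
  expect_lt(abs(curve$freq[peak_bin] - f0), 1.5 * (curve$freq[2] - curve$freq[1]))

  # white noise: flat radial spectrum (no trend, modest ring-to-ring
  # scatter from the finite ring populations)
  noise <- matrix(rnorm(n * n), n, n)
  cn <- psd_ca(noise)
  tail_curve <- cn$psd[-(1:3)]
  expect_lt(stats::sd(tail_curve) / mean(tail_curve), 0.25)
  h <- length(tail_curve) %/% 2
  expect_lt(abs(mean(tail_curve[1:h]) /
                  mean(tail_curve[(h + 1):length(tail_curve)]) - 1), 0.2)
  expect_error(psd_ca(matrix(1, 64, 64)), "constant")
})

test_that("zero-padding upsampling halves the measured cut-off frequency", {
  # isotropic fixture: strip the corner frequencies of the square sampling
  # lattice so the noise floor is a clean radial plateau at both scales
  set.seed(12)
  n <- 96
  noise <- matrix(stats::rnorm(n * n, sd = 0.02), n, n)
  fr <- sqrt(outer(panosim:::.fftfreq(n)^2, panosim:::.fftfreq(n)^2, `+`))
  noise <- Re(stats::fft(stats::fft(noise) * (fr <= 0.5),
                         inverse = TRUE)) / n^2
  img <- gaussian_blur(fix_texture_scene()[1:n, 1:n], 1) + noise
  img <- img - min(img)
  c1 <- psd_ca(img)$cutoff_freq
  c2 <- psd_ca(upsample_fourier(img, 2))$cutoff_freq
  expect_equal(c2, c1 / 2, tolerance = 0.15)
})

test_that("PSD resolution is scale-invariant and degrades with blur", {
  img <- fix_star_scene()[81:208, 81:208]
  set.seed(9)
  noisy <- function(x) x + matrix(rnorm(length(x), sd = 0.01), nrow(x))
  i1 <- noisy(gaussian_blur(img, 1))
  r1 <- resolution_from_psd(psd_ca(i1), 100)
  r1s <- resolution_from_psd(psd_ca(i1 * 37.5), 100)
  expect_equal(r1, r1s, tolerance = 1e-10)
  set.seed(9)
  i2 <- noisy(gaussian_blur(img, 2))
  r2 <- resolution_from_psd(psd_ca(i2), 100)
  expect_gt(r2, r1)
  # closed forms
  expect_equal(resolution_from_psd(
    structure(list(cutoff_freq = 0.5), class = "psd_curve"), 100), 200)
  expect_equal(resolution_from_psd(
    structure(list(cutoff_freq = 0.25), class = "psd_curve"), 216.7), 866.8)
})

test_that("grid artifact spectrum flags a pure tone at the stitch period", {
  n <- 512; tpx <- 128
  tone <- outer(rep(1, n), 1 + 0.5 * cos(2 * pi * seq(0, n - 1) / tpx))
  rep_ <- grid_artifact_spectrum(tone, t_stitch_px = tpx)
  expect_gt(rep_$peak_ratio, 100)
  expect_equal(rep_$fundamental_freq, 1 / tpx)
  flat <- matrix(3, 256, 256)
  expect_equal(grid_artifact_spectrum(flat, t_stitch_px = 64)$peak_ratio, 0)
  expect_error(grid_artifact_spectrum(matrix(1, 32, 32), t_stitch_px = 64),
               "larger")
})
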