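# Shared fixtures, built once per test run and memoised.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fix)) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

fix_texture_scene <- function() fixture("texture300",
  function() make_scene("texture", 300, seed = 11))

fix_star_scene <- function() fixture("star300",
  function() make_scene("star", 300))

# one noiseless 5-phase patterned stack over a 2x2 grid with vignette
fix_noiseless_mosaic <- function() fixture("noiseless_mosaic", function() {
  scene <- fix_texture_scene()
  layout <- make_mosaic_layout(2, 2, 64, 0.2, origin = c(10, 10))
  vig <- make_vignette(64, 0.4)
  truth <- scene_truth(scene, psf_sigma_px = 1.5, vignette_truth = vig,
                       seed = 5)
  pattern <- make_line_patterns(64, 5, 5)
  list(scene = scene, layout = layout, vig = vig, truth = truth,
       pattern = pattern,
       stacks = simulate_mosaic(truth, layout, pattern))
})

# single noisy star-target stack for resolution tests
fix_star_stack <- function() fixture("star_stack", function() {
  scene <- fix_star_scene()
  layout <- make_mosaic_layout(1, 1, 128, 0.2, origin = c(80, 80))
  pattern <- make_line_patterns(128, 5, 5)
  truth <- scene_truth(scene, psf_sigma_px = 1.5, poisson_scale = 500,
                       read_noise_sd = 0.005, seed = 2)
  list(scene = scene, layout = layout, pattern = pattern, truth = truth,
       stack = simulate_mosaic(truth, layout, pattern)[[1]])
})

cv <- function(x) stats::sd(x) / mean(x)

rel_rms <- function(est, truth) sqrt(mean((est - truth)^2)) / mean(truth)
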