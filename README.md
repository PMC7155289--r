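# panosim

Whole-slide ("panoramic") imaging with structured illumination microscopy
(SIM) acquires a grid of overlapping tiles, each tile a stack of N images
under a shifting patterned illumination, and computationally combines them
into one seamless, optically sectioned, resolution-enhanced image. Two
processing problems dominate the quality of the result:

1. **Vignetting.** SIM reconstruction leaves every tile with a smooth,
   sample-dependent shading that a calibration slide cannot predict. Left
   uncorrected, stitching turns it into a periodic grid with period
   `T_stitch = l(1 - r)` (tile width `l`, proportional overlap `r`), visible
   in the mosaic's FFT as bright peaks at `1/T_stitch`.
2. **Resolution accounting.** The point of SIM is resolution; a measured,
   not nominal, resolution figure is needed, obtained from the cut-off of
   the normalized radially averaged power spectral density (PSD).

`panosim` is an R package for microscopists and image-analysis developers
that implements the full pipeline:

* **simulate** - a parameterized forward model (scene x binary line
  pattern, Gaussian PSF, shared vignette, Poisson + read noise) producing
  multi-page TIFF tile stacks with a YAML sidecar;
* **reconstruct** - wide-field (`I_WF = (1/N) sum I_n`), optically
  sectioned OS-SIM (N-phase homodyne demodulation
  `OS = (2/N)|sum_n I_n e^{-2 pi i n/N}|`), and MAP-SIM: a nonnegative
  maximum a posteriori estimate minimizing
  `sum_n ||P(m_n x) - I_n||^2 + lambda ||grad x||^2`, merged with the
  OS-SIM spectrum in the Fourier domain;
* **devignette** - divide each tile by the unit-mean, border-limited-mean
  blurred average intensity projection of all tiles (per reconstruction
  method), or add the inverse of an empty-field image for bright-field
  colour tiles;
* **stitch** - grid placement with optional phase-correlation offset
  refinement and feather/average/overwrite blending;
* **measure** - PSD cut-off resolution and grid-artifact peak ratios.

## Worked example

Simulate a 5x5 mosaic of 64 px tiles (20% overlap, 5-phase pattern,
vignette strength 0.4, sCMOS-like noise), reconstruct, devignette, stitch,
and quantify the grid artifact:

```r
library(panosim)

lay    <- make_mosaic_layout(5, 5, tile_px = 64, overlap_frac = 0.2)
scene  <- make_scene("texture", 4 * lay$step + 64, seed = 42)
truth  <- scene_truth(scene, psf_sigma_px = 1.5,
                      vignette_truth = make_vignette(64, 0.4),
                      poisson_scale = 200, read_noise_sd = 0.01, seed = 42)
stacks <- simulate_mosaic(truth, lay, make_line_patterns(64, 5, 5))

wf      <- lapply(stacks, reconstruct_widefield)
profile <- estimate_vignette(wf, radius = 6)
profile
#> <vignette_profile> 64x64, range [0.776, 1.151], normalization 0.1735

wf_corr <- lapply(wf, apply_devignette, profile = profile)
raw <- stitch_grid(wf, lay)
cor <- stitch_grid(wf_corr, lay)
cor
#> <stitch_result> mosaic 268x268 from 25 tiles, blend 'feather', max |shift| 0 px

grid_artifact_spectrum(raw$mosaic, lay)
#> <grid_artifact_report> T_stitch 51.2 px (f0 0.01953 cyc/px), peak/background 126
grid_artifact_spectrum(cor$mosaic, lay)
#> <grid_artifact_report> T_stitch 51.2 px (f0 0.01953 cyc/px), peak/background 5.12
```

The estimated profile spans 0.78-1.15 (unit mean) - the simulated
strength-0.4 vignette. The uncorrected stitch has a spectral peak at the
stitching frequency 126x above background; devignetting drops it to 5x, a
25-fold suppression of the grid artifact. The same chain for MAP-SIM
tiles, plus resolution measurement, runs via the one-call driver:

```r
manifest <- run_pipeline(default_config())
manifest$metrics
# t_stitch_px, grid peak ratios (corrected / uncorrected),
# resolution_nm_wf, resolution_nm_mapsim
```

A thin command-line front end with subcommands `simulate`, `reconstruct`,
`devignette`, `stitch`, `measure`, `run` lives at `inst/cli/panosim.R`.

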