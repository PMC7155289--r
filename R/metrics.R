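#' Grid-artifact period of a stitched mosaic
#'
#' Uncorrected vignetting repeats with the spacing between tiles, so the
#' artifact period in the stitched image is `T_stitch = l * (1 - r)` where
#' `l` is the tile width in pixels and `r` the proportional overlap. For
#' square camera sensors the period is the same along both axes.
#'
#' @param l tile width in pixels (> 0).
#' @param r proportional overlap in `[0, 1)`.
#' @return the period in pixels (not rounded; round for reporting).
#' @examples
#' round(t_stitch(2048, 0.2))  # 1638
#' @export
t_stitch <- function(l, r) {
  if (l <= 0) stop("l must be positive")
  if (r < 0 || r >= 1) stop("r must be in [0, 1)")
  l * (1 - r)
}

#' Normalized radially averaged power spectral density
#'
#' Computes the circularly averaged power spectrum of an image and derives
#' a resolution cut-off from it: the image is Hann-windowed, Fourier
#' transformed, the squared magnitude averaged over rings of constant
#' radial frequency, and the curve normalized to a maximum of one. A noise
#' floor is estimated as the mean of the curve over the top decile of
#' frequencies; the cut-off frequency is the first point at which the
#' noise-corrected curve reaches zero (linearly interpolated between the
#' neighbouring bins). Beyond the cut-off no image content rises above the
#' noise, so its period is the resolution limit.
#'
#' @param img 2-D matrix, side >= 32, not constant.
#' @param window apply a Hann window before the FFT (recommended; raw FFTs
#'   leak edge discontinuities into the radial average).
#' @return Object of class `psd_curve`: `freq` (cycles/pixel, ascending),
#'   `psd` (normalized), `noise_floor`, `cutoff_freq`.
#' @export
psd_ca <- function(img, window = TRUE) {
  stopifnot(is.matrix(img), min(dim(img)) >= 32)
  if (max(img) == min(img))
    stop("constant image: no spectrum beyond DC, cut-off undefined")
  d <- dim(img)
  if (window) {
    hy <- 0.5 * (1 - cos(2 * pi * seq(0, d[1] - 1) / (d[1] - 1)))
    hx <- 0.5 * (1 - cos(2 * pi * seq(0, d[2] - 1) / (d[2] - 1)))
    img <- img * outer(hy, hx)
  }
  P <- Mod(.fft2(img))^2
  fr <- sqrt(outer(.fftfreq(d[1])^2, .fftfreq(d[2])^2, `+`))
  nb <- floor(min(d) / 2)
  bin <- pmin(floor(fr * 2 * nb) + 1L, nb)  # bin width 0.5/nb cycles/px
  psd <- as.vector(tapply(as.vector(P), as.vector(bin), mean))
  freq <- (seq_len(nb) - 0.5) * 0.5 / nb
  psd <- psd / max(psd)
  # bins with essentially no power (e.g. beyond the band limit of an
  # interpolated image) are outside the effective sampling band; exclude
  # them from the noise-floor estimate
  band <- max(which(psd > 1e-8))
  ntail <- max(1L, floor(band / 10))
  noise_floor <- mean(psd[(band - ntail + 1):band])
  corr <- psd - noise_floor
  below <- which(corr <= 0)
  if (length(below) == 0 || below[1] == 1) {
    cutoff <- if (length(below) == 0) 0.5 else freq[1]
  } else {
    i <- below[1]
    # linear interpolation between last positive and first nonpositive bin
    f0 <- freq[i - 1]; f1 <- freq[i]
    c0 <- corr[i - 1]; c1 <- corr[i]
    cutoff <- f0 + (f1 - f0) * c0 / (c0 - c1)
  }
  structure(list(freq = freq, psd = psd, noise_floor = noise_floor,
                 cutoff_freq = cutoff),
            class = "psd_curve")
}

#' @export
print.psd_curve <- function(x, ...) {
  cat(sprintf("<psd_curve> %d bins to Nyquist, noise floor %.3g, cut-off %.4f cycles/px\n",
              length(x$freq), x$noise_floor, x$cutoff_freq))
  invisible(x)
}

#' Plot a PSD curve
#'
#' Log-scale radially averaged power spectral density with the noise floor
#' and the cut-off frequency marked.
#'
#' @param x a [psd_ca()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.psd_curve <- function(x, ...) {
  graphics::plot(x$freq, x$psd, type = "l", log = "y",
                 xlab = "spatial frequency (cycles/pixel)",
                 ylab = "normalized PSD", ...)
  graphics::abline(h = x$noise_floor, lty = 2, col = "grey40")
  graphics::abline(v = x$cutoff_freq, lty = 3, col = "red")
  invisible(x)
}

#' Real-space resolution from a PSD cut-off
#'
#' The resolution limit is the real-space period of the cut-off frequency:
#' `pixel_size_nm / cutoff_freq`. For images reconstructed on an upsampled
#' grid pass the effective (finer) pixel size.
#'
#' @param curve a [psd_ca()] result.
#' @param pixel_size_nm physical pixel pitch of the analysed image.
#' @return resolution in nanometres (smaller is better).
#' @export
resolution_from_psd <- function(curve, pixel_size_nm) {
  stopifnot(inherits(curve, "psd_curve"))
  if (!is.finite(curve$cutoff_freq) || curve$cutoff_freq <= 0)
    stop("cut-off frequency undefined")
  pixel_size_nm / curve$cutoff_freq
}

#' Quantify residual grid artifacts in a stitched mosaic
#'
#' A vignette left uncorrected repeats at the tile spacing and shows up in
#' the mosaic's FFT as bright peaks at the fundamental frequency
#' `1 / T_stitch` on both frequency axes. This function samples the power
#' spectrum at `(+/-1/T, 0)` and `(0, +/-1/T)` (maximum over a 3x3 bin
#' neighbourhood, to absorb one-bin discretization error), compares it with
#' the median power in a surrounding annulus (radii 2-8 bins, peak
#' neighbourhood excluded), and reports the ratio. It also returns the 1-D
#' power profiles along both frequency axes for plotting.
#'
#' @param mosaic stitched image, larger than one artifact period per axis.
#' @param layout the [make_mosaic_layout()] describing the stitch (supplies
#'   tile width and overlap), or `NULL` if `t_stitch_px` is given.
#' @param t_stitch_px optionally, the artifact period in pixels directly.
#' @return Object of class `grid_artifact_report`: `t_stitch_px`,
#'   `fundamental_freq` (cycles/pixel), `peak_power`, `background_power`,
#'   `peak_ratio`, and `profile_x` / `profile_y` (data frames of frequency
#'   vs power through the spectrum centre).
#' @export
grid_artifact_spectrum <- function(mosaic, layout = NULL, t_stitch_px = NULL) {
  if (is.null(t_stitch_px)) {
    stopifnot(inherits(layout, "mosaic_layout"))
    t_stitch_px <- t_stitch(layout$tile_px, layout$overlap_frac)
  }
  d <- dim(mosaic)
  if (any(d <= t_stitch_px))
    stop("mosaic must be larger than one artifact period in both axes")
  f0 <- 1 / t_stitch_px
  P <- Mod(.fft2(mosaic))^2
  # peak bins on each axis (frequency index, 0-based)
  ky <- round(f0 * d[1]); kx <- round(f0 * d[2])
  peak_at <- function(iy, ix) {
    ry <- ((iy + (-1:1)) %% d[1]) + 1
    rx <- ((ix + (-1:1)) %% d[2]) + 1
    max(P[ry, rx])
  }
  peaks <- c(peak_at(ky, 0), peak_at(d[1] - ky, 0),
             peak_at(0, kx), peak_at(0, d[2] - kx))
  peak_power <- max(peaks)
  # background: median over annulus radii 2..8 bins around each peak,
  # excluding the 3x3 peak neighbourhoods
  rr <- sqrt(outer((-8:8)^2, (-8:8)^2, `+`))
  in_annulus <- rr >= 2 & rr <= 8  # never intersects the 3x3 peak patch
  bg <- c()
  for (pk in list(c(ky, 0), c(d[1] - ky, 0), c(0, kx), c(0, d[2] - kx))) {
    iy <- (pk[1] + (-8:8)) %% d[1]; ix <- (pk[2] + (-8:8)) %% d[2]
    bg <- c(bg, P[iy + 1, ix + 1][in_annulus])
  }
  background_power <- stats::median(bg)
  peak_ratio <- if (background_power > 0) peak_power / background_power
    else if (peak_power == 0) 0 else Inf
  half_y <- floor(d[1] / 2); half_x <- floor(d[2] / 2)
  structure(
    list(t_stitch_px = t_stitch_px, fundamental_freq = f0,
         peak_power = peak_power, background_power = background_power,
         peak_ratio = peak_ratio,
         profile_y = data.frame(freq = (0:half_y) / d[1],
                                power = P[1:(half_y + 1), 1]),
         profile_x = data.frame(freq = (0:half_x) / d[2],
                                power = P[1, 1:(half_x + 1)])),
    class = "grid_artifact_report")
}

#' @export
print.grid_artifact_report <- function(x, ...) {
  cat(sprintf("<grid_artifact_report> T_stitch %.1f px (f0 %.5f cyc/px), peak/background %.3g\n",
              x$t_stitch_px, x$fundamental_freq, x$peak_ratio))
  invisible(x)
}

#' Plot grid-artifact axis profiles
#'
#' Power along the two frequency axes through the spectrum centre, with
#' the expected fundamental `1 / T_stitch` marked.
#'
#' @param x a [grid_artifact_spectrum()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grid_artifact_report <- function(x, ...) {
  graphics::plot(x$profile_x$freq[-1], x$profile_x$power[-1], type = "l",
                 log = "y", xlab = "spatial frequency (cycles/pixel)",
                 ylab = "power", col = "steelblue", ...)
  graphics::lines(x$profile_y$freq[-1], x$profile_y$power[-1], col = "tomato")
  graphics::abline(v = x$fundamental_freq, lty = 3)
  graphics::legend("topright", c("x axis", "y axis"), lty = 1,
                   col = c("steelblue", "tomato"), bty = "n")
  invisible(x)
}
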