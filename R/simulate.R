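#' Gaussian blur with periodic boundary
#'
#' Convolves an image with an isotropic Gaussian point-spread function via
#' the FFT, using the analytic Gaussian transfer function
#' `exp(-2 pi^2 sigma^2 f^2)`. The operator is linear, preserves constants,
#' and is self-adjoint, which the MAP solver relies on.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian width in pixels; `sigma <= 0` returns the input.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Re(.ifft2(.fft2(img) * .gauss_otf(dim(img), sigma)))
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# frequency grid in cycles/pixel for an axis of length n (fftfreq layout)
.fftfreq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

.gauss_otf <- function(dims, sigma) {
  fy <- .fftfreq(dims[1]); fx <- .fftfreq(dims[2])
  exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
}

#' Raw phase-stepped image stack for one mosaic tile
#'
#' Container for the N patterned-illumination exposures acquired at a single
#' mosaic position. Images are stored as an `H x W x N` array (one slice per
#' phase).
#'
#' @param data `H x W x N` nonnegative array, or a list of N matrices.
#' @param pattern the [pattern_set] used during acquisition.
#' @param position integer `(row, col)` grid index of the tile.
#' @param pixel_size_nm physical pixel pitch.
#' @return Object of class `tile_stack`.
#' @export
tile_stack <- function(data, pattern, position = c(1L, 1L),
                       pixel_size_nm = 216.7) {
  if (is.list(data)) data <- simplify2array(data)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  if (any(data < 0)) stop("tile_stack intensities must be >= 0")
  if (!is.null(pattern) && dim(data)[3] != pattern$n_phases)
    stop("number of stack slices must equal pattern$n_phases")
  structure(
    list(data = data, pattern = pattern,
         position = as.integer(position), pixel_size_nm = pixel_size_nm),
    class = "tile_stack")
}

#' @export
print.tile_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tile_stack> tile (%d,%d): %d phases of %dx%d px, %.1f nm/px\n",
              x$position[1], x$position[2], d[3], d[1], d[2], x$pixel_size_nm))
  invisible(x)
}

# Evaluate the line pattern analytically at arbitrary (possibly negative)
# 0-based pixel coordinates, so masks can be extended beyond the tile for
# blur padding. rows/cols are vectors of coordinates.
.pattern_mask_at <- function(pattern, phase, rows, cols) {
  if (pattern$duty >= 1) return(matrix(1, length(rows), length(cols)))
  th <- pattern$orientation_deg * pi / 180
  step <- pattern$duty * pattern$period_px
  coord <- cos(th) * matrix(rows, length(rows), length(cols)) +
           sin(th) * matrix(cols, length(rows), length(cols), byrow = TRUE)
  ph <- (coord - (phase - 1) * step) %% pattern$period_px
  (ph < step) + 0
}

#' Simulate a full patterned-illumination mosaic acquisition
#'
#' Applies the forward model to every tile position of `layout`: crop the
#' scene, multiply by the shifted illumination mask, convolve with the
#' Gaussian PSF, multiply by the common vignette field, then (optionally)
#' apply Poisson shot noise and Gaussian read noise. Blurring is performed
#' on a scene crop padded by `4 * psf_sigma` pixels so that overlapping
#' tiles see consistent data; the line pattern is evaluated analytically on
#' the padded region, treating it as an infinite periodic pattern anchored
#' at the tile origin.
#'
#' With all noise terms zero the simulation is exactly linear, so the
#' average of the N phase images equals `duty * vignette * blurred crop`.
#'
#' @param truth a [scene_truth()] object.
#' @param layout a [make_mosaic_layout()] object that fits inside the scene.
#' @param pattern a [pattern_set], typically from [make_line_patterns()].
#' @return list of [tile_stack] objects in row-major tile order.
#' @export
simulate_mosaic <- function(truth, layout, pattern) {
  stopifnot(inherits(truth, "scene_truth"),
            inherits(layout, "mosaic_layout"),
            inherits(pattern, "pattern_set"))
  scene <- truth$scene
  l <- layout$tile_px
  if (!identical(dim(pattern$masks[[1]]), c(l, l)))
    stop("pattern mask shape must equal layout tile size")
  lim <- dim(scene)
  if (any(layout$offsets < 0) ||
      any(layout$offsets[, 1] + l > lim[1]) ||
      any(layout$offsets[, 2] + l > lim[2]))
    stop("layout exceeds scene bounds")
  if (!is.null(truth$vignette_truth) &&
      !identical(dim(truth$vignette_truth), c(l, l)))
    stop("vignette_truth shape must equal layout tile size")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed)
  pad <- if (truth$psf_sigma_px > 0) ceiling(4 * truth$psf_sigma_px) else 0L
  vig <- truth$vignette_truth
  stacks <- vector("list", nrow(layout$offsets))
  for (t in seq_len(nrow(layout$offsets))) {
    off <- layout$offsets[t, ]
    crop <- .crop_padded(scene, off, l, pad)
    imgs <- array(0, c(l, l, pattern$n_phases))
    for (n in seq_len(pattern$n_phases)) {
      mask <- .pattern_mask_at(pattern, n, seq(-pad, l + pad - 1),
                               seq(-pad, l + pad - 1))
      img <- gaussian_blur(crop * mask, truth$psf_sigma_px)
      img <- img[(pad + 1):(pad + l), (pad + 1):(pad + l), drop = FALSE]
      if (!is.null(vig)) img <- img * vig
      if (truth$poisson_scale > 0)
        img <- matrix(stats::rpois(length(img),
                                   pmax(img, 0) * truth$poisson_scale) /
                        truth$poisson_scale, l, l)
      if (truth$read_noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img),
                                         sd = truth$read_noise_sd), l, l)
      img[img < 0] <- 0
      imgs[, , n] <- img
    }
    pos <- c((t - 1L) %/% layout$cols + 1L, (t - 1L) %% layout$cols + 1L)
    stacks[[t]] <- tile_stack(imgs, pattern, pos, layout$pixel_size_nm)
  }
  stacks
}

# crop scene[off_y .. off_y+l-1, ...] (0-based, half-open) with `pad` extra
# pixels on every side; parts falling outside the scene are edge-replicated
.crop_padded <- function(scene, off, l, pad) {
  ry <- (off[1] - pad):(off[1] + l + pad - 1) + 1L  # to 1-based
  rx <- (off[2] - pad):(off[2] + l + pad - 1) + 1L
  ry <- pmin(pmax(ry, 1L), nrow(scene))
  rx <- pmin(pmax(rx, 1L), ncol(scene))
  scene[ry, rx, drop = FALSE]
}

#' Crop the region of the scene spanned by a mosaic layout
#'
#' Ground-truth oracle for stitching tests: the bounding box of all tiles.
#'
#' @param scene scene matrix.
#' @param layout a [make_mosaic_layout()] object.
#' @return matrix covering the layout's bounding box.
#' @export
scene_crop <- function(scene, layout) {
  l <- layout$tile_px
  y0 <- min(layout$offsets[, 1]); x0 <- min(layout$offsets[, 2])
  y1 <- max(layout$offsets[, 1]) + l; x1 <- max(layout$offsets[, 2]) + l
  scene[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}
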