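#' Synthetic ground-truth scenes
#'
#' Generates a large nonnegative intensity image standing in for the sample
#' on the slide. Three kinds are available:
#' \describe{
#'   \item{`beads`}{sparse Gaussian spots on a dark background, useful for
#'     registration and point-source tests.}
#'   \item{`star`}{a Siemens-star radial target centred in the image, the
#'     standard resolution phantom: spoke spacing shrinks toward the hub so
#'     a resolution limit appears as the radius where spokes blur together.}
#'   \item{`texture`}{low-pass-filtered noise riding on a uniform baseline,
#'     mimicking the low-contrast appearance of dense, uniformly stained
#'     tissue in a wide-field fluorescence image.}
#' }
#'
#' @param kind one of `"beads"`, `"star"`, `"texture"`.
#' @param size_px side length of the square scene.
#' @param seed integer RNG seed; the scene is deterministic given the seed.
#' @param n_spokes number of bright spokes for the star target.
#' @param contrast relative fluctuation amplitude (sd / mean) of the
#'   texture scene around its baseline.
#' @return `size_px` x `size_px` numeric matrix, values >= 0.
#' @export
make_scene <- function(kind = c("beads", "star", "texture"), size_px,
                       seed = 1L, n_spokes = 36L, contrast = 0.15) {
  kind <- match.arg(kind)
  size_px <- as.integer(size_px)
  stopifnot(size_px >= 16)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sc <- switch(kind,
    beads = .scene_beads(size_px),
    star = .scene_star(size_px, n_spokes),
    texture = .scene_texture(size_px, contrast))
  sc[sc < 0] <- 0
  sc
}

.scene_beads <- function(n) {
  k <- max(10L, round(n^2 / 400))
  y <- runif(k, 1, n); x <- runif(k, 1, n)
  amp <- runif(k, 0.5, 1); sig <- runif(k, 1, 2.5)
  img <- matrix(0.02, n, n)  # faint background so tiles are never all-zero
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (i in seq_len(k)) {
    # render each bead only in a local window for speed
    r0 <- max(1, floor(y[i] - 4 * sig[i])); r1 <- min(n, ceiling(y[i] + 4 * sig[i]))
    c0 <- max(1, floor(x[i] - 4 * sig[i])); c1 <- min(n, ceiling(x[i] + 4 * sig[i]))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - y[i])^2, (cc - x[i])^2, `+`)
    img[rr, cc] <- img[rr, cc] + amp[i] * exp(-d2 / (2 * sig[i]^2))
  }
  img
}

.scene_star <- function(n, n_spokes) {
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n) - ctr, n, n)
  cols <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  theta <- atan2(rows, cols)
  r <- sqrt(rows^2 + cols^2)
  img <- 0.5 * (1 + sign(cos(n_spokes * theta)))
  img[r < 0.01 * n] <- 1        # solid hub
  img[r > 0.48 * n] <- 0.1      # dim surround beyond the target
  img + 0.05
}

.scene_texture <- function(n, contrast) {
  g <- matrix(rnorm(n * n), n, n)
  sm <- gaussian_blur(g, sigma = 2)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  img <- 1 + contrast * sm
  img[img < 0] <- 0
  img
}

#' Synthetic smooth vignette field
#'
#' A radially decreasing multiplicative shading field: 1 at the tile centre
#' falling quadratically to `1 - strength` at the corners. This emulates the
#' smooth intensity falloff common to every tile of a mosaic, which after
#' stitching produces the periodic grid artifact.
#'
#' @param tile_px side length in pixels.
#' @param strength falloff depth in `[0, 1)`; 0 gives a flat field of ones.
#' @return `tile_px` x `tile_px` matrix with values in `(0, 1]`.
#' @export
make_vignette <- function(tile_px, strength = 0.4) {
  if (strength < 0 || strength >= 1)
    stop("strength must be in [0, 1); corners would reach zero otherwise")
  n <- as.integer(tile_px)
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n) - ctr, n, n)
  cols <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  d2 <- rows^2 + cols^2
  1 - strength * d2 / max(d2)
}

#' Ground-truth description of a simulated acquisition
#'
#' Bundles the scene, the optical blur, the per-tile vignette and the noise
#' model that together define the forward model used by [simulate_mosaic()].
#'
#' @param scene 2-D nonnegative intensity matrix (the whole-slide sample).
#' @param psf_sigma_px Gaussian point-spread-function width in pixels;
#'   0 disables blurring.
#' @param vignette_truth tile-shaped multiplicative field in `(0, 1]`, or
#'   `NULL` for no vignetting.
#' @param poisson_scale expected photons per intensity unit for shot noise;
#'   0 disables Poisson noise.
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   (intensity units); 0 disables it.
#' @param seed RNG seed controlling all simulated noise.
#' @return Object of class `scene_truth`.
#' @export
scene_truth <- function(scene, psf_sigma_px = 0, vignette_truth = NULL,
                        poisson_scale = 0, read_noise_sd = 0, seed = 1L) {
  stopifnot(is.matrix(scene), all(scene >= 0))
  if (!is.null(vignette_truth)) {
    stopifnot(is.matrix(vignette_truth),
              all(vignette_truth > 0), all(vignette_truth <= 1))
  }
  structure(
    list(scene = scene, psf_sigma_px = psf_sigma_px,
         vignette_truth = vignette_truth,
         poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
         seed = as.integer(seed)),
    class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> scene %dx%d, psf sigma %g px, vignette %s, poisson %g, read sd %g, seed %d\n",
              nrow(x$scene), ncol(x$scene), x$psf_sigma_px,
              if (is.null(x$vignette_truth)) "none" else "yes",
              x$poisson_scale, x$read_noise_sd, x$seed))
  invisible(x)
}

# save/restore the global RNG state so generators are self-seeding without
# clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
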