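#' Average intensity projection of a tile set
#'
#' The pixelwise arithmetic mean across all tiles. Averaging many tiles
#' merges their (uncorrelated) foreground content into a nearly uniform
#' background while the vignetting profile, identical in every tile,
#' survives unchanged - which is what makes the blurred projection a good
#' vignette estimate.
#'
#' @param tiles list of matrices of identical shape.
#' @return matrix of the same shape.
#' @export
average_projection <- function(tiles) {
  if (length(tiles) < 1) stop("need at least one tile")
  d <- dim(tiles[[1]])
  for (t in tiles) if (!identical(dim(t), d)) stop("tile shape mismatch")
  Reduce(`+`, tiles) / length(tiles)
}

#' Border-limited mean filter
#'
#' Square-window mean filter whose averaging window is intersected with the
#' image domain: near edges the window shrinks so that no values outside
#' the border are sampled. Unlike padded or mirrored blurs, this cannot
#' brighten (or darken) the edges of a smooth image - a constant image is
#' returned exactly unchanged at every radius - which matters because the
#' blurred projection is later used as a divisor.
#'
#' Implemented with summed-area tables, so the cost is independent of the
#' radius.
#'
#' @param img numeric matrix.
#' @param radius window half-width in pixels; 0 is the identity.
#' @return filtered matrix, same shape.
#' @export
border_limited_mean <- function(img, radius) {
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  # summed-area table with a zero top row/left column
  S <- matrix(0, n + 1, m + 1)
  S[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  r0 <- pmax(seq_len(n) - radius, 1L); r1 <- pmin(seq_len(n) + radius, n)
  c0 <- pmax(seq_len(m) - radius, 1L); c1 <- pmin(seq_len(m) + radius, m)
  sums <- S[r1 + 1, c1 + 1, drop = FALSE] - S[r0, c1 + 1, drop = FALSE] -
    S[r1 + 1, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  counts <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  sums / counts
}

#' Estimate the vignetting profile from reconstructed tiles
#'
#' The profile is the border-limited-mean blur of the average intensity
#' projection of the tiles, normalized to unit mean. SIM reconstruction
#' introduces shading beyond pure illumination nonuniformity, so the
#' profile must be estimated from the reconstructed tiles themselves (a
#' uniform calibration slide is not sufficient), and it must be estimated
#' separately for each reconstruction method (wide-field and MAP-SIM tiles
#' carry different profiles).
#'
#' @param tiles list of reconstructed tiles (matrices, one method only).
#' @param radius blur half-width in pixels; the default 200 suits
#'   full-size (2048 px) camera tiles - scale it down proportionally for
#'   smaller tiles (roughly a tenth of the tile side).
#' @return Object of class `vignette_profile` with fields `profile` (unit
#'   mean, strictly positive) and `normalization` (mean of the raw blurred
#'   projection, retained so corrections preserve the intensity scale).
#' @export
estimate_vignette <- function(tiles, radius = 200L) {
  proj <- average_projection(tiles)
  blurred <- border_limited_mean(proj, radius)
  if (any(blurred <= 0))
    stop("blurred projection has nonpositive pixels; ",
         "profile unusable as a divisor")
  nrm <- mean(blurred)
  structure(list(profile = blurred / nrm, normalization = nrm),
            class = "vignette_profile")
}

#' @export
print.vignette_profile <- function(x, ...) {
  cat(sprintf("<vignette_profile> %dx%d, range [%.3f, %.3f], normalization %.4g\n",
              nrow(x$profile), ncol(x$profile), min(x$profile),
              max(x$profile), x$normalization))
  invisible(x)
}

#' Remove the vignette from one tile
#'
#' Divides the tile by the unit-mean vignetting profile. Because the
#' profile has mean one, the overall intensity scale of the tile set is
#' preserved.
#'
#' @param tile matrix.
#' @param profile a [estimate_vignette()] result (or a plain unit-mean
#'   positive matrix).
#' @return corrected matrix.
#' @export
apply_devignette <- function(tile, profile) {
  p <- if (inherits(profile, "vignette_profile")) profile$profile else profile
  if (!identical(dim(tile), dim(p))) stop("tile/profile shape mismatch")
  if (any(p <= 0)) stop("profile must be strictly positive")
  tile / p
}

#' Additive empty-field correction for bright-field color tiles
#'
#' Bright-field vignetting is removed by adding the photographic inverse of
#' an empty-field acquisition, `white_level - empty`, to every tile (per
#' channel) and clipping to `[0, white_level]`. A pixel where the tile
#' equals the empty reference maps to pure white, so an empty field becomes
#' uniformly white - removing both shading and color-balance artifacts in
#' one step. The empty image must be acquired under conditions identical to
#' the tiles.
#'
#' @param tile,empty numeric arrays of identical shape (`H x W` or
#'   `H x W x channels`).
#' @param white_level the white point (e.g. 255 for 8-bit data, 1 for
#'   normalized data).
#' @return corrected array, clipped to `[0, white_level]`.
#' @export
devignette_brightfield <- function(tile, empty, white_level = 255) {
  if (!identical(dim(tile), dim(empty)))
    stop("tile and empty reference must have identical shape and channels")
  out <- tile + (white_level - empty)
  out[out < 0] <- 0
  out[out > white_level] <- white_level
  out
}
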