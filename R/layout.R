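#' Mosaic grid layout
#'
#' Describes the tile grid of a panoramic acquisition: grid dimensions, tile
#' side length `l`, proportional overlap `r` between adjacent tiles, and the
#' nominal top-left position of every tile in mosaic coordinates. The step
#' between adjacent tiles is `round(l * (1 - r))`, which is also the period
#' of the grid artifact an uncorrected vignette produces after stitching.
#'
#' Conventions: row-major tile order, top-left origin, y increasing
#' downward, 0-based pixel offsets, half-open crops.
#'
#' @param rows,cols grid dimensions.
#' @param tile_px tile side length `l` in pixels.
#' @param overlap_frac proportional overlap `r` in `[0, 0.5)`.
#' @param pixel_size_nm physical pixel pitch in nanometres.
#' @param origin 0-based (y, x) offset of tile (1, 1) within the scene.
#' @return Object of class `mosaic_layout` with an `offsets` matrix
#'   (`rows*cols` x 2, columns y then x, row-major tile order).
#' @export
make_mosaic_layout <- function(rows, cols, tile_px, overlap_frac = 0.2,
                               pixel_size_nm = 216.7, origin = c(0, 0)) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  tile_px <- as.integer(tile_px)
  if (overlap_frac < 0 || overlap_frac >= 0.5)
    stop("overlap_frac must be in [0, 0.5)")
  step <- as.integer(round(tile_px * (1 - overlap_frac)))
  idx <- expand.grid(col = seq_len(cols), row = seq_len(rows))  # row-major
  offsets <- cbind(y = origin[1] + (idx$row - 1L) * step,
                   x = origin[2] + (idx$col - 1L) * step)
  structure(
    list(rows = rows, cols = cols, tile_px = tile_px,
         overlap_frac = overlap_frac, step = step,
         pixel_size_nm = pixel_size_nm, offsets = offsets),
    class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("<mosaic_layout> %dx%d tiles of %d px, overlap %.0f%% (step %d px), %.1f nm/px\n",
              x$rows, x$cols, x$tile_px, 100 * x$overlap_frac, x$step,
              x$pixel_size_nm))
  invisible(x)
}

#' Add integer stage jitter to a layout
#'
#' Perturbs every tile offset (except the first, which anchors the grid) by
#' independent uniform integer shifts in `[-max_px, max_px]`. Used as a test
#' fixture for phase-correlation offset refinement: the stitcher should
#' recover exactly the injected shifts.
#'
#' @param layout a [make_mosaic_layout()] object.
#' @param max_px maximum absolute jitter per axis, integer.
#' @param seed RNG seed.
#' @return The layout with perturbed `offsets` and an added
#'   `jitter` matrix recording the injected (dy, dx) per tile.
#' @export
jitter_layout <- function(layout, max_px = 3L, seed = 1L) {
  stopifnot(inherits(layout, "mosaic_layout"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(layout$offsets)
  jit <- matrix(sample(seq(-max_px, max_px), 2 * n, replace = TRUE), n, 2)
  jit[1, ] <- 0L
  layout$offsets <- layout$offsets + jit
  layout$jitter <- jit
  layout
}
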