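#' Illumination pattern sets
#'
#' A `pattern_set` describes the shifting binary line patterns projected onto
#' the sample during a structured-illumination acquisition: one binary mask
#' per phase position, all sharing a common period and orientation. The
#' defining property of a usable set is that the pixelwise sum of all masks
#' is spatially constant, so that the average of the phase images is a
#' conventional wide-field image.
#'
#' @param masks list of N binary matrices (values 0/1), one per phase.
#' @param period_px pattern repeat length in pixels (integer > 1).
#' @param orientation_deg orientation of the line pattern in degrees;
#'   0 means lines run horizontally (intensity varies along rows).
#' @param duty fraction of "on" pixels per period, in (0, 1].
#' @return An object of class `pattern_set` with fields `masks`,
#'   `period_px`, `n_phases`, `orientation_deg`, `duty`.
#' @export
pattern_set <- function(masks, period_px, orientation_deg = 0, duty = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1)
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!is.matrix(m) || !identical(dim(m), dims))
      stop("all masks must be matrices of identical shape")
    if (!all(m %in% c(0, 1)))
      stop("masks must be binary (0/1)")
  }
  if (is.null(duty)) duty <- mean(masks[[1]])
  structure(
    list(masks = masks, period_px = as.integer(period_px),
         n_phases = length(masks), orientation_deg = orientation_deg,
         duty = duty, shape = dims),
    class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d phases, period %d px, orientation %g deg, duty %.3f, %dx%d\n",
              x$n_phases, x$period_px, x$orientation_deg, x$duty,
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' Generate a shifting binary line pattern set
#'
#' Builds `n_phases` binary line masks of size `tile_px` x `tile_px`. The
#' pattern period is divided into `n_phases` equal integer steps; mask `n`
#' is mask `n-1` shifted by one step along the pattern normal (cyclically).
#' Because the "on" stripe width equals the step, every pixel is lit in
#' exactly one phase and the pixelwise sum of the set is exactly constant
#' (homogeneous illumination), which is what makes the average intensity
#' projection of the phase images a valid wide-field reconstruction.
#'
#' @param tile_px side length of the (square) masks in pixels.
#' @param period_px pattern period in pixels; must be divisible by
#'   `n_phases` so integer phase steps tile the period exactly.
#' @param n_phases number of phase steps (>= 2).
#' @param orientation_deg pattern orientation; 0 gives horizontal stripes
#'   (varying along rows), 90 vertical stripes (varying along columns).
#' @return A [pattern_set] with duty cycle `1 / n_phases`.
#' @examples
#' p <- make_line_patterns(16, period_px = 4, n_phases = 4)
#' Reduce(`+`, p$masks)[1:3, 1:3]  # constant 1
#' @export
make_line_patterns <- function(tile_px, period_px, n_phases,
                               orientation_deg = 0) {
  tile_px <- as.integer(tile_px); period_px <- as.integer(period_px)
  n_phases <- as.integer(n_phases)
  if (n_phases < 2) stop("n_phases must be >= 2")
  if (period_px <= 1) stop("period_px must be > 1")
  if (period_px %% n_phases != 0)
    stop("period_px must be divisible by n_phases; otherwise integer phase ",
         "steps cannot sum to homogeneous illumination")
  step <- period_px / n_phases
  # pattern coordinate along the normal of the lines; 0 deg -> rows
  th <- orientation_deg * pi / 180
  row <- matrix(0:(tile_px - 1), tile_px, tile_px)          # y, down
  col <- matrix(0:(tile_px - 1), tile_px, tile_px, byrow = TRUE)  # x, right
  coord <- cos(th) * row + sin(th) * col
  masks <- vector("list", n_phases)
  for (n in seq_len(n_phases)) {
    ph <- (coord - (n - 1) * step) %% period_px
    masks[[n]] <- (ph < step) + 0  # half-open stripe [0, step)
  }
  pattern_set(masks, period_px, orientation_deg, duty = step / period_px)
}

#' Uniform (all-on) pattern set
#'
#' A degenerate pattern set in which every mask is fully "on" (duty 1).
#' Useful as an identity forward model: with this pattern every phase image
#' equals a plain wide-field exposure.
#'
#' @inheritParams make_line_patterns
#' @return A [pattern_set] whose masks are all ones.
#' @export
make_uniform_pattern <- function(tile_px, n_phases = 1) {
  tile_px <- as.integer(tile_px)
  ones <- matrix(1, tile_px, tile_px)
  masks <- replicate(as.integer(n_phases), ones, simplify = FALSE)
  pattern_set(masks, period_px = tile_px, orientation_deg = 0, duty = 1)
}
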