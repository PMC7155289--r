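#' Phase-correlation shift estimate
#'
#' Estimates the translation of `b` relative to `a` as the peak of the
#' inverse transform of the normalized cross-power spectrum, with sub-pixel
#' refinement by a separable quadratic fit around the peak. If
#' `b == circshift(a, c(dy, dx))` the estimate is `c(dy, dx)`; identical
#' images give `c(0, 0)` exactly. Shifts are reported in `(-n/2, n/2]` per
#' axis.
#'
#' @param a,b matrices of identical shape with nonzero variance.
#' @return numeric `c(dy, dx)` with attribute `peak` (the correlation peak
#'   height, in `[0, 1]`, a confidence measure).
#' @export
phase_correlate <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("images must have identical shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("phase correlation undefined for zero-variance input")
  d <- dim(a)
  # mean removal and a Hann window suppress the edge discontinuities that
  # non-circular shifts introduce; regularized whitening keeps frequencies
  # with negligible signal from contributing pure noise phase
  hann <- outer(0.5 * (1 - cos(2 * pi * seq(0, d[1] - 1) / (d[1] - 1))),
                0.5 * (1 - cos(2 * pi * seq(0, d[2] - 1) / (d[2] - 1))))
  X <- .fft2((b - mean(b)) * hann) * Conj(.fft2((a - mean(a)) * hann))
  mag <- Mod(X)
  r <- Re(.ifft2(X / (mag + 1e-6 * max(mag))))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  d <- dim(r)
  est <- numeric(2)
  for (ax in 1:2) {
    i <- pk[ax]
    ip <- (i %% d[ax]) + 1L          # next bin, wrapped
    im <- ((i - 2) %% d[ax]) + 1L    # previous bin, wrapped
    y0 <- if (ax == 1) r[im, pk[2]] else r[pk[1], im]
    y1 <- r[pk[1], pk[2]]
    y2 <- if (ax == 1) r[ip, pk[2]] else r[pk[1], ip]
    denom <- y0 - 2 * y1 + y2
    frac <- if (abs(denom) > .Machine$double.eps^0.5)
      0.5 * (y0 - y2) / denom else 0
    frac <- max(min(frac, 0.5), -0.5)
    s <- (i - 1) + frac
    if (s > d[ax] / 2) s <- s - d[ax]  # wrap to signed shift
    est[ax] <- s
  }
  attr(est, "peak") <- max(r)
  est
}

# Integer shift estimate for overlap strips: the phase-correlation surface
# proposes candidate shifts (top peaks, wrap-disambiguated), and direct
# normalized cross-correlation of the actually-overlapping pixels picks the
# winner. This two-stage scheme is the standard grid-stitching practice:
# the correlation surface alone is ambiguous on narrow, smooth strips.
.refine_shift <- function(a, b, max_shift, n_candidates = 8L) {
  d <- dim(a)
  hann <- outer(0.5 * (1 - cos(2 * pi * seq(0, d[1] - 1) / (d[1] - 1))),
                0.5 * (1 - cos(2 * pi * seq(0, d[2] - 1) / (d[2] - 1))))
  X <- .fft2((b - mean(b)) * hann) * Conj(.fft2((a - mean(a)) * hann))
  mag <- Mod(X)
  r <- Re(.ifft2(X / (mag + 1e-6 * max(mag))))
  ord <- order(r, decreasing = TRUE)[seq_len(min(n_candidates, length(r)))]
  cands <- do.call(rbind, lapply(ord, function(i) {
    iy <- (i - 1) %% d[1]; ix <- (i - 1) %/% d[1]
    sy <- if (iy > d[1] / 2) iy - d[1] else iy
    sx <- if (ix > d[2] / 2) ix - d[2] else ix
    c(sy, sx)
  }))
  # the clamp window is small, so also score it exhaustively: narrow smooth
  # strips can hide the true peak below spurious ones
  w <- floor(max_shift)
  cands <- unique(rbind(cands, as.matrix(expand.grid(-w:w, -w:w))))
  best <- c(0, 0); best_score <- -Inf
  for (k in seq_len(nrow(cands))) {
    s <- cands[k, ]
    if (any(abs(s) > max_shift)) next
    # overlap of a[p - s] with b[p]
    ry <- max(1, 1 + s[1]):min(d[1], d[1] + s[1])
    rx <- max(1, 1 + s[2]):min(d[2], d[2] + s[2])
    if (length(ry) < 4 || length(rx) < 4) next
    av <- as.vector(a[ry - s[1], rx - s[2], drop = FALSE])
    bv <- as.vector(b[ry, rx, drop = FALSE])
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
    score <- stats::cor(av, bv)
    if (score > best_score) { best_score <- score; best <- s }
  }
  structure(as.numeric(best), peak = if (is.finite(best_score)) best_score else 0)
}

#' Stitch a grid of tiles into a panoramic mosaic
#'
#' Places every tile at its nominal grid offset (step
#' `round(tile_px * (1 - overlap_frac))`). With `refine = TRUE` each tile's
#' offset is first corrected by phase-correlating its overlap strips
#' against the already-placed top and left neighbours (row-major order);
#' corrections are rounded to whole pixels and clamped at `max_shift`.
#' Overlapping pixels are resolved by the blend mode:
#' \describe{
#'   \item{feather}{weights proportional to 1 + distance to the nearest
#'     tile edge, normalized to sum to one at every mosaic pixel.}
#'   \item{average}{unweighted mean of all covering tiles.}
#'   \item{overwrite}{the last tile placed wins.}
#' }
#'
#' @param tiles list of `rows * cols` matrices in row-major order.
#' @param layout a [make_mosaic_layout()]; its `offsets` give the nominal
#'   placements.
#' @param refine logical; phase-correlation offset refinement.
#' @param blend one of `"feather"`, `"average"`, `"overwrite"`.
#' @param max_shift clamp on refinement corrections per axis, in pixels
#'   (default a tenth of the tile side). Larger estimated shifts are
#'   treated as spurious: a warning is given and the nominal offset kept.
#' @return Object of class `stitch_result`: `mosaic` (the composite),
#'   `offsets_used` (final 0-based placements relative to the mosaic
#'   origin), `refinement_shifts` (per-tile applied corrections).
#' @export
stitch_grid <- function(tiles, layout, refine = FALSE,
                        blend = c("feather", "average", "overwrite"),
                        max_shift = NULL) {
  blend <- match.arg(blend)
  stopifnot(inherits(layout, "mosaic_layout"))
  nt <- layout$rows * layout$cols
  if (length(tiles) != nt)
    stop("expected ", nt, " tiles, got ", length(tiles))
  l <- layout$tile_px
  for (t in tiles) if (!identical(dim(t), c(l, l)))
    stop("all tiles must be tile_px x tile_px")
  if (is.null(max_shift)) max_shift <- 0.1 * l

  # nominal offsets on the regular grid (refinement is measured against
  # these; layout$offsets may carry simulated jitter)
  nominal <- cbind(
    y = (rep(seq_len(layout$rows), each = layout$cols) - 1L) * layout$step,
    x = (rep(seq_len(layout$cols), layout$rows) - 1L) * layout$step)
  offsets <- nominal
  shifts <- matrix(0, nt, 2)

  if (refine && nt > 1) {
    ov <- l - layout$step  # nominal overlap width in pixels
    if (ov < 4) warning("overlap too small for refinement; skipping")
    else for (t in 2:nt) {
      row <- (t - 1) %/% layout$cols + 1; col <- (t - 1) %% layout$cols + 1
      ests <- list()
      if (col > 1) {  # left neighbour: its right strip vs our left strip
        nb <- t - 1
        a <- tiles[[nb]][, (l - ov + 1):l, drop = FALSE]
        b <- tiles[[t]][, 1:ov, drop = FALSE]
        adj <- offsets[nb, ] + c(0, layout$step) - nominal[t, ]
        if (stats::sd(a) > 0 && stats::sd(b) > 0) {
          pc <- .refine_shift(a, b, max_shift)
          e <- adj - pc  # correlation measures neighbour-minus-current shift
          attr(e, "peak") <- attr(pc, "peak")
          ests[[length(ests) + 1]] <- e
        }
      }
      if (row > 1) {  # top neighbour: its bottom strip vs our top strip
        nb <- t - layout$cols
        a <- tiles[[nb]][(l - ov + 1):l, , drop = FALSE]
        b <- tiles[[t]][1:ov, , drop = FALSE]
        adj <- offsets[nb, ] + c(layout$step, 0) - nominal[t, ]
        if (stats::sd(a) > 0 && stats::sd(b) > 0) {
          pc <- .refine_shift(a, b, max_shift)
          e <- adj - pc
          attr(e, "peak") <- attr(pc, "peak")
          ests[[length(ests) + 1]] <- e
        }
      }
      if (length(ests) == 0) next
      pw <- vapply(ests, function(e) attr(e, "peak"), numeric(1))
      s <- round(ests[[which.max(pw)]])
      if (any(abs(s) > max_shift)) {
        warning(sprintf("tile (%d,%d): refinement shift (%g,%g) exceeds clamp %g; using nominal offset",
                        row, col, s[1], s[2], max_shift))
        s <- c(0, 0)
      }
      shifts[t, ] <- s
      offsets[t, ] <- nominal[t, ] + s
    }
  }

  # canvas bounding box
  y0 <- min(offsets[, 1]); x0 <- min(offsets[, 2])
  H <- max(offsets[, 1]) + l - y0; W <- max(offsets[, 2]) + l - x0
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  wt <- switch(blend,
    feather = {
      dedge <- pmin(outer(pmin(seq_len(l), l:1), rep(1, l)),
                    outer(rep(1, l), pmin(seq_len(l), l:1)))
      dedge + 0  # distance to nearest edge, >= 1 so weights never vanish
    },
    average = matrix(1, l, l),
    overwrite = NULL)
  for (t in seq_len(nt)) {
    ry <- (offsets[t, 1] - y0) + seq_len(l)
    rx <- (offsets[t, 2] - x0) + seq_len(l)
    if (blend == "overwrite") {
      acc[ry, rx] <- tiles[[t]]
      wacc[ry, rx] <- 1
    } else {
      acc[ry, rx] <- acc[ry, rx] + wt * tiles[[t]]
      wacc[ry, rx] <- wacc[ry, rx] + wt
    }
  }
  mosaic <- acc
  covered <- wacc > 0
  mosaic[covered] <- acc[covered] / wacc[covered]
  structure(
    list(mosaic = mosaic, offsets_used = offsets,
         refinement_shifts = shifts, blend = blend, layout = layout),
    class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("<stitch_result> mosaic %dx%d from %d tiles, blend '%s', max |shift| %g px\n",
              nrow(x$mosaic), ncol(x$mosaic), nrow(x$offsets_used), x$blend,
              max(abs(x$refinement_shifts))))
  invisible(x)
}
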