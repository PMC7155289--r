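#' Write a mosaic of tile stacks to a directory
#'
#' One multi-page TIFF per tile (`tile_r{row}_c{col}.tif`, one page per
#' phase, 32-bit samples) plus a `layout.yml` sidecar holding the grid
#' geometry, the pattern parameters and the intensity scale. TIFF samples
#' are stored normalized to `[0, 1]`; the common scale factor recorded in
#' the sidecar restores physical intensities on read.
#'
#' @param stacks list of [tile_stack] objects (row-major).
#' @param layout the [make_mosaic_layout()] used.
#' @param dir output directory (created if missing).
#' @param truth optional [scene_truth()]; its parameters go into the
#'   sidecar and, when `write_truth = TRUE`, the ground-truth scene and
#'   vignette are written as `scene.tif` / `vignette.tif` for oracle tests.
#' @param write_truth write ground-truth images as well.
#' @return `dir`, invisibly.
#' @export
write_tile_dir <- function(stacks, layout, dir, truth = NULL,
                           write_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(1e-12, max(vapply(stacks, function(s) max(s$data), numeric(1))))
  for (s in stacks) {
    pages <- lapply(seq_len(dim(s$data)[3]),
                    function(n) s$data[, , n] / scale)
    tiff::writeTIFF(pages, file.path(dir,
      sprintf("tile_r%d_c%d.tif", s$position[1], s$position[2])),
      bits.per.sample = 32L)
  }
  pat <- stacks[[1]]$pattern
  side <- list(
    layout = list(rows = layout$rows, cols = layout$cols,
                  tile_px = layout$tile_px,
                  overlap_frac = layout$overlap_frac,
                  pixel_size_nm = layout$pixel_size_nm),
    pattern = list(period_px = pat$period_px, n_phases = pat$n_phases,
                   orientation_deg = pat$orientation_deg, duty = pat$duty),
    intensity_scale = scale)
  if (!is.null(truth)) {
    side$truth <- list(psf_sigma_px = truth$psf_sigma_px,
                       poisson_scale = truth$poisson_scale,
                       read_noise_sd = truth$read_noise_sd,
                       seed = truth$seed,
                       vignetted = !is.null(truth$vignette_truth))
    if (write_truth) {
      smax <- max(truth$scene, 1e-12)
      tiff::writeTIFF(truth$scene / smax, file.path(dir, "scene.tif"),
                      bits.per.sample = 32L)
      side$truth$scene_scale <- smax
      if (!is.null(truth$vignette_truth))
        tiff::writeTIFF(truth$vignette_truth,
                        file.path(dir, "vignette.tif"),
                        bits.per.sample = 32L)
    }
  }
  yaml::write_yaml(side, file.path(dir, "layout.yml"))
  invisible(dir)
}

#' Read a directory of tile stacks
#'
#' Reads `tile_r{row}_c{col}.tif` multi-page TIFFs plus the `layout.yml`
#' sidecar written by [write_tile_dir()] (or assembled by hand; without a
#' sidecar the grid is inferred from the filenames and `overlap_frac` must
#' be supplied). Fails informatively on missing grid positions or
#' inconsistent page counts.
#'
#' @param dir directory path.
#' @param overlap_frac overlap, only needed when there is no sidecar.
#' @param pixel_size_nm pixel pitch, only needed when there is no sidecar.
#' @return list with `stacks` (row-major list of [tile_stack]) and
#'   `layout` (a [make_mosaic_layout()]).
#' @export
read_tile_dir <- function(dir, overlap_frac = NULL, pixel_size_nm = 216.7) {
  files <- list.files(dir, pattern = "^tile_r\\d+_c\\d+\\.tif$")
  if (length(files) == 0) stop("no tile_r*_c*.tif files in ", dir)
  pos <- do.call(rbind, lapply(files, function(f) {
    as.integer(regmatches(f, gregexpr("\\d+", f))[[1]][1:2])
  }))
  rows <- max(pos[, 1]); cols <- max(pos[, 2])
  want <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  missing <- !paste(want$row, want$col) %in% paste(pos[, 1], pos[, 2])
  if (any(missing))
    stop("missing tile(s) at grid position(s): ",
         paste(sprintf("(%d,%d)", want$row[missing], want$col[missing]),
               collapse = ", "))

  side_path <- file.path(dir, "layout.yml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else NULL
  scale <- if (!is.null(side)) side$intensity_scale else 1
  if (!is.null(side)) {
    overlap_frac <- side$layout$overlap_frac
    pixel_size_nm <- side$layout$pixel_size_nm
  }
  if (is.null(overlap_frac))
    stop("no layout.yml sidecar: overlap_frac must be supplied")

  pages <- lapply(files, function(f)
    tiff::readTIFF(file.path(dir, f), all = TRUE))
  npages <- vapply(pages, length, integer(1))
  if (length(unique(npages)) != 1)
    stop("inconsistent phase counts across tiles: ",
         paste(sprintf("%s has %d", files[npages != npages[1]],
                       npages[npages != npages[1]]), collapse = ", "))
  tile_px <- nrow(pages[[1]][[1]])
  pattern <- if (!is.null(side$pattern)) {
    if (side$pattern$duty >= 1)
      make_uniform_pattern(tile_px, side$pattern$n_phases)
    else
      make_line_patterns(tile_px, side$pattern$period_px,
                         side$pattern$n_phases,
                         side$pattern$orientation_deg)
  } else NULL
  layout <- make_mosaic_layout(rows, cols, tile_px, overlap_frac,
                               pixel_size_nm)
  ord <- order(pos[, 1], pos[, 2])  # row-major
  stacks <- lapply(ord, function(i) {
    data <- simplify2array(pages[[i]]) * scale
    if (is.null(pattern))
      tile_stack(data, pattern_set(lapply(seq_len(dim(data)[3]),
                   function(j) matrix(1, tile_px, tile_px)),
                 period_px = tile_px, duty = 1),
                 pos[i, ], pixel_size_nm)
    else tile_stack(data, pattern, pos[i, ], pixel_size_nm)
  })
  list(stacks = stacks, layout = layout)
}

#' Write a single image as 32-bit TIFF
#'
#' Intensities are stored normalized to `[0, 1]`; the scale is returned
#' (and should be recorded alongside if physical values matter).
#'
#' @param img matrix.
#' @param path output file.
#' @return the scale factor, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  scale <- max(img, 1e-12)
  tiff::writeTIFF(img / scale, path, bits.per.sample = 32L)
  invisible(scale)
}
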