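#' Multimodal NLO image container
#'
#' Bundles the co-registered 2D channels acquired simultaneously for one field
#' of view (FOV): two-photon excited fluorescence (`TPEF`, a.u.), stimulated
#' Raman gain as a normalized modulation (`SRS`, dimensionless ΔI/I),
#' forward- and epi-detected coherent anti-Stokes Raman scattering (`FCARS`,
#' `ECARS`, a.u.) and the linear Stokes transmission (`transmission`).
#' Channels are numeric matrices sharing one raster geometry; pixels are
#' row-major with the origin at the top-left, matching the scan order of the
#' microscope stage.
#'
#' @param channels named list of numeric matrices with identical dimensions.
#' @param pixel_size_um pixel pitch in micrometres (default 0.35, i.e. a
#'   105 um field sampled at 300 px).
#' @param fov_id,condition,time_point optional labels carried into metric rows.
#' @return an object of class `multimodal_image`.
#' @export
multimodal_image <- function(channels, pixel_size_um = 0.35,
                             fov_id = NA_character_, condition = NA_character_,
                             time_point = NA_character_) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("all channels must be numeric matrices")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all channels must share identical dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if ("SRS" %in% names(channels) && !all(is.finite(channels$SRS)))
    stop("SRS channel contains non-finite values")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 fov_id = fov_id, condition = condition,
                 time_point = time_point),
            class = "multimodal_image")
}

#' @export
print.multimodal_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multimodal_image> %d x %d px @ %.3g um/px; channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  fov=%s condition=%s time=%s\n", x$fov_id, x$condition,
              x$time_point))
  invisible(x)
}

#' Binary cell-footprint mask
#'
#' @param mask logical matrix, `TRUE` inside cells.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param warning logical flag set by segmentation when the mask is empty or
#'   the input was degenerate.
#' @return object of class `cell_mask` with precomputed `area_px` and
#'   `area_um2`.
#' @export
cell_mask <- function(mask, pixel_size_um, warning = FALSE) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0)
  area_px <- sum(mask)
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 area_px = area_px,
                 area_um2 = area_px * pixel_size_um^2,
                 warning = isTRUE(warning)),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d px (%.2f um2)%s\n", x$area_px, x$area_um2,
              if (x$warning) " [warning]" else ""))
  invisible(x)
}

#' 3D refractive-index tomogram
#'
#' A reconstructed refractive-index (RI) grid as produced by holotomography,
#' together with its voxel geometry and the RI of the surrounding medium
#' (PBS, 1.3342 by default).
#'
#' @param ri numeric 3D array of refractive indices.
#' @param voxel_size_um numeric length-3 vector `(dx, dy, dz)` in micrometres.
#' @param n_medium background medium RI.
#' @param cell_id,condition,time_point optional labels.
#' @return object of class `tomogram`.
#' @export
tomogram <- function(ri, voxel_size_um, n_medium = 1.3342,
                     cell_id = NA_character_, condition = NA_character_,
                     time_point = NA_character_) {
  stopifnot(is.array(ri), length(dim(ri)) == 3L)
  if (!all(is.finite(ri)) || any(ri < 1))
    stop("RI values must be finite and >= 1")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive numbers (dx, dy, dz)")
  structure(list(ri = ri, voxel_size_um = voxel_size_um, n_medium = n_medium,
                 cell_id = cell_id, condition = condition,
                 time_point = time_point),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf("<tomogram> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um; n_medium=%.4f\n",
              d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3], x$n_medium))
  invisible(x)
}

#' 2D quantitative phase image
#'
#' @param phase numeric matrix of optical phase shifts (radians).
#' @param wavelength_um illumination wavelength in micrometres.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return object of class `qpi_phase_image`.
#' @export
qpi_phase_image <- function(phase, wavelength_um, pixel_size_um) {
  stopifnot(is.matrix(phase), wavelength_um > 0, pixel_size_um > 0)
  structure(list(phase = phase, wavelength_um = wavelength_um,
                 pixel_size_um = pixel_size_um),
            class = "qpi_phase_image")
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
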