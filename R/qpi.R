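# Morphometrics from 3D refractive-index tomograms: segmentation against
# the medium RI, volume, thickness, dry mass (volumetric RI-excess route and
# phase-projection route), and lipid-droplet quantification in the
# 1.40-1.46 RI band.
#
# Dry-mass unit convention: with the RI excess dn (dimensionless), voxel
# volume in um^3 and the refraction increment alpha in ml/g,
# dn * V[um^3] / alpha[ml/g] is directly in picograms
# (1 um^3 / (ml/g) = 1e-12 cm^3 * g/cm^3 = 1 pg).

ALPHA_CELL_ML_PER_G <- 0.19
ALPHA_LIPID_ML_PER_G <- 0.135
LIPID_RI_RANGE <- c(1.40, 1.46)

#' Segment cell voxels from a tomogram
#'
#' Thresholds the RI grid at `n_medium + delta_n`, applies a 3D morphological
#' closing (cube radius 1) and drops 26-connected components smaller than
#' `min_voxels`. All surviving components are kept, one per connected cell.
#'
#' @param tomo a [tomogram()].
#' @param delta_n segmentation margin above the medium RI (default 0.003;
#'   the medium itself is 1.3342 for PBS).
#' @param min_voxels minimum component size.
#' @param closing_radius radius of the closing cube; 0 disables closing.
#' @return logical 3D array with attributes `n_cells` (component count) and
#'   `warning` (`TRUE` when the mask is empty).
#' @export
segment_cell_3d <- function(tomo, delta_n = 0.003, min_voxels = 100L,
                            closing_radius = 1L) {
  stopifnot(inherits(tomo, "tomogram"))
  mask <- tomo$ri > tomo$n_medium + delta_n
  if (!any(mask)) {
    attr(mask, "n_cells") <- 0L
    attr(mask, "warning") <- TRUE
    return(mask)
  }
  if (closing_radius > 0) mask <- close_3d(mask, radius = closing_radius)
  lab <- label_components(mask, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  mask <- array(lab %in% keep, dim(lab))
  attr(mask, "n_cells") <- length(keep)
  attr(mask, "warning") <- !any(mask)
  mask
}

#' Cell volume from a voxel mask
#'
#' @param mask logical 3D array.
#' @param voxel_size_um numeric length-3 `(dx, dy, dz)` in micrometres.
#' @return volume in um^3.
#' @export
cell_volume <- function(mask, voxel_size_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  sum(mask) * prod(voxel_size_um)
}

# xy footprint: columns (x, y) containing at least one masked voxel
footprint_xy <- function(mask) apply(mask, c(1L, 2L), any)

#' Mean cell thickness
#'
#' Volume divided by the projected xy footprint area (the union of all
#' columns containing at least one masked voxel). For a full box this is the
#' box height; for a hemisphere of radius r it approaches `(2/3) r`.
#'
#' @inheritParams cell_volume
#' @return mean thickness in um.
#' @export
mean_thickness <- function(mask, voxel_size_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask")
  fp <- sum(footprint_xy(mask)) * voxel_size_um[1] * voxel_size_um[2]
  cell_volume(mask, voxel_size_um) / fp
}

#' Maximum column thickness
#'
#' Alternative thickness readout: the largest per-column masked voxel count
#' times the axial voxel size.
#'
#' @inheritParams cell_volume
#' @return maximum thickness in um.
#' @export
max_thickness <- function(mask, voxel_size_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask")
  max(apply(mask, c(1L, 2L), sum)) * voxel_size_um[3]
}

#' Dry mass from the volumetric RI excess
#'
#' `DM = sum(ri - n_medium over mask) * voxel_volume / alpha`, in picograms.
#' Negative RI-excess voxels (noise below the medium level inside the mask)
#' contribute zero and their count is reported in the `n_negative` attribute.
#'
#' @param tomo a [tomogram()].
#' @param mask logical 3D array selecting the integration region.
#' @param alpha_ml_per_g refraction increment dn/dc (0.19 ml/g for bulk cell
#'   matter, 0.135 ml/g for lipid).
#' @return dry mass in pg, with attribute `n_negative`.
#' @export
dry_mass_from_ri <- function(tomo, mask, alpha_ml_per_g = ALPHA_CELL_ML_PER_G) {
  stopifnot(inherits(tomo, "tomogram"))
  if (alpha_ml_per_g <= 0) stop("alpha must be positive")
  if (!identical(dim(mask), dim(tomo$ri))) stop("mask and grid dimensions differ")
  dn <- tomo$ri[mask] - tomo$n_medium
  neg <- dn < 0
  dn[neg] <- 0
  out <- sum(dn) * prod(tomo$voxel_size_um) / alpha_ml_per_g
  attr(out, "n_negative") <- sum(neg)
  out
}

#' Dry mass from a 2D phase image
#'
#' `DM = lambda / (2 * pi * alpha) * sum(phase) * pixel_area`, in picograms
#' (lengths in um). On a noise-free phantom whose phase is the projected RI
#' excess, `phase = (2*pi/lambda) * sum_z (ri - n_medium) * dz`, this equals
#' the volumetric route [dry_mass_from_ri()].
#'
#' @param ph a [qpi_phase_image()].
#' @param alpha_ml_per_g refraction increment dn/dc.
#' @return dry mass in pg.
#' @export
dry_mass_from_phase <- function(ph, alpha_ml_per_g = ALPHA_CELL_ML_PER_G) {
  stopifnot(inherits(ph, "qpi_phase_image"))
  if (alpha_ml_per_g <= 0) stop("alpha must be positive")
  ph$wavelength_um / (2 * pi * alpha_ml_per_g) *
    sum(ph$phase) * ph$pixel_size_um^2
}

#' Project a tomogram to a phase image
#'
#' Computes the optical phase shift a plane wave of wavelength
#' `wavelength_um` accumulates through the RI grid:
#' `phase(x, y) = (2*pi/lambda) * sum_z (ri - n_medium) * dz`. Used to
#' cross-validate the two dry-mass routes on phantoms.
#'
#' @param tomo a [tomogram()].
#' @param wavelength_um illumination wavelength (um).
#' @param mask optional logical 3D array restricting the projection.
#' @return a [qpi_phase_image()].
#' @export
phase_from_tomogram <- function(tomo, wavelength_um = 0.532, mask = NULL) {
  stopifnot(inherits(tomo, "tomogram"))
  dn <- tomo$ri - tomo$n_medium
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(tomo$ri)))
    dn[!mask] <- 0
  }
  opl <- apply(dn, c(1L, 2L), sum) * tomo$voxel_size_um[3]
  qpi_phase_image(2 * pi / wavelength_um * opl, wavelength_um,
                  pixel_size_um = tomo$voxel_size_um[1])
}

#' Segment and quantify lipid droplets in a tomogram
#'
#' Lipid droplets have a distinctly high RI; voxels of the cell mask whose
#' RI lies in the inclusive band `ri_range` (default 1.40-1.46) are taken as
#' lipid. Volume is the voxel count times the voxel volume; dry mass uses
#' the lipid refraction increment 0.135 ml/g.
#'
#' @param tomo a [tomogram()].
#' @param cell_mask logical 3D array of cell voxels.
#' @param ri_range inclusive RI band for lipid.
#' @param alpha_ml_per_g lipid refraction increment.
#' @return list with `mask` (logical 3D array), `lipid_volume_um3`,
#'   `lipid_dry_mass_pg`.
#' @export
segment_lipid <- function(tomo, cell_mask, ri_range = LIPID_RI_RANGE,
                          alpha_ml_per_g = ALPHA_LIPID_ML_PER_G) {
  stopifnot(inherits(tomo, "tomogram"),
            identical(dim(cell_mask), dim(tomo$ri)))
  lm <- cell_mask & tomo$ri >= ri_range[1] & tomo$ri <= ri_range[2]
  vol <- cell_volume(lm, tomo$voxel_size_um)
  dm <- if (any(lm)) as.numeric(dry_mass_from_ri(tomo, lm, alpha_ml_per_g)) else 0
  list(mask = lm, lipid_volume_um3 = vol, lipid_dry_mass_pg = dm)
}

#' Compute the full QPI metric row for one tomogram
#'
#' Segments the cell, then reports volume, projected area, mean thickness,
#' dry mass (volumetric route, dn/dc 0.19 ml/g) and the lipid-droplet
#' volume and dry mass (RI band 1.40-1.46, dn/dc 0.135 ml/g).
#'
#' @param tomo a [tomogram()].
#' @param delta_n,min_voxels passed to [segment_cell_3d()].
#' @return one-row data frame; zeroed metrics with `mask_warning = TRUE`
#'   when no cell is found.
#' @export
qpi_metrics <- function(tomo, delta_n = 0.003, min_voxels = 100L) {
  stopifnot(inherits(tomo, "tomogram"))
  keys <- data.frame(cell_id = tomo$cell_id, condition = tomo$condition,
                     time_point = tomo$time_point, stringsAsFactors = FALSE)
  mask <- segment_cell_3d(tomo, delta_n = delta_n, min_voxels = min_voxels)
  if (attr(mask, "warning"))
    return(cbind(keys, data.frame(
      volume_um3 = 0, projected_area_um2 = 0, mean_thickness_um = NA_real_,
      dry_mass_pg = 0, lipid_volume_um3 = 0, lipid_dry_mass_pg = 0,
      n_cells = 0L, mask_warning = TRUE)))
  vs <- tomo$voxel_size_um
  lip <- segment_lipid(tomo, mask)
  cbind(keys, data.frame(
    volume_um3 = cell_volume(mask, vs),
    projected_area_um2 = sum(footprint_xy(mask)) * vs[1] * vs[2],
    mean_thickness_um = mean_thickness(mask, vs),
    dry_mass_pg = as.numeric(dry_mass_from_ri(tomo, mask)),
    lipid_volume_um3 = lip$lipid_volume_um3,
    lipid_dry_mass_pg = lip$lipid_dry_mass_pg,
    n_cells = attr(mask, "n_cells"),
    mask_warning = FALSE))
}
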