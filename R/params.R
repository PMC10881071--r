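#' Phenotype parameters for the synthetic-data generator
#'
#' Describes one experimental condition (untreated control vs therapy-induced
#' senescent, TIS) at one time point, for either the multimodal NLO field of
#' view generator ([generate_nlo_fov()]) or the RI tomogram generator
#' ([generate_qpi_tomogram()]). Defaults describe a proliferating HepG2-like
#' control culture; [nlo_preset()] and [qpi_preset()] return per-time-point
#' parameter sets whose metric targets track the senescence phenotype
#' (mitochondrial signal condensing into puncta, lipid droplets accumulating
#' from 72 h, cells enlarging and flattening).
#'
#' @param condition `"control"` or `"TIS"`.
#' @param time_point free label, e.g. `"0h"`, `"24h"`, `"72h"`, `"7d"`.
#' @param modality `"nlo"` (2D multichannel FOV) or `"qpi"` (3D RI tomogram).
#' @param n_cells_per_fov number of cells to place.
#' @param cell_radius_um mean in-plane cell radius (um).
#' @param cell_thickness_um cell thickness (um); used by the tomogram
#'   generator only (ellipsoid z extent).
#' @param tpef_pattern `"diffuse_perinuclear"` (wide perinuclear annulus) or
#'   `"punctate"` (small dense puncta).
#' @param tpef_area_frac_target fraction of the cell area carrying
#'   above-threshold TPEF signal.
#' @param tpef_peak TPEF amplitude painted on the pattern (a.u.).
#' @param tpef_base diffuse cytoplasmic TPEF level (a.u.), kept below the
#'   0.25 a.u. analysis threshold.
#' @param droplet_density_per_cell mean lipid droplet count per cell
#'   (Poisson).
#' @param droplet_radius_um length-2 `(mean, sd)` of droplet radius (um).
#' @param droplet_srs_amp SRS amplitude of a droplet, in ΔI/I units.
#' @param droplet_fcars_amp F-CARS amplitude of a droplet (a.u.).
#' @param fcars_speckle_frac fraction of the cell area covered by dim
#'   F-CARS-only speckles: sub-resolution lipid accumulations whose
#'   vibrational signal is amplified by the nonresonant background but too
#'   weak to register in SRS. Present in both conditions.
#' @param nrb_level nonresonant four-wave-mixing background painted on the
#'   F-CARS channel inside cells (a.u.).
#' @param noise_sd named per-channel additive Gaussian noise SD
#'   (`TPEF`, `SRS`, `FCARS`, `ECARS`, `transmission`); for `"qpi"` the
#'   single element `ri` is the RI noise inside the cell.
#' @param outlier_rate fraction of pixels per channel replaced by 1-pixel
#'   cosmic-ray-like outliers.
#' @param serpentine_shift_px integer circular shift applied to even-indexed
#'   scan rows (0-based), emulating stage serpentine distortion.
#' @param lipid_ri,cell_ri,background_ri refractive-index ranges/values for
#'   the tomogram generator.
#' @param droplet_clusters_per_cell mean number of droplet cluster centers
#'   per cell; droplets scatter around these centers.
#' @param droplet_cluster_sd_um spatial SD of droplets around their cluster
#'   center (um).
#' @param fov_px side of the square NLO raster in pixels.
#' @param pixel_size_um NLO pixel pitch (um); 0.35 reproduces a 105 um field
#'   at 300 px.
#' @param qpi_grid integer length-3 tomogram grid `(nx, ny, nz)`; the default
#'   is the instrument's 848 x 848 x 210 grid downscaled 4x.
#' @param qpi_fov_um physical tomogram extent (um) fixed at
#'   80.470 x 80.470 x 39.666.
#' @param cell_radius_jitter relative SD of per-cell radius jitter.
#' @param fov_jitter_sd relative (log-normal) SD of a per-FOV multiplier on
#'   droplet density and TPEF targets, emulating plate-to-plate variability.
#' @return validated object of class `phenotype_params`.
#' @export
phenotype_params <- function(condition = c("control", "TIS"),
                             time_point = "0h",
                             modality = c("nlo", "qpi"),
                             n_cells_per_fov = 8L,
                             cell_radius_um = 8,
                             cell_thickness_um = 11,
                             tpef_pattern = c("diffuse_perinuclear", "punctate"),
                             tpef_area_frac_target = 0.15,
                             tpef_peak = 1.0,
                             tpef_base = 0.1,
                             droplet_density_per_cell = 1.0,
                             droplet_radius_um = c(0.35, 0.08),
                             droplet_srs_amp = 1e-3,
                             droplet_fcars_amp = 1.0,
                             fcars_speckle_frac = 0.015,
                             nrb_level = 0.2,
                             noise_sd = c(TPEF = 0.02, SRS = 2e-5, FCARS = 0.02,
                                          ECARS = 0.02, transmission = 0.01),
                             outlier_rate = 5e-4,
                             serpentine_shift_px = 0L,
                             lipid_ri = c(1.40, 1.46),
                             cell_ri = c(1.345, 1.358),
                             background_ri = 1.3342,
                             droplet_clusters_per_cell = 1.0,
                             droplet_cluster_sd_um = 1.0,
                             fov_px = 300L,
                             pixel_size_um = 0.35,
                             qpi_grid = c(212L, 212L, 64L),
                             qpi_fov_um = c(80.470, 80.470, 39.666),
                             cell_radius_jitter = 0.10,
                             fov_jitter_sd = 0.15) {
  condition <- match.arg(condition)
  modality <- match.arg(modality)
  tpef_pattern <- match.arg(tpef_pattern)
  stopifnot(n_cells_per_fov >= 0, cell_radius_um > 0, cell_thickness_um > 0,
            tpef_peak > 0, tpef_base >= 0,
            droplet_density_per_cell >= 0,
            length(droplet_radius_um) == 2L, droplet_radius_um[1] > 0,
            droplet_radius_um[2] >= 0,
            droplet_srs_amp > 0, droplet_fcars_amp > 0, nrb_level >= 0,
            fov_px >= 16L, pixel_size_um > 0,
            length(qpi_grid) == 3L, all(qpi_grid >= 8),
            length(qpi_fov_um) == 3L, all(qpi_fov_um > 0),
            droplet_clusters_per_cell > 0, droplet_cluster_sd_um > 0,
            cell_radius_jitter >= 0, fov_jitter_sd >= 0)
  frac_in_01 <- function(x) all(x >= 0 & x <= 1)
  if (!frac_in_01(tpef_area_frac_target) || !frac_in_01(outlier_rate))
    stop("fractions and rates must lie in [0, 1]")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (length(lipid_ri) != 2L || lipid_ri[1] > lipid_ri[2] ||
      lipid_ri[1] < 1.33 || lipid_ri[2] > 1.50)
    stop("lipid_ri must be an increasing range within [1.33, 1.50]")
  if (length(cell_ri) != 2L || cell_ri[1] > cell_ri[2] || cell_ri[1] <= background_ri)
    stop("cell_ri must be an increasing range above background_ri")
  serpentine_shift_px <- as.integer(serpentine_shift_px)
  structure(list(condition = condition, time_point = time_point,
                 modality = modality,
                 n_cells_per_fov = as.integer(n_cells_per_fov),
                 cell_radius_um = cell_radius_um,
                 cell_thickness_um = cell_thickness_um,
                 tpef_pattern = tpef_pattern,
                 tpef_area_frac_target = tpef_area_frac_target,
                 tpef_peak = tpef_peak, tpef_base = tpef_base,
                 droplet_density_per_cell = droplet_density_per_cell,
                 droplet_radius_um = droplet_radius_um,
                 droplet_srs_amp = droplet_srs_amp,
                 droplet_fcars_amp = droplet_fcars_amp,
                 fcars_speckle_frac = fcars_speckle_frac,
                 nrb_level = nrb_level, noise_sd = noise_sd,
                 outlier_rate = outlier_rate,
                 serpentine_shift_px = serpentine_shift_px,
                 lipid_ri = lipid_ri, cell_ri = cell_ri,
                 background_ri = background_ri,
                 droplet_clusters_per_cell = droplet_clusters_per_cell,
                 droplet_cluster_sd_um = droplet_cluster_sd_um,
                 fov_px = as.integer(fov_px), pixel_size_um = pixel_size_um,
                 qpi_grid = as.integer(qpi_grid), qpi_fov_um = qpi_fov_um,
                 cell_radius_jitter = cell_radius_jitter,
                 fov_jitter_sd = fov_jitter_sd),
            class = "phenotype_params")
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf("<phenotype_params> %s @ %s (%s): %d cells, r=%.1f um, tpef=%s %.0f%%, droplets=%.1f/cell\n",
              x$condition, x$time_point, x$modality, x$n_cells_per_fov,
              x$cell_radius_um, x$tpef_pattern,
              100 * x$tpef_area_frac_target, x$droplet_density_per_cell))
  invisible(x)
}

# Named preset tables. Targets track the published time-course trends
# qualitatively: TPEF-positive area shrinking from ~15% to ~4% of the cell
# while the signal condenses into brighter puncta (aggregation index up),
# lipid droplets appearing at 72 h (~3% of cell area) and peaking at 7 days
# (~20%, larger droplets, more clusters); TIS cells enlarging and flattening
# in the tomograms, with dry mass and lipid content rising.
nlo_preset_table <- list(
  control = list(
    "0h"  = list(),
    "12h" = list(),
    "24h" = list(),
    "72h" = list(),
    "7d"  = list()
  ),
  TIS = list(
    "0h"  = list(),
    "12h" = list(tpef_pattern = "punctate", tpef_area_frac_target = 0.12,
                 tpef_peak = 1.3, tpef_base = 0.12),
    "24h" = list(tpef_pattern = "punctate", tpef_area_frac_target = 0.08,
                 tpef_peak = 4.0, tpef_base = 0.14, cell_radius_um = 9,
                 droplet_density_per_cell = 2),
    "72h" = list(tpef_pattern = "punctate", tpef_area_frac_target = 0.06,
                 tpef_peak = 7.0, tpef_base = 0.16, cell_radius_um = 10,
                 n_cells_per_fov = 6L, droplet_density_per_cell = 12,
                 droplet_radius_um = c(0.45, 0.10),
                 droplet_clusters_per_cell = 3),
    "7d"  = list(tpef_pattern = "punctate", tpef_area_frac_target = 0.04,
                 tpef_peak = 20.0, tpef_base = 0.18, cell_radius_um = 10.5,
                 n_cells_per_fov = 5L, droplet_density_per_cell = 45,
                 droplet_radius_um = c(0.67, 0.12),
                 droplet_clusters_per_cell = 6,
                 droplet_cluster_sd_um = 1.6)
  )
)

qpi_preset_table <- list(
  control = list(
    "0h" = list(), "24h" = list(), "48h" = list(), "72h" = list(), "7d" = list()
  ),
  TIS = list(
    "0h"  = list(),
    "24h" = list(cell_radius_um = 10.5, cell_thickness_um = 10.5,
                 cell_ri = c(1.348, 1.362), droplet_density_per_cell = 3),
    "48h" = list(cell_radius_um = 11.5, cell_thickness_um = 10,
                 cell_ri = c(1.350, 1.365), droplet_density_per_cell = 6,
                 droplet_radius_um = c(0.9, 0.15)),
    "72h" = list(cell_radius_um = 13.5, cell_thickness_um = 9.25,
                 cell_ri = c(1.352, 1.368), droplet_density_per_cell = 12,
                 droplet_radius_um = c(1.0, 0.15)),
    "7d"  = list(cell_radius_um = 15.5, cell_thickness_um = 8.25,
                 cell_ri = c(1.355, 1.370), droplet_density_per_cell = 24,
                 droplet_radius_um = c(1.2, 0.18))
  )
)

#' Named phenotype presets for the NLO and QPI generators
#'
#' Return a [phenotype_params()] object whose targets follow the published
#' control/TIS time-course trends. NLO time points: `"0h"`, `"12h"`, `"24h"`,
#' `"72h"`, `"7d"`; QPI time points: `"0h"`, `"24h"`, `"48h"`, `"72h"`,
#' `"7d"`. At `"0h"` the TIS preset equals the control preset (treatment has
#' had no time to act), so time-zero comparisons are null by construction.
#'
#' @param condition `"control"` or `"TIS"`.
#' @param time_point one of the modality's time points.
#' @param ... overrides forwarded to [phenotype_params()].
#' @return a `phenotype_params` object.
#' @export
nlo_preset <- function(condition = c("control", "TIS"), time_point = "0h", ...) {
  condition <- match.arg(condition)
  tp <- nlo_preset_table[[condition]]
  if (!time_point %in% names(tp))
    stop(sprintf("unknown NLO time point '%s' (have: %s)", time_point,
                 paste(names(tp), collapse = ", ")))
  args <- tp[[time_point]]
  args$condition <- condition
  args$time_point <- time_point
  args$modality <- "nlo"
  do.call(phenotype_params, utils::modifyList(args, list(...)))
}

#' @rdname nlo_preset
#' @export
qpi_preset <- function(condition = c("control", "TIS"), time_point = "0h", ...) {
  condition <- match.arg(condition)
  tp <- qpi_preset_table[[condition]]
  if (!time_point %in% names(tp))
    stop(sprintf("unknown QPI time point '%s' (have: %s)", time_point,
                 paste(names(tp), collapse = ", ")))
  base <- list(modality = "qpi", n_cells_per_fov = 1L,
               cell_radius_um = 9, cell_thickness_um = 11,
               droplet_density_per_cell = 2,
               droplet_radius_um = c(0.8, 0.12),
               noise_sd = c(ri = 0.0015))
  args <- utils::modifyList(base, tp[[time_point]])
  args$condition <- condition
  args$time_point <- time_point
  do.call(phenotype_params, utils::modifyList(args, list(...)))
}
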