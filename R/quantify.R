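# Per-FOV NLO metrics: cell footprint segmentation from the linear
# transmission, TPEF mitochondrial indices, and SRS lipid-droplet particle
# analysis with the 5 px^2 size / 0.3-1 circularity filter.

#' Segment the cell footprint from the linear transmission channel
#'
#' Cells attenuate the Stokes beam, so they appear as relatively dark regions
#' against the bright substrate. The mask is the below-Otsu-threshold region,
#' cleaned by morphological closing, hole filling and removal of small
#' components.
#'
#' @param transmission numeric matrix (linear Stokes transmission).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param closing_radius radius (px) of the disc used for closing.
#' @param min_area_px components smaller than this are dropped.
#' @return a [cell_mask()]; for a constant raster an empty mask with the
#'   `warning` flag set.
#' @export
segment_cells <- function(transmission, pixel_size_um = 0.35,
                          closing_radius = 2L, min_area_px = 50L) {
  stopifnot(is.matrix(transmission))
  rg <- range(transmission)
  if (diff(rg) == 0)
    return(cell_mask(matrix(FALSE, nrow(transmission), ncol(transmission)),
                     pixel_size_um, warning = TRUE))
  norm <- (transmission - rg[1]) / diff(rg)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm < thr                      # dark regions are cells
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
  }
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  mask <- matrix(as.logical(mask), nrow(transmission), ncol(transmission))
  if (min_area_px > 0 && any(mask)) {
    lab <- label_components(mask, connectivity = 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  cell_mask(mask, pixel_size_um, warning = !any(mask))
}

assert_mask <- function(channel, mask) {
  stopifnot(is.matrix(channel), inherits(mask, "cell_mask"))
  if (!identical(dim(channel), dim(mask$mask)))
    stop("channel and mask dimensions differ")
  if (mask$area_px == 0L) stop("empty cell mask")
}

#' Percentage of the cell area above a threshold
#'
#' `100 * |{in-mask pixels with value > threshold}| / |mask|`, with a strict
#' inequality: pixels exactly at the threshold do not count. With the
#' universal TPEF threshold of 0.25 a.u. this is the
#' Area(TPEF)/Area(Cell) index; with the SRS threshold of 2.2e-4 ΔI/I it is
#' the lipid-covered-area index.
#'
#' @param channel numeric matrix.
#' @param mask a nonempty [cell_mask()].
#' @param threshold scalar threshold.
#' @return percentage in `[0, 100]`.
#' @export
area_fraction_pct <- function(channel, mask, threshold) {
  assert_mask(channel, mask)
  100 * sum(channel[mask$mask] > threshold) / mask$area_px
}

#' Mean of the top decile of in-mask pixel values
#'
#' A robust stand-in for the channel maximum: the average of the
#' `ceiling(0.1 * |mask|)` highest in-mask pixel values. Used as Max(TPEF)
#' in the aggregation index so that single hot pixels (already median
#' filtered) cannot dominate.
#'
#' @inheritParams area_fraction_pct
#' @return scalar mean of the top-decile values.
#' @export
top_decile_max <- function(channel, mask) {
  assert_mask(channel, mask)
  v <- channel[mask$mask]
  k <- ceiling(0.1 * length(v))
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Mitochondrial aggregation index
#'
#' `Max(TPEF) x [Area(TPEF)/Area(Cell)]%`, the product of the top-decile
#' TPEF maximum ([top_decile_max()]) and the TPEF-positive percentage of the
#' cell area ([area_fraction_pct()]). It rises when coenzyme fluorescence
#' condenses into dense puncta; units are a.u. x percent.
#'
#' @inheritParams area_fraction_pct
#' @param threshold TPEF threshold (default 0.25 a.u.).
#' @return scalar index.
#' @export
aggregation_index <- function(channel, mask, threshold = 0.25) {
  top_decile_max(channel, mask) * area_fraction_pct(channel, mask, threshold)
}

#' Mean in-mask intensity
#'
#' Arithmetic mean of the channel over the cell mask, without thresholding.
#' For TPEF this tracks the average NAD(P)H/FAD level, a metabolic readout.
#'
#' @inheritParams area_fraction_pct
#' @return scalar mean.
#' @export
mean_intensity <- function(channel, mask) {
  assert_mask(channel, mask)
  mean(channel[mask$mask])
}

#' Detect lipid droplets in the SRS channel
#'
#' Thresholds the in-mask ΔI/I raster, labels connected components
#' (8-connected by default, the ImageJ convention) and measures per-component
#' area, crack-edge perimeter, circularity `4*pi*A/P^2` and centroid.
#' Components with area below `min_area_px` are discarded. Every remaining
#' component is a lipid *cluster*; those whose circularity (clamped at 1
#' before the test) falls within `circ_range` are additionally flagged
#' `quasi_single` -- beads regular enough to be read as single vesicles.
#'
#' @param srs numeric matrix of normalized ΔI/I values.
#' @param mask a nonempty [cell_mask()].
#' @param threshold ΔI/I threshold separating dense vesicles from diffuse
#'   cytoplasmic lipid (default 2.2e-4).
#' @param min_area_px minimum particle size in px^2 (default 5).
#' @param circ_range circularity window for the quasi-single flag
#'   (default `c(0.3, 1)`).
#' @param connectivity 8 (default) or 4.
#' @return a `droplet_set`: data frame with columns `label`, `area_px`,
#'   `area_um2`, `perimeter_px`, `circularity`, `centroid_row`,
#'   `centroid_col`, `quasi_single`; pixel size kept as an attribute.
#' @export
detect_droplets <- function(srs, mask, threshold = 2.2e-4, min_area_px = 5L,
                            circ_range = c(0.3, 1.0), connectivity = 8L) {
  assert_mask(srs, mask)
  binary <- srs > threshold & mask$mask
  lab <- label_components(binary, connectivity = connectivity)
  shapes <- component_shapes(lab)
  shapes <- shapes[shapes$area_px >= min_area_px, , drop = FALSE]
  shapes$area_um2 <- shapes$area_px * mask$pixel_size_um^2
  circ_clamped <- pmin(shapes$circularity, 1.0)
  shapes$quasi_single <- circ_clamped >= circ_range[1] & circ_clamped <= circ_range[2]
  rownames(shapes) <- NULL
  structure(shapes[, c("label", "area_px", "area_um2", "perimeter_px",
                       "circularity", "centroid_row", "centroid_col",
                       "quasi_single")],
            pixel_size_um = mask$pixel_size_um,
            class = c("droplet_set", "data.frame"))
}

#' Summarize a droplet set into per-FOV lipid metrics
#'
#' @param droplets a `droplet_set` from [detect_droplets()].
#' @param mask the [cell_mask()] the droplets were detected in.
#' @return list with `srs_area_pct` (percentage of the cell area covered by
#'   clusters), `mean_quasi_single_area_um2` (`NA` when no quasi-single
#'   droplet exists -- reported as missing, not zero), `cluster_count` and
#'   `clusters_per_cell_area` (count per um^2 of cell).
#' @export
droplet_summaries <- function(droplets, mask) {
  stopifnot(inherits(droplets, "droplet_set"), inherits(mask, "cell_mask"))
  if (mask$area_px == 0L) stop("empty cell mask")
  qs <- droplets$area_um2[droplets$quasi_single]
  list(srs_area_pct = 100 * sum(droplets$area_px) / mask$area_px,
       mean_quasi_single_area_um2 = if (length(qs)) mean(qs) else NA_real_,
       cluster_count = nrow(droplets),
       clusters_per_cell_area = nrow(droplets) / mask$area_um2)
}

#' Compute the full per-FOV NLO metric row
#'
#' Segments the cell footprint from the transmission channel, then computes
#' the TPEF indices (area fraction, top-decile maximum, aggregation index,
#' mean intensity) and the SRS lipid metrics on the union cell mask.
#'
#' @param image a preprocessed [multimodal_image()].
#' @param mask optional precomputed [cell_mask()]; segmented from the
#'   transmission channel when `NULL`.
#' @param tpef_threshold TPEF threshold (a.u.).
#' @param srs_threshold SRS ΔI/I threshold.
#' @param ... passed to [detect_droplets()].
#' @return one-row data frame of metrics keyed by `fov_id`, `condition`,
#'   `time_point`; all metric columns `NA` (with `mask_warning = TRUE`) when
#'   segmentation found no cells.
#' @export
nlo_metrics <- function(image, mask = NULL, tpef_threshold = 0.25,
                        srs_threshold = 2.2e-4, ...) {
  stopifnot(inherits(image, "multimodal_image"))
  need <- c("TPEF", "SRS", "transmission")
  if (!all(need %in% names(image$channels)))
    stop("image must contain channels: ", paste(need, collapse = ", "))
  if (is.null(mask))
    mask <- segment_cells(image$channels$transmission,
                          pixel_size_um = image$pixel_size_um)
  keys <- data.frame(fov_id = image$fov_id, condition = image$condition,
                     time_point = image$time_point,
                     stringsAsFactors = FALSE)
  if (mask$area_px == 0L)
    return(cbind(keys, data.frame(
      cell_area_um2 = 0, tpef_area_pct = NA_real_, tpef_top_decile = NA_real_,
      aggregation_index = NA_real_, tpef_mean = NA_real_,
      srs_area_pct = NA_real_, mean_quasi_single_area_um2 = NA_real_,
      cluster_count = NA_integer_, clusters_per_cell_area = NA_real_,
      mask_warning = TRUE)))
  tpef <- image$channels$TPEF
  drops <- detect_droplets(image$channels$SRS, mask, threshold = srs_threshold, ...)
  ds <- droplet_summaries(drops, mask)
  cbind(keys, data.frame(
    cell_area_um2 = mask$area_um2,
    tpef_area_pct = area_fraction_pct(tpef, mask, tpef_threshold),
    tpef_top_decile = top_decile_max(tpef, mask),
    aggregation_index = aggregation_index(tpef, mask, tpef_threshold),
    tpef_mean = mean_intensity(tpef, mask),
    srs_area_pct = ds$srs_area_pct,
    mean_quasi_single_area_um2 = ds$mean_quasi_single_area_um2,
    cluster_count = ds$cluster_count,
    clusters_per_cell_area = ds$clusters_per_cell_area,
    mask_warning = mask$warning))
}
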