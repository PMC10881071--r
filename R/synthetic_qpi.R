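# Synthetic refractive-index tomogram generator.
#
# Cells are axis-aligned ellipsoids of constant RI sitting near the bottom
# of the grid, embedding spherical lipid droplets whose RI falls in the
# 1.40-1.46 band. The background is exactly the medium RI, and optional
# Gaussian RI noise is confined to the cell interior so segmentation against
# the exact background stays well defined. Ground truth records the analytic
# volume, mean thickness and dry mass implied by the painted geometry.

# voxel-center coordinates (um) along one axis
axis_coords <- function(n_vox, extent_um) {
  dv <- extent_um / n_vox
  (seq_len(n_vox) - 0.5) * dv
}

#' Generate one synthetic RI tomogram
#'
#' @param params a [phenotype_params()] object with `modality = "qpi"`. Cell
#'   shape is an ellipsoid with in-plane semi-axes `cell_radius_um` (jittered
#'   per cell) and vertical semi-axis `cell_thickness_um / 2`; when
#'   `cell_thickness_um == 2 * cell_radius_um` the cell is a sphere.
#' @param seed integer seed; identical `(params, seed)` give identical grids.
#' @return list of class `qpi_tomogram` with `tomo` (a [tomogram()]) and
#'   `truth` holding per-cell analytic volume (um^3), mean thickness (um),
#'   dry mass (pg, cell matter at dn/dc 0.19 ml/g plus lipid at 0.135 ml/g),
#'   lipid sphere geometry, and the seed.
#' @export
generate_qpi_tomogram <- function(params, seed) {
  stopifnot(inherits(params, "phenotype_params"))
  if (missing(seed)) stop("a seed is required")
  with_local_seed(seed, generate_qpi_tomogram_impl(params, seed))
}

generate_qpi_tomogram_impl <- function(params, seed) {
  gd <- params$qpi_grid
  fov <- params$qpi_fov_um
  voxel <- fov / gd
  vox_vol <- prod(voxel)
  ri <- array(params$background_ri, gd)
  xs <- axis_coords(gd[1], fov[1])
  ys <- axis_coords(gd[2], fov[2])
  zs <- axis_coords(gd[3], fov[3])

  jf <- if (params$fov_jitter_sd > 0) exp(stats::rnorm(1, 0, params$fov_jitter_sd)) else 1

  n_cells <- params$n_cells_per_fov
  cells <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0), a_um = numeric(0), b_um = numeric(0),
                      c_um = numeric(0), ri = numeric(0),
                      volume_um3 = numeric(0), mean_thickness_um = numeric(0))
  attempts <- 0L
  while (nrow(cells) < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(1L, n_cells))
      stop("could not place ", n_cells, " non-overlapping cells in the grid",
           call. = FALSE)
    a <- params$cell_radius_um * exp(stats::rnorm(1, 0, params$cell_radius_jitter)) * jf
    b <- params$cell_radius_um * exp(stats::rnorm(1, 0, params$cell_radius_jitter)) * jf
    cth <- params$cell_thickness_um * exp(stats::rnorm(1, 0, params$cell_radius_jitter / 2))
    cc <- cth / 2
    if (2 * max(a, b) + 2 > min(fov[1], fov[2]) || cth + 2 > fov[3]) next
    cx <- stats::runif(1, a + 1, fov[1] - a - 1)
    cy <- stats::runif(1, b + 1, fov[2] - b - 1)
    cz <- cc + 1  # adherent: sitting just above the substrate
    if (nrow(cells) > 0) {
      dd <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(dd < pmax(cells$a_um, cells$b_um) + max(a, b) + 0.5)) next
    }
    cri <- stats::runif(1, params$cell_ri[1], params$cell_ri[2])
    cells <- rbind(cells, data.frame(
      cell = nrow(cells) + 1L, cx = cx, cy = cy, cz = cz,
      a_um = a, b_um = b, c_um = cc, ri = cri,
      volume_um3 = 4 / 3 * pi * a * b * cc,
      mean_thickness_um = 4 / 3 * cc))
  }

  lipids <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                       cz = numeric(0), r_um = numeric(0), ri = numeric(0))
  cell_mask_true <- array(FALSE, gd)
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    rho2 <- outer(outer(((xs - ce$cx) / ce$a_um)^2,
                        ((ys - ce$cy) / ce$b_um)^2, "+"),
                  ((zs - ce$cz) / ce$c_um)^2, "+")
    inside <- rho2 <= 1
    ri[inside] <- ce$ri
    cell_mask_true <- cell_mask_true | inside

    n_lip <- stats::rpois(1, params$droplet_density_per_cell * jf)
    for (l in seq_len(n_lip)) {
      ok <- FALSE
      for (try in 1:100) {
        r_um <- max(0.3, stats::rnorm(1, params$droplet_radius_um[1],
                                      params$droplet_radius_um[2]))
        # sample a center whose whole sphere fits inside the ellipsoid:
        # shrink the ellipsoid by r along each axis
        sa <- ce$a_um - r_um; sb <- ce$b_um - r_um; sc <- ce$c_um - r_um
        if (sa <= 0 || sb <= 0 || sc <= 0) next
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        lx <- ce$cx + u[1] * sa; ly <- ce$cy + u[2] * sb; lz <- ce$cz + u[3] * sc
        ok <- TRUE
        break
      }
      if (!ok)
        stop("failed to place a lipid sphere inside the cell after retries",
             call. = FALSE)
      lri <- stats::runif(1, params$lipid_ri[1], params$lipid_ri[2])
      d2 <- outer(outer((xs - lx)^2, (ys - ly)^2, "+"), (zs - lz)^2, "+")
      ri[d2 <= r_um^2] <- lri
      lipids <- rbind(lipids, data.frame(cell = ce$cell, cx = lx, cy = ly,
                                         cz = lz, r_um = r_um, ri = lri))
    }
  }

  sd_ri <- if ("ri" %in% names(params$noise_sd)) params$noise_sd[["ri"]] else 0
  if (!is.na(sd_ri) && sd_ri > 0) {
    idx <- which(cell_mask_true)
    ri[idx] <- pmax(1.0, ri[idx] + stats::rnorm(length(idx), 0, sd_ri))
  }

  # analytic ground truth (lipid spheres may overlap; treated as disjoint,
  # overlaps are rare for the default densities and noted as approximation)
  alpha_cell <- 0.19; alpha_lipid <- 0.135
  lip_vol <- if (nrow(lipids)) 4 / 3 * pi * lipids$r_um^3 else numeric(0)
  cell_dn <- cells$ri - params$background_ri
  lip_dn <- if (nrow(lipids)) lipids$ri - params$background_ri else numeric(0)
  by_cell <- function(x) {
    if (!nrow(lipids)) return(rep(0, nrow(cells)))
    v <- tapply(x, factor(lipids$cell, levels = cells$cell), sum, default = 0)
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  lip_vol_by_cell <- by_cell(lip_vol)
  # cell dry mass integrates the voxel-wise RI excess at the cell's dn/dc,
  # so lipid voxels contribute their own (higher) excess at alpha_cell here
  dry_mass_cells <- (cell_dn * (cells$volume_um3 - lip_vol_by_cell) +
                       by_cell(lip_dn * lip_vol)) / alpha_cell

  truth <- list(
    seed = seed, params = params, fov_jitter = jf,
    cells = cells, lipids = lipids,
    cell_mask = cell_mask_true,
    volume_um3 = sum(cells$volume_um3),
    mean_thickness_um = if (nrow(cells)) stats::weighted.mean(
      cells$mean_thickness_um, pi * cells$a_um * cells$b_um) else NA_real_,
    dry_mass_pg = sum(dry_mass_cells),
    lipid_volume_um3 = sum(lip_vol),
    lipid_dry_mass_pg = if (nrow(lipids)) sum(lip_dn * lip_vol / alpha_lipid) else 0
  )

  tomo <- tomogram(ri, voxel_size_um = voxel, n_medium = params$background_ri,
                   condition = params$condition, time_point = params$time_point)
  structure(list(tomo = tomo, truth = truth), class = "qpi_tomogram")
}
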