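# Synthetic multimodal NLO field-of-view generator.
#
# The generator is phenomenological: it paints the signal structures the
# downstream metrics respond to (dark cell footprints in transmission,
# perinuclear/punctate TPEF, sparse bright SRS droplets colocalized with
# F-CARS over a nonresonant background, mitochondria-like E-CARS texture)
# and then injects the acquisition artifacts the preprocessing stage must
# undo (per-channel Gaussian noise, 1-pixel outliers, serpentine row shift).
# Every random draw happens under the caller's seed, so identical
# (params, seed) pairs give bit-identical rasters.

circular_shift_vec <- function(v, k) {
  n <- length(v)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(v)
  c(v[(n - k + 1L):n], v[1L:(n - k)])
}

# shift even-indexed (0-based) rows of a matrix circularly by k pixels
shift_even_rows <- function(m, k) {
  if (k == 0L) return(m)
  rows <- seq(1L, nrow(m), by = 2L)  # R rows 1,3,... are 0-based even
  for (r in rows) m[r, ] <- circular_shift_vec(m[r, ], k)
  m
}

paint_disk <- function(canvas, cx, cy, r, value, combine = c("max", "add", "set")) {
  combine <- match.arg(combine)
  n_r <- nrow(canvas); n_c <- ncol(canvas)
  r0 <- max(1L, floor(cy - r)); r1 <- min(n_r, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(n_c, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(canvas)
  rr <- r0:r1; cc <- c0:c1
  dd <- outer((rr - cy)^2, (cc - cx)^2, "+") <= r^2
  sub <- canvas[rr, cc]
  sub[dd] <- switch(combine,
                    max = pmax(sub[dd], value),
                    add = sub[dd] + value,
                    set = value)
  canvas[rr, cc] <- sub
  canvas
}

# normalized elliptical radius field over a bounding box; returns list of
# index vectors and rho values for pixels with rho <= 1
ellipse_pixels <- function(n_r, n_c, cx, cy, rx, ry) {
  r0 <- max(1L, floor(cy - ry)); r1 <- min(n_r, ceiling(cy + ry))
  c0 <- max(1L, floor(cx - rx)); c1 <- min(n_c, ceiling(cx + rx))
  rr <- r0:r1; cc <- c0:c1
  rho <- sqrt(outer(((rr - cy) / ry)^2, ((cc - cx) / rx)^2, "+"))
  inside <- which(rho <= 1, arr.ind = TRUE)
  list(rows = rr[inside[, 1L]], cols = cc[inside[, 2L]],
       rho = rho[inside], bbox = c(r0, r1, c0, c1))
}

#' Generate one synthetic multimodal NLO field of view
#'
#' Places non-overlapping elliptical cells on a bright transmission
#' background, paints the TPEF mitochondrial pattern (diffuse perinuclear
#' annulus or dense puncta), sparse lipid droplets visible as normalized
#' ΔI/I spots in the SRS channel and bright F-CARS spots riding on a
#' nonresonant background, and an E-CARS channel tracking the mitochondrial
#' texture plus small droplets. Gaussian noise, 1-pixel outliers and a
#' serpentine row shift are then injected according to `params`.
#'
#' @param params a [phenotype_params()] object with `modality = "nlo"`.
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   output. The caller's RNG state is left untouched.
#' @param keep_clean if `TRUE` the pre-noise, pre-artifact channels are kept
#'   in the ground truth (used by round-trip tests).
#' @return a list of class `nlo_fov` with elements `image`
#'   (a [multimodal_image()]) and `truth` (cell/droplet geometry, true metric
#'   values, artifact bookkeeping, the seed).
#' @export
generate_nlo_fov <- function(params, seed, keep_clean = FALSE) {
  stopifnot(inherits(params, "phenotype_params"))
  if (missing(seed)) stop("a seed is required")
  with_local_seed(seed, generate_nlo_fov_impl(params, seed, keep_clean))
}

generate_nlo_fov_impl <- function(params, seed, keep_clean) {
  n <- params$fov_px
  px <- params$pixel_size_um
  chans <- c("TPEF", "SRS", "FCARS", "ECARS", "transmission")
  img <- stats::setNames(lapply(chans, function(x) matrix(0, n, n)), chans)
  img$transmission[] <- 1.0
  img$FCARS[] <- 0.02
  img$ECARS[] <- 0.02

  # per-FOV biological variability multiplier
  jf <- if (params$fov_jitter_sd > 0) exp(stats::rnorm(1, 0, params$fov_jitter_sd)) else 1
  density <- params$droplet_density_per_cell * jf
  area_target <- min(0.6, params$tpef_area_frac_target * jf)

  # --- place cells -----------------------------------------------------
  n_cells <- params$n_cells_per_fov
  cells <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                      rx_px = numeric(0), ry_px = numeric(0),
                      area_px = integer(0))
  r_base <- params$cell_radius_um / px
  attempts <- 0L
  placed <- 0L
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(1L, n_cells))
      stop("could not place ", n_cells, " non-overlapping cells in a ",
           n, "x", n, " FOV; reduce n_cells_per_fov or cell_radius_um",
           call. = FALSE)
    rx <- r_base * exp(stats::rnorm(1, 0, params$cell_radius_jitter))
    ry <- r_base * exp(stats::rnorm(1, 0, params$cell_radius_jitter))
    rmax <- max(rx, ry)
    if (2 * rmax + 4 > n) next
    cx <- stats::runif(1, rmax + 2, n - rmax - 1)
    cy <- stats::runif(1, rmax + 2, n - rmax - 1)
    if (nrow(cells) > 0) {
      dd <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(dd < 0.95 * (pmax(cells$rx_px, cells$ry_px) + rmax))) next
    }
    placed <- placed + 1L
    cells <- rbind(cells, data.frame(cell = placed, cx = cx, cy = cy,
                                     rx_px = rx, ry_px = ry, area_px = 0L))
  }

  cell_mask <- matrix(FALSE, n, n)
  droplets <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                         r_px = numeric(0), srs_amp = numeric(0),
                         fcars_amp = numeric(0))

  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    ep <- ellipse_pixels(n, n, ce$cx, ce$cy, ce$rx_px, ce$ry_px)
    lin <- cbind(ep$rows, ep$cols)
    cell_mask[lin] <- TRUE
    cells$area_px[i] <- length(ep$rho)
    img$transmission[lin] <- 0.70
    img$FCARS[lin] <- params$nrb_level
    img$ECARS[lin] <- 0.05
    img$TPEF[lin] <- params$tpef_base

    # mitochondrial TPEF pattern
    if (params$tpef_pattern == "diffuse_perinuclear") {
      rho_in <- 0.45
      rho_out <- sqrt(min(1, area_target + rho_in^2))
      sel <- ep$rho >= rho_in & ep$rho <= rho_out
      vals <- params$tpef_peak * stats::runif(sum(sel), 0.85, 1.15)
      img$TPEF[lin[sel, , drop = FALSE]] <- vals
      # E-CARS scatterers overlap the coenzyme pattern only partially: a
      # contiguous radial sub-band covering a random ~2/3 of the annulus
      # scatters detectably, and small CH2-rich scatterers sit outside it,
      # so the two colocalization fractions are comparable but not
      # degenerate. Contiguous/disk shapes survive the 1-pixel outlier
      # filter that isolated bright pixels would not.
      p_sel <- stats::runif(1, 0.55, 0.75)
      ann2 <- rho_out^2 - rho_in^2
      s2 <- rho_in^2 + stats::runif(1) * (1 - p_sel) * ann2
      e2 <- s2 + p_sel * ann2
      esel <- ep$rho^2 >= s2 & ep$rho^2 <= e2
      img$ECARS[lin[esel, , drop = FALSE]] <-
        0.6 * stats::runif(sum(esel), 0.85, 1.15)
      q <- stats::runif(1, 0.55, 0.80)
      n_extra <- round(q * sum(sel) / 9)
      for (s in seq_len(n_extra)) {
        repeat {
          rho <- sqrt(stats::runif(1)) * 0.9
          if (rho^2 < s2 - 0.06 || rho^2 > e2 + 0.06) break
        }
        th <- stats::runif(1, 0, 2 * pi)
        img$ECARS <- paint_disk(img$ECARS,
                                ce$cx + rho * ce$rx_px * cos(th),
                                ce$cy + rho * ce$ry_px * sin(th), 1.5,
                                0.6 * stats::runif(1, 0.85, 1.15))
      }
    } else {
      # puncta large enough (21 px) that the 1-pixel outlier filter cannot
      # mistake their rim for cosmic rays
      puncta_r <- 2.5
      puncta_area <- sum(outer((-3:3)^2, (-3:3)^2, "+") <= puncta_r^2)
      n_puncta <- max(1L, round(area_target * cells$area_px[i] / puncta_area))
      for (p in seq_len(n_puncta)) {
        rho <- stats::runif(1, 0.30, 0.85)
        th <- stats::runif(1, 0, 2 * pi)
        pcx <- ce$cx + rho * ce$rx_px * cos(th)
        pcy <- ce$cy + rho * ce$ry_px * sin(th)
        amp <- params$tpef_peak * stats::runif(1, 0.9, 1.1)
        img$TPEF <- paint_disk(img$TPEF, pcx, pcy, puncta_r, amp)
        img$ECARS <- paint_disk(img$ECARS, pcx, pcy, puncta_r, 0.8)
      }
    }

    # NRB-amplified sub-resolution lipid texture: dim F-CARS speckles with no
    # SRS counterpart, present in every cell. These dominate the F-CARS
    # positive population of control cells, where they keep the fraction of
    # F-CARS signal co-occurring with SRS near zero.
    if (params$fcars_speckle_frac > 0) {
      spk_r <- 1.3
      spk_area <- sum(outer((-2:2)^2, (-2:2)^2, "+") <= spk_r^2)
      n_spk <- round(params$fcars_speckle_frac * cells$area_px[i] / spk_area)
      for (s in seq_len(n_spk)) {
        rho <- stats::runif(1, 0.1, 0.9)
        th <- stats::runif(1, 0, 2 * pi)
        img$FCARS <- paint_disk(img$FCARS,
                                ce$cx + rho * ce$rx_px * cos(th),
                                ce$cy + rho * ce$ry_px * sin(th), spk_r,
                                params$nrb_level +
                                  0.5 * params$droplet_fcars_amp *
                                  stats::runif(1, 0.7, 1.3))
      }
    }

    # lipid droplets, scattered around cluster centers
    n_drop <- stats::rpois(1, density)
    if (n_drop > 0) {
      n_clust <- max(1L, stats::rpois(1, params$droplet_clusters_per_cell))
      cl_rho <- stats::runif(n_clust, 0.15, 0.70)
      cl_th <- stats::runif(n_clust, 0, 2 * pi)
      cl_x <- ce$cx + cl_rho * ce$rx_px * cos(cl_th)
      cl_y <- ce$cy + cl_rho * ce$ry_px * sin(cl_th)
      cl_sd <- params$droplet_cluster_sd_um / px
      for (dI in seq_len(n_drop)) {
        ci <- sample.int(n_clust, 1L)
        dx <- NA; dy <- NA
        for (try in 1:50) {
          cand_x <- cl_x[ci] + stats::rnorm(1, 0, cl_sd)
          cand_y <- cl_y[ci] + stats::rnorm(1, 0, cl_sd)
          rho <- sqrt(((cand_x - ce$cx) / ce$rx_px)^2 +
                      ((cand_y - ce$cy) / ce$ry_px)^2)
          if (rho <= 0.92) { dx <- cand_x; dy <- cand_y; break }
        }
        if (is.na(dx)) { dx <- cl_x[ci]; dy <- cl_y[ci] }  # center is inside
        r_um <- max(0.5 * px,
                    stats::rnorm(1, params$droplet_radius_um[1],
                                 params$droplet_radius_um[2]))
        r_drop <- r_um / px
        s_amp <- params$droplet_srs_amp * exp(stats::rnorm(1, 0, 0.1))
        f_amp <- params$droplet_fcars_amp * exp(stats::rnorm(1, 0, 0.1))
        img$SRS <- paint_disk(img$SRS, dx, dy, r_drop, s_amp)
        img$FCARS <- paint_disk(img$FCARS, dx, dy, r_drop,
                                params$nrb_level + f_amp)
        if (r_um < 0.6)  # subwavelength droplets also scatter into E-CARS
          img$ECARS <- paint_disk(img$ECARS, dx, dy, r_drop, 0.5)
        droplets <- rbind(droplets,
                          data.frame(cell = ce$cell, cx = dx, cy = dy,
                                     r_px = r_drop, srs_amp = s_amp,
                                     fcars_amp = f_amp))
      }
    }
  }

  n_cell_px <- sum(cell_mask)
  truth <- list(
    seed = seed, params = params, fov_jitter = jf,
    cells = cells, droplets = droplets, cell_mask = cell_mask,
    tpef_area_frac = if (n_cell_px > 0)
      sum(img$TPEF[cell_mask] > 0.25) / n_cell_px else NA_real_,
    tpef_mean = if (n_cell_px > 0) mean(img$TPEF[cell_mask]) else NA_real_,
    srs_area_frac = if (n_cell_px > 0)
      sum(img$SRS[cell_mask] > 2.2e-4) / n_cell_px else NA_real_
  )
  if (keep_clean) truth$clean <- img

  # --- artifacts -------------------------------------------------------
  for (ch in chans) {
    sd <- params$noise_sd[[ch]]
    if (!is.null(sd) && !is.na(sd) && sd > 0)
      img[[ch]] <- img[[ch]] + matrix(stats::rnorm(n * n, 0, sd), n, n)
  }
  outliers <- list()
  if (params$outlier_rate > 0) {
    for (ch in chans) {
      k <- stats::rbinom(1, n * n, params$outlier_rate)
      if (k > 0) {
        pos <- sample.int(n * n, k)
        bright <- stats::runif(k) < 0.5
        m <- stats::median(img[[ch]])
        sc <- max(diff(range(img[[ch]])), abs(m), 1e-6)
        img[[ch]][pos] <- ifelse(bright, m + 10 * sc, m - 10 * sc)
        outliers[[ch]] <- arrayInd(pos, c(n, n))
      }
    }
  }
  truth$outliers <- outliers
  if (params$serpentine_shift_px != 0L)
    for (ch in chans)
      img[[ch]] <- shift_even_rows(img[[ch]], params$serpentine_shift_px)
  truth$serpentine_shift_px <- params$serpentine_shift_px

  image <- multimodal_image(img, pixel_size_um = px,
                            condition = params$condition,
                            time_point = params$time_point)
  structure(list(image = image, truth = truth), class = "nlo_fov")
}
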