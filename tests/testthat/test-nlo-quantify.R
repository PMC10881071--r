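# Per-FOV NLO metrics: footprint segmentation, TPEF indices, droplet
# particle analysis with the size/circularity filter.

test_that("a dark square on a bright field segments to exactly that square", {
  tr <- matrix(1, 100, 100)
  tr[30:69, 40:79] <- 0.5
  m <- segment_cells(tr)
  expect_equal(m$area_px, 1600L)
  truth <- matrix(FALSE, 100, 100); truth[30:69, 40:79] <- TRUE
  expect_identical(m$mask, truth)
  expect_false(m$warning)
})

test_that("a constant transmission raster gives an empty mask with warning", {
  m <- segment_cells(matrix(0.8, 60, 60))
  expect_equal(m$area_px, 0L)
  expect_true(m$warning)
})

test_that("segmented footprints overlap ground truth (Jaccard >= 0.9)", {
  g <- generate_nlo_fov(clean_nlo(), seed = 13)
  m <- segment_cells(g$image$channels$transmission)
  jac <- sum(m$mask & g$truth$cell_mask) / sum(m$mask | g$truth$cell_mask)
  expect_gte(jac, 0.9)
})

test_that("area fraction uses a strict threshold and percent units", {
  ch <- matrix(0, 10, 10)
  ch[1:25] <- 1
  m <- full_mask(ch)
  expect_equal(area_fraction_pct(ch, m, 0.5), 25)
  expect_equal(area_fraction_pct(matrix(0.25, 10, 10), m, 0.25), 0)  # strict >
  expect_equal(area_fraction_pct(ch, m, -1), 100)
  empty <- cell_mask(matrix(FALSE, 10, 10), 0.35)
  expect_error(area_fraction_pct(ch, empty, 0.5), "empty")
})

test_that("area fraction is monotonically non-increasing in the threshold", {
  set.seed(17)
  ch <- matrix(rlnorm(400), 20, 20)
  m <- full_mask(ch)
  fr <- vapply(seq(0, 5, by = 0.25), function(t) area_fraction_pct(ch, m, t),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("top-decile maximum equals the direct sort oracle", {
  mk <- function(v) matrix(v, 1)
  m10 <- full_mask(mk(1:10))
  expect_equal(top_decile_max(mk(1:10), m10), 10)
  m20 <- full_mask(mk(1:20))
  expect_equal(top_decile_max(mk(1:20), m20), mean(c(19, 20)))
  expect_equal(top_decile_max(mk(rep(7, 30)), full_mask(mk(rep(7, 30)))), 7)
  set.seed(3)
  v <- rnorm(123)
  k <- ceiling(0.1 * 123)
  expect_equal(top_decile_max(mk(v), full_mask(mk(v))),
               mean(rev(sort(v))[1:k]))
})

test_that("aggregation index is the product of its two factors", {
  ch <- matrix(0, 10, 10); ch[1:25] <- 2
  m <- full_mask(ch)
  expect_equal(aggregation_index(ch, m, 0.5),
               top_decile_max(ch, m) * area_fraction_pct(ch, m, 0.5))
  expect_equal(aggregation_index(matrix(0, 10, 10), m, 0.5), 0)
})

test_that("bright punctate patterns out-score diffuse ones on the index", {
  # senescent-like preset: puncta concentrate a higher coenzyme density
  gd <- generate_nlo_fov(clean_nlo(), seed = 41)
  gp <- generate_nlo_fov(clean_nlo("TIS", "7d", tpef_pattern = "punctate",
                                   tpef_area_frac_target = 0.04,
                                   tpef_peak = 20, tpef_base = 0.18),
                         seed = 41)
  md <- segment_cells(gd$image$channels$transmission)
  mp <- segment_cells(gp$image$channels$transmission)
  expect_gt(aggregation_index(gp$image$channels$TPEF, mp, 0.25),
            aggregation_index(gd$image$channels$TPEF, md, 0.25))
})

test_that("mean in-mask intensity matches ground truth within noise SE", {
  half <- matrix(c(rep(0, 50), rep(2, 50)), 10, 10)
  expect_equal(mean_intensity(half, full_mask(half)), 1)
  expect_equal(mean_intensity(matrix(3, 5, 5), full_mask(matrix(3, 5, 5))), 3)

  p <- small_nlo(outlier_rate = 0, serpentine_shift_px = 0L)
  g <- generate_nlo_fov(p, seed = 19)
  m <- cell_mask(g$truth$cell_mask, p$pixel_size_um)
  se <- p$noise_sd[["TPEF"]] / sqrt(m$area_px)
  expect_lt(abs(mean_intensity(g$image$channels$TPEF, m) - g$truth$tpef_mean),
            5 * se)
})

test_that("droplet detection applies the 5 px^2 / circularity filter", {
  n <- 40
  srs <- disk_matrix(n, cx = 20, cy = 20, r = 4, value = 1e-3)
  m <- full_mask(srs)
  d <- detect_droplets(srs, m)
  expect_equal(nrow(d), 1L)
  expect_equal(d$area_px, sum(srs > 0))
  expect_equal(d$perimeter_px, oracle_perimeter(srs > 0))
  expect_equal(d$circularity, 4 * pi * d$area_px / oracle_perimeter(srs > 0)^2)
  expect_true(d$quasi_single)

  sq <- matrix(0, 20, 20); sq[5:6, 5:6] <- 1e-3   # 4 px < 5 px^2
  expect_equal(nrow(detect_droplets(sq, full_mask(sq))), 0L)

  ln <- matrix(0, 30, 30); ln[10, 6:25] <- 1e-3   # 1 x 20 line
  dl <- detect_droplets(ln, full_mask(ln))
  expect_equal(nrow(dl), 1L)
  expect_equal(dl$perimeter_px, oracle_perimeter(ln > 0))
  expect_equal(dl$perimeter_px, 42)                # crack edges: 2*(1+20)
  expect_equal(dl$circularity, 4 * pi * 20 / 42^2)
  expect_false(dl$quasi_single)
})

test_that("quasi-single droplets are never more numerous than clusters", {
  for (seed in 1:5) {
    g <- generate_nlo_fov(small_nlo("TIS", "7d"), seed = seed)
    m <- cell_mask(g$truth$cell_mask, 0.35)
    d <- detect_droplets(g$image$channels$SRS, m)
    expect_lte(sum(d$quasi_single), nrow(d))
  }
})

test_that("droplet summaries convert areas and report missing means as NA", {
  none <- detect_droplets(matrix(0, 20, 20), full_mask(matrix(0, 20, 20)))
  s0 <- droplet_summaries(none, full_mask(matrix(0, 20, 20)))
  expect_equal(s0$srs_area_pct, 0)
  expect_equal(s0$cluster_count, 0L)
  expect_true(is.na(s0$mean_quasi_single_area_um2))

  # one 10-px droplet at 0.35 um pixels: 10 * 0.1225 = 1.225 um^2
  srs <- matrix(0, 20, 20); srs[8:12, 9:10] <- 1e-3
  m <- full_mask(srs)
  d <- detect_droplets(srs, m)
  expect_equal(d$area_px, 10L)
  s <- droplet_summaries(d, m)
  expect_equal(s$mean_quasi_single_area_um2, 10 * 0.35^2)
  expect_equal(s$srs_area_pct, 100 * 10 / 400)
  expect_equal(s$clusters_per_cell_area, 1 / (400 * 0.35^2))
})

test_that("cluster count equals the painted droplet count on clean FOVs", {
  p <- clean_nlo(droplet_density_per_cell = 2.5,
                 droplet_radius_um = c(0.8, 0.05),
                 droplet_clusters_per_cell = 2, droplet_cluster_sd_um = 3)
  g <- generate_nlo_fov(p, seed = 30, keep_clean = TRUE)
  dr <- g$truth$droplets
  k <- nrow(dr)
  expect_gt(k, 2L)
  # guard: this seed paints mutually separated droplets, so components
  # cannot merge and the count comparison is meaningful
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    expect_gt(sqrt((dr$cx[i] - dr$cx[j])^2 + (dr$cy[i] - dr$cy[j])^2),
              dr$r_px[i] + dr$r_px[j] + 2.5)
  m <- cell_mask(g$truth$cell_mask, 0.35)
  d <- detect_droplets(g$truth$clean$SRS, m)
  expect_equal(nrow(d), k)
})

test_that("all metrics are invariant under translation of the scene", {
  # constructed scene: disk cell with an off-centre TPEF blob and two
  # droplets, placed far from the border so a (7, 9) shift cannot clip it
  n <- 90
  cellm <- disk_matrix(n, cx = 35, cy = 35, r = 20) > 0
  tp <- disk_matrix(n, cx = 30, cy = 38, r = 8, value = 1.4, base = 0)
  tp[cellm & tp == 0] <- 0.1
  sr <- disk_matrix(n, cx = 42, cy = 30, r = 3, value = 1e-3) +
    disk_matrix(n, cx = 28, cy = 28, r = 2, value = 1e-3)
  shift2 <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  mk <- cell_mask(cellm, 0.35)
  mk2 <- cell_mask(shift2(cellm, 7, 9) > 0, 0.35)
  tp2 <- shift2(tp, 7, 9); sr2 <- shift2(sr, 7, 9)
  expect_equal(area_fraction_pct(tp2, mk2, 0.25),
               area_fraction_pct(tp, mk, 0.25))
  expect_equal(top_decile_max(tp2, mk2), top_decile_max(tp, mk))
  expect_equal(mean_intensity(tp2, mk2), mean_intensity(tp, mk))
  s1 <- droplet_summaries(detect_droplets(sr, mk), mk)
  s2 <- droplet_summaries(detect_droplets(sr2, mk2), mk2)
  expect_equal(s1, s2)
})
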