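# RI tomogram morphometrics: segmentation, volume, thickness, dry mass
# (both routes), lipid quantification.

test_that("segmentation recovers embedded shapes and flags empty grids", {
  tm0 <- tomogram(array(1.3342, c(12, 12, 12)), c(1, 1, 1))
  m0 <- segment_cell_3d(tm0)
  expect_false(any(m0))
  expect_true(attr(m0, "warning"))

  ri <- array(1.3342, c(16, 16, 16))
  ri[5:12, 5:12, 5:12] <- 1.36
  tm <- tomogram(ri, c(1, 1, 1))
  m <- segment_cell_3d(tm)
  expect_identical(unname(which(m)), unname(which(ri > 1.35)))
  expect_equal(attr(m, "n_cells"), 1L)
})

test_that("sphere phantom volume is within 5% of 4/3*pi*r^3 (r = 10 voxels)", {
  tm <- phantom_tomogram(c(32, 32, 32), fill = function(x, y, z)
    (x - 16)^2 + (y - 16)^2 + (z - 16)^2 <= 10^2)
  m <- segment_cell_3d(tm)
  va <- 4 / 3 * pi * 10^3
  expect_lt(abs(cell_volume(m, c(1, 1, 1)) - va) / va, 0.05)
})

test_that("cell_volume is voxel count times voxel volume", {
  m1 <- array(FALSE, c(3, 3, 3)); m1[1, 1, 1] <- TRUE
  expect_equal(cell_volume(m1, c(0.1, 0.1, 0.1)), 1e-3)
  mb <- array(FALSE, c(12, 12, 6)); mb[1:10, 1:10, 1:5] <- TRUE
  expect_equal(cell_volume(mb, c(0.1, 0.1, 0.2)), 500 * 0.002)
  expect_equal(cell_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
})

test_that("mean thickness is volume over footprint", {
  mb <- array(FALSE, c(12, 12, 6)); mb[1:10, 1:10, 1:5] <- TRUE
  expect_equal(mean_thickness(mb, c(0.1, 0.1, 0.2)), 1.0)
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  expect_equal(mean_thickness(m1, c(0.1, 0.1, 0.7)), 0.7)
  expect_error(mean_thickness(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
  expect_equal(max_thickness(mb, c(0.1, 0.1, 0.2)), 1.0)
})

test_that("hemisphere mean thickness approaches (2/3) r", {
  r <- 16
  tm <- phantom_tomogram(c(48, 48, 20), fill = function(x, y, z)
    (x - 24)^2 + (y - 24)^2 + z^2 <= r^2)
  m <- segment_cell_3d(tm)
  expect_equal(mean_thickness(m, c(1, 1, 1)), 2 / 3 * r, tolerance = 0.02)
})

test_that("dry mass unit identity: dn 0.019 over 1 um^3 at 0.19 ml/g is 0.1 pg", {
  ri <- array(1.3342, c(1, 1, 1)); ri[1, 1, 1] <- 1.3342 + 0.019
  tm <- tomogram(ri, c(1, 1, 1))
  mask <- array(TRUE, c(1, 1, 1))
  expect_equal(as.numeric(dry_mass_from_ri(tm, mask, 0.19)), 0.1)
  tm0 <- tomogram(array(1.3342, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(as.numeric(dry_mass_from_ri(tm0, array(TRUE, c(4, 4, 4)), 0.19)), 0)
  expect_error(dry_mass_from_ri(tm, mask, 0), "positive")
})

test_that("dry mass is linear in the RI excess and clips negative voxels", {
  ri <- array(1.3342, c(4, 4, 4))
  set.seed(5)
  ri[1:2, , ] <- 1.3342 + runif(32, 0.005, 0.03)
  tm1 <- tomogram(ri, c(0.5, 0.5, 0.5))
  tm2 <- tomogram(array(1.3342 + 2 * (ri - 1.3342), dim(ri)), c(0.5, 0.5, 0.5))
  mask <- array(TRUE, c(4, 4, 4))
  expect_equal(as.numeric(dry_mass_from_ri(tm2, mask)),
               2 * as.numeric(dry_mass_from_ri(tm1, mask)))

  rin <- array(1.3342, c(3, 3, 3)); rin[1, 1, 1] <- 1.33  # below medium
  dm <- dry_mass_from_ri(tomogram(rin, c(1, 1, 1)), array(TRUE, c(3, 3, 3)))
  expect_equal(as.numeric(dm), 0)
  expect_equal(attr(dm, "n_negative"), 1L)
})

test_that("phase-route dry mass matches the volumetric route", {
  lam <- 0.532
  # single column: dn = 0.019 over a 1 um path above one 1 um^2 pixel
  ph <- qpi_phase_image(matrix(2 * pi / lam * 0.019 * 1, 1, 1), lam, 1)
  expect_equal(dry_mass_from_phase(ph, 0.19), 0.1)
  expect_equal(dry_mass_from_phase(qpi_phase_image(matrix(0, 3, 3), lam, 1)), 0)
  ph2 <- qpi_phase_image(2 * ph$phase, lam, 1)
  expect_equal(dry_mass_from_phase(ph2, 0.19), 0.2)

  # noise-free ellipsoid phantom: the two routes agree within 1%
  tm <- phantom_tomogram(c(40, 40, 24), voxel = c(0.5, 0.5, 0.5),
                         fill = function(x, y, z)
                           ((x - 10) / 7)^2 + ((y - 10) / 5)^2 + ((z - 6) / 4)^2 <= 1,
                         ri_inside = 1.358)
  mask <- tm$ri > tm$n_medium
  dm_vol <- as.numeric(dry_mass_from_ri(tm, mask))
  dm_ph <- dry_mass_from_phase(phase_from_tomogram(tm, lam))
  expect_lt(abs(dm_vol - dm_ph) / dm_vol, 0.01)
})

test_that("dry mass is additive over disjoint masks", {
  set.seed(6)
  ri <- array(1.3342 + runif(4^3, 0, 0.04), c(4, 4, 4))
  tm <- tomogram(ri, c(1, 1, 1))
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[3:4, , ] <- TRUE
  expect_equal(as.numeric(dry_mass_from_ri(tm, a | b)),
               as.numeric(dry_mass_from_ri(tm, a)) +
                 as.numeric(dry_mass_from_ri(tm, b)))
})

test_that("lipid segmentation uses inclusive 1.40-1.46 bounds", {
  ri <- array(1.3342, c(2, 2, 2))
  ri[1, 1, 1] <- 1.39; ri[2, 1, 1] <- 1.40; ri[1, 2, 1] <- 1.45
  ri[2, 2, 1] <- 1.46; ri[1, 1, 2] <- 1.461
  tm <- tomogram(ri, c(1, 1, 1))
  lip <- segment_lipid(tm, array(TRUE, c(2, 2, 2)))
  expect_identical(which(lip$mask),
                   which(array(ri >= 1.40 & ri <= 1.46, dim(ri))))
  expect_equal(lip$lipid_volume_um3, 3)

  none <- segment_lipid(tomogram(array(1.3342, c(2, 2, 2)), c(1, 1, 1)),
                        array(TRUE, c(2, 2, 2)))
  expect_equal(none$lipid_volume_um3, 0)
  expect_equal(none$lipid_dry_mass_pg, 0)
})

test_that("lipid spheres of radius 3 voxels are recovered within 10%", {
  # centers on voxel centers (half-integer grid coordinates); a 3-voxel
  # digital sphere then holds 123 voxels vs 113.1 analytic
  centers <- list(c(7.5, 7.5, 7.5), c(19.5, 11.5, 9.5), c(11.5, 21.5, 13.5))
  tm <- phantom_tomogram(c(28, 28, 20), fill = function(x, y, z) {
    any(vapply(centers, function(cc)
      (x - cc[1])^2 + (y - cc[2])^2 + (z - cc[3])^2 <= 9, logical(1)))
  }, ri_inside = 1.43)
  # embed in a cell-level background so the lipid band is selective
  cellm <- array(TRUE, dim(tm$ri))
  lip <- segment_lipid(tm, cellm)
  va <- 3 * 4 / 3 * pi * 27
  expect_lt(abs(lip$lipid_volume_um3 - va) / va, 0.10)
})

test_that("metrics are invariant under translation of the cell", {
  fillfun <- function(dx, dy, dz) function(x, y, z)
    ((x - 10 - dx) / 6)^2 + ((y - 10 - dy) / 6)^2 + ((z - 6 - dz) / 4)^2 <= 1
  t1 <- phantom_tomogram(c(40, 40, 24), fill = fillfun(0, 0, 0), ri_inside = 1.37)
  t2 <- phantom_tomogram(c(40, 40, 24), fill = fillfun(9, 7, 5), ri_inside = 1.37)
  m1 <- segment_cell_3d(t1); m2 <- segment_cell_3d(t2)
  v <- c(1, 1, 1)
  expect_equal(cell_volume(m1, v), cell_volume(m2, v))
  expect_equal(mean_thickness(m1, v), mean_thickness(m2, v))
  expect_equal(as.numeric(dry_mass_from_ri(t1, m1)),
               as.numeric(dry_mass_from_ri(t2, m2)))
})

test_that("qpi_metrics assembles a consistent per-cell row", {
  g <- generate_qpi_tomogram(qpi_preset("TIS", "7d", qpi_grid = c(96L, 96L, 32L)),
                             seed = 15)
  row <- qpi_metrics(g$tomo)
  expect_false(row$mask_warning)
  expect_gt(row$volume_um3, 0)
  expect_lte(row$lipid_volume_um3, row$volume_um3)
  expect_equal(row$mean_thickness_um,
               row$volume_um3 / row$projected_area_um2)
  # voxel metrics track the analytic ground truth
  expect_lt(abs(row$volume_um3 - g$truth$volume_um3) / g$truth$volume_um3, 0.15)
  expect_lt(abs(row$dry_mass_pg - g$truth$dry_mass_pg) / g$truth$dry_mass_pg, 0.15)
})
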