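# Synthetic-data generator: determinism, degenerate cases, ground-truth
# consistency, and the on-disk time-course dataset.

test_that("NLO generator is deterministic and leaves the caller's RNG alone", {
  p <- small_nlo()
  set.seed(999); before <- .Random.seed
  g1 <- generate_nlo_fov(p, seed = 42)
  expect_identical(.Random.seed, before)
  g2 <- generate_nlo_fov(p, seed = 42)
  expect_identical(g1$image$channels, g2$image$channels)
  expect_identical(g1$truth$droplets, g2$truth$droplets)
  g3 <- generate_nlo_fov(p, seed = 43)
  expect_false(identical(g1$image$channels$TPEF, g3$image$channels$TPEF))
})

test_that("empty and zero-signal FOVs come out exactly as specified", {
  p0 <- clean_nlo(n_cells_per_fov = 0L)
  g <- generate_nlo_fov(p0, seed = 1)
  expect_equal(unique(as.vector(g$image$channels$transmission)), 1.0)
  expect_equal(nrow(g$truth$cells), 0L)
  expect_equal(nrow(g$truth$droplets), 0L)

  pz <- clean_nlo(droplet_density_per_cell = 0)
  gz <- generate_nlo_fov(pz, seed = 2)
  expect_true(all(gz$image$channels$SRS == 0))
})

test_that("impossible cell packings raise a placement error", {
  p <- clean_nlo(n_cells_per_fov = 30L, cell_radius_um = 12)
  expect_error(generate_nlo_fov(p, seed = 1), "could not place")
})

test_that("painted SRS pixels match the recorded droplet geometry exactly", {
  p <- clean_nlo(droplet_density_per_cell = 4, droplet_radius_um = c(0.8, 0.1))
  g <- generate_nlo_fov(p, seed = 11, keep_clean = TRUE)
  expect_gt(nrow(g$truth$droplets), 0L)
  n <- p$fov_px
  painted <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(g$truth$droplets))) {
    d <- g$truth$droplets[k, ]
    for (i in 1:n) for (j in 1:n)
      if ((i - d$cy)^2 + (j - d$cx)^2 <= d$r_px^2) painted[i, j] <- TRUE
  }
  expect_identical(g$truth$clean$SRS > 0, painted)
})

test_that("tomogram generator is deterministic with exact background", {
  q <- qpi_preset("control", "0h", qpi_grid = c(64L, 64L, 24L))
  g1 <- generate_qpi_tomogram(q, seed = 5)
  g2 <- generate_qpi_tomogram(q, seed = 5)
  expect_identical(g1$tomo$ri, g2$tomo$ri)
  out <- g1$tomo$ri[!g1$truth$cell_mask]
  expect_true(all(out == q$background_ri))

  q0 <- qpi_preset("control", "0h", n_cells_per_fov = 0L,
                   qpi_grid = c(32L, 32L, 16L))
  g0 <- generate_qpi_tomogram(q0, seed = 1)
  expect_true(all(g0$tomo$ri == 1.3342))
})

test_that("a spherical 5-um cell records the analytic volume 523.60 um^3", {
  q <- qpi_preset("control", "0h", cell_radius_um = 5, cell_thickness_um = 10,
                  droplet_density_per_cell = 0, cell_radius_jitter = 0,
                  fov_jitter_sd = 0, noise_sd = c(ri = 0),
                  qpi_grid = c(96L, 96L, 48L),
                  qpi_fov_um = c(24, 24, 12))
  g <- generate_qpi_tomogram(q, seed = 3)
  expect_equal(g$truth$volume_um3, 4 / 3 * pi * 5^3, tolerance = 1e-12)
  expect_equal(round(g$truth$volume_um3, 2), 523.60)
})

test_that("analytic and voxel-counted ground truth agree within 5%", {
  # in-plane semi-axes ~24 voxels, vertical ~11: discretization error small
  q <- qpi_preset("control", "0h", cell_radius_um = 9,
                  droplet_density_per_cell = 0, noise_sd = c(ri = 0),
                  fov_jitter_sd = 0, qpi_grid = c(106L, 106L, 48L))
  g <- generate_qpi_tomogram(q, seed = 8)
  vox_vol <- sum(g$truth$cell_mask) * prod(g$tomo$voxel_size_um)
  expect_lt(abs(vox_vol - g$truth$volume_um3) / g$truth$volume_um3, 0.05)
})

test_that("generate_timecourse writes the expected manifest deterministically", {
  p_ctl <- clean_nlo(fov_px = 64L, n_cells_per_fov = 1L, cell_radius_um = 4)
  p_tis <- clean_nlo("TIS", "0h", fov_px = 64L, n_cells_per_fov = 1L,
                     cell_radius_um = 4)
  design <- c(
    lapply(1:5, function(i) list(params = p_ctl, n_fovs = 2L,
                                 plate = paste0("C", i))),
    lapply(1:5, function(i) list(params = p_tis, n_fovs = 2L,
                                 plate = paste0("T", i))))
  d1 <- withr::local_tempdir()
  m1 <- generate_timecourse(design, d1, seed = 7)
  expect_equal(nrow(m1), 20L)
  expect_equal(sum(m1$condition == "control"), 10L)
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  expect_true(all(file.exists(m1$path)), info = "all FOV files written")

  d2 <- withr::local_tempdir()
  m2 <- generate_timecourse(design, d2, seed = 7)
  expect_identical(m1[setdiff(names(m1), c("path", "truth_path"))],
                   m2[setdiff(names(m2), c("path", "truth_path"))])
  expect_identical(unname(tools::md5sum(m1$path[1])),
                   unname(tools::md5sum(m2$path[1])))

  expect_error(generate_timecourse(list(), d1, seed = 1), "nonempty")
  dup <- list(list(params = p_ctl, n_fovs = 2L, plate = "P"),
              list(params = p_ctl, n_fovs = 1L, plate = "P"))
  expect_error(generate_timecourse(dup, d1, seed = 1), "duplicate")
})

test_that("image and tomogram files round-trip through TIFF + sidecar", {
  g <- generate_nlo_fov(small_nlo(), seed = 21)
  f <- withr::local_tempfile(fileext = ".tif")
  write_multimodal_tiff(g$image, f)
  back <- read_multimodal_tiff(f)
  expect_equal(names(back$channels), names(g$image$channels))
  for (ch in names(back$channels))
    expect_equal(back$channels[[ch]], g$image$channels[[ch]],
                 tolerance = 1e-6, ignore_attr = TRUE)

  q <- generate_qpi_tomogram(qpi_preset("TIS", "7d", qpi_grid = c(48L, 48L, 16L)),
                             seed = 22)
  ft <- withr::local_tempfile(fileext = ".tif")
  write_tomogram_tiff(q$tomo, ft)
  backt <- read_tomogram_tiff(ft)
  expect_equal(backt$ri, q$tomo$ri, tolerance = 1e-6)
  expect_equal(backt$voxel_size_um, q$tomo$voxel_size_um)

  expect_error(read_multimodal_tiff(file.path(tempdir(), "nope.tif")),
               "missing TIFF")
})
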