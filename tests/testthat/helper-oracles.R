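# Brute-force oracles kept deliberately independent of the package
# implementations they check, plus small fixture builders.

# -- fixtures -----------------------------------------------------------

# reduced FOV for fast tests; cell radius capped so that the larger TIS
# presets still pack three cells into 120 px
small_nlo <- function(condition = "control", time_point = "0h",
                      cell_radius_um = 7, n_cells_per_fov = 3L,
                      fov_px = 120L, ...) {
  nlo_preset(condition, time_point, fov_px = fov_px,
             n_cells_per_fov = n_cells_per_fov,
             cell_radius_um = cell_radius_um, ...)
}

clean_noise <- c(TPEF = 0, SRS = 0, FCARS = 0, ECARS = 0, transmission = 0)

clean_nlo <- function(condition = "control", time_point = "0h", ...) {
  small_nlo(condition, time_point, noise_sd = clean_noise, outlier_rate = 0,
            fov_jitter_sd = 0, ...)
}

full_mask <- function(m, px = 0.35) {
  cell_mask(matrix(TRUE, nrow(m), ncol(m)), pixel_size_um = px)
}

# rasterized disk in an n x n matrix
disk_matrix <- function(n, cx, cy, r, value = 1, base = 0) {
  m <- matrix(base, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- value
  m
}

# uniform-RI phantom tomogram built directly (not via the generator)
phantom_tomogram <- function(dim3, voxel = c(1, 1, 1), n_medium = 1.3342,
                             fill = function(x, y, z) FALSE, ri_inside = 1.36) {
  ri <- array(n_medium, dim3)
  xs <- (seq_len(dim3[1]) - 0.5) * voxel[1]
  ys <- (seq_len(dim3[2]) - 0.5) * voxel[2]
  zs <- (seq_len(dim3[3]) - 0.5) * voxel[3]
  nx <- dim3[1]; ny <- dim3[2]
  for (k in seq_len(dim3[3])) {
    sl <- matrix(mapply(function(a, b) isTRUE(fill(a, b, zs[k])),
                        rep(xs, times = ny), rep(ys, each = nx)), nx, ny)
    ri[, , k][sl] <- ri_inside
  }
  tomogram(ri, voxel_size_um = voxel, n_medium = n_medium)
}

# -- oracles ------------------------------------------------------------

# window-by-window outlier filter: explicit loops, edge-replicated windows
oracle_outlier_filter <- function(m, z = 5) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in 1:nr) for (j in 1:nc) {
    w <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      w <- c(w, m[ii, jj])
    }
    med <- median(w)
    spread <- 1.4826 * median(abs(w - med))
    if (abs(m[i, j] - med) > z * spread) out[i, j] <- med
  }
  out
}

# per-pixel exposed-edge count (crack perimeter)
oracle_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- 0L
  for (i in 1:nr) for (j in 1:nc) {
    if (!mask[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) p <- p + 1L
    }
  }
  p
}

# quadrant counts by explicit pixel loop
oracle_quadrants <- function(x, y, t1, t2) {
  tr <- br <- tl <- 0L
  for (k in seq_along(x)) {
    if (x[k] > t1 && y[k] > t2) tr <- tr + 1L
    else if (x[k] > t1) br <- br + 1L
    else if (y[k] > t2) tl <- tl + 1L
  }
  c(tr = tr, br = br, tl = tl)
}

# exact two-sided Mann-Whitney p by full enumeration over label assignments
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_of(seq_len(n))
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2L, u_of)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}
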