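# Raw-image corrections applied before any quantification: median filtering
# of 1-pixel outliers (cosmic rays on the detectors), compensation of the
# serpentine scan distortion of the motorized stage, and normalization of the
# lock-in stimulated Raman gain signal to the Stokes transmission.

# pad a matrix by one pixel with edge replication
pad_replicate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[1L, ] <- p[2L, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1L] <- p[, 2L]; p[, nc + 2L] <- p[, nc + 1L]
  p
}

# the 9 3x3-neighborhood values of every pixel, as an (nr*nc) x 9 matrix
neighborhood9 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_replicate1(m)
  out <- matrix(0, nr * nc, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    out[, k] <- as.vector(p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  }
  out
}

# vectorized median over the 9 columns via a min/max selection network
median9 <- function(v) {
  s <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  v <- lapply(seq_len(ncol(v)), function(j) v[, j])
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  v[[5]]
}

#' Median-filter 1-pixel outliers
#'
#' Replaces pixels that deviate from their 3x3 neighborhood median by more
#' than `z_thresh` times the MAD-scaled local spread (1.4826 x the median
#' absolute deviation of the window from its median) with that median. Both
#' dark and bright outliers are corrected; all other pixels pass through
#' unchanged. In a locally flat window the spread is zero, so any deviating
#' center pixel is replaced -- which is exactly the 1-pixel cosmic-ray case.
#' A consequence of the windowed median is that a *pair* of adjacent extreme
#' pixels is also corrected: the 3x3 median around each member of the pair is
#' still the surrounding level.
#'
#' @param raster numeric matrix, at least 3x3, all values finite.
#' @param z_thresh robust z-score gate (default 5).
#' @return filtered matrix with attribute `n_replaced`.
#' @export
remove_outlier_pixels <- function(raster, z_thresh = 5) {
  stopifnot(is.matrix(raster))
  if (nrow(raster) < 3L || ncol(raster) < 3L)
    stop("raster must be at least 3x3")
  if (!all(is.finite(raster))) {
    bad <- which(!is.finite(raster), arr.ind = TRUE)
    stop("non-finite pixels at (row,col): ",
         paste(apply(utils::head(bad, 10L), 1L,
                     function(x) paste0("(", x[1], ",", x[2], ")")),
               collapse = " "))
  }
  nb <- neighborhood9(raster)
  med <- median9(nb)
  spread <- 1.4826 * median9(abs(nb - med))
  x <- as.vector(raster)
  repl <- abs(x - med) > z_thresh * spread
  x[repl] <- med[repl]
  out <- matrix(x, nrow(raster), ncol(raster))
  attr(out, "n_replaced") <- sum(repl)
  out
}

#' Estimate and correct the serpentine scan shift
#'
#' Bidirectional stage scanning displaces alternate scan lines by an integer
#' number of pixels. The shift is estimated globally as the integer `k` (over
#' `|k| <= max_shift`) that maximizes the mean Pearson correlation between
#' each even-indexed row (0-based; the reverse-scan rows) circularly shifted
#' by `-k` and its adjacent odd rows; ties break toward smaller `|k|`. The
#' returned raster has its even rows circularly shifted by `-k_hat`.
#'
#' @param raster numeric matrix with at least 4 rows.
#' @param max_shift search half-window in pixels (default 10).
#' @return list with `corrected` (matrix), `shift_px` (estimated injected
#'   shift `k_hat`) and `warning` (`TRUE` when the raster was constant or no
#'   row pair had usable variance, in which case the input is returned with
#'   `shift_px = 0`).
#' @export
correct_serpentine <- function(raster, max_shift = 10L) {
  stopifnot(is.matrix(raster))
  if (nrow(raster) < 4L) stop("raster must have at least 4 rows")
  degenerate <- function() list(corrected = raster, shift_px = 0L, warning = TRUE)
  if (stats::sd(raster) == 0) return(degenerate())
  nr <- nrow(raster)
  # estimate on a winsorized copy: cosmic-ray outliers would dominate the
  # row correlations, and clipping the extreme 1% tames them without mixing
  # rows (which a median filter would, erasing the shift signature)
  qs <- stats::quantile(raster, c(0.01, 0.99), names = FALSE)
  est_raster <- pmin(pmax(raster, qs[1]), qs[2])
  even_rows <- seq(1L, nr, by = 2L)            # 0-based even
  cand <- order(abs(-max_shift:max_shift), -max_shift:max_shift)
  cand <- (-max_shift:max_shift)[cand]         # 0, -1, 1, -2, 2, ...
  scores <- rep(NA_real_, length(cand))
  for (ci in seq_along(cand)) {
    k <- cand[ci]
    cors <- c()
    for (r in even_rows) {
      er <- circular_shift_vec(est_raster[r, ], -k)
      if (stats::sd(er) == 0) next
      for (nbr in c(r - 1L, r + 1L)) {
        if (nbr < 1L || nbr > nr) next
        orow <- est_raster[nbr, ]
        if (stats::sd(orow) == 0) next
        cors <- c(cors, stats::cor(er, orow))
      }
    }
    if (length(cors)) scores[ci] <- mean(cors)
  }
  if (all(is.na(scores))) return(degenerate())
  k_hat <- cand[which.max(scores)]             # first max: smallest |k| wins ties
  list(corrected = shift_even_rows(raster, -k_hat),
       shift_px = as.integer(k_hat), warning = FALSE)
}

#' Normalize stimulated Raman gain to the Stokes transmission
#'
#' Converts the demodulated lock-in signal (ΔI, VRMS) into the dimensionless
#' modulation ΔI/I by pixel-wise division by the linear Stokes transmission
#' (I, V). Scaling both inputs by a common gain leaves the output unchanged.
#'
#' @param lockin_signal numeric matrix, lock-in output.
#' @param stokes_transmission numeric matrix of the same shape, strictly
#'   positive everywhere.
#' @return ΔI/I matrix.
#' @export
normalize_srg <- function(lockin_signal, stokes_transmission) {
  stopifnot(is.matrix(lockin_signal), is.matrix(stokes_transmission))
  if (!identical(dim(lockin_signal), dim(stokes_transmission)))
    stop("inputs must have identical dimensions")
  if (any(stokes_transmission <= 0)) {
    bad <- which(stokes_transmission <= 0, arr.ind = TRUE)
    stop("non-positive Stokes transmission at (row,col): ",
         paste(apply(utils::head(bad, 10L), 1L,
                     function(x) paste0("(", x[1], ",", x[2], ")")),
               collapse = " "))
  }
  lockin_signal / stokes_transmission
}

#' Preprocess all channels of a multimodal image
#'
#' Estimates a single global serpentine shift on one reference channel (the
#' transmission by default, which always carries cell structure), applies the
#' same correction to all channels -- they are acquired simultaneously by the
#' same stage motion -- and then median-filters 1-pixel outliers in every
#' channel with [remove_outlier_pixels()]. The geometric correction runs
#' first: the outlier filter drags displaced scan rows toward their
#' neighbours and would erase the very misalignment the shift estimate
#' needs, while a handful of cosmic-ray pixels barely perturbs the row
#' correlations.
#'
#' @param image a [multimodal_image()].
#' @param z_thresh outlier gate, see [remove_outlier_pixels()].
#' @param max_shift serpentine search half-window.
#' @param shift_channel channel used for the shift estimate.
#' @return list with `image` (corrected [multimodal_image()]), `shift_px`,
#'   `n_replaced` (named per channel) and `warning`.
#' @export
preprocess_image <- function(image, z_thresh = 5, max_shift = 10L,
                             shift_channel = "transmission") {
  stopifnot(inherits(image, "multimodal_image"))
  if (!shift_channel %in% names(image$channels))
    stop("unknown shift_channel: ", shift_channel)
  ch <- image$channels
  est <- correct_serpentine(ch[[shift_channel]], max_shift = max_shift)
  if (!est$warning && est$shift_px != 0L)
    for (nm in names(ch)) ch[[nm]] <- shift_even_rows(ch[[nm]], -est$shift_px)
  n_repl <- integer(0)
  for (nm in names(ch)) {
    ch[[nm]] <- remove_outlier_pixels(ch[[nm]], z_thresh = z_thresh)
    n_repl[nm] <- attr(ch[[nm]], "n_replaced")
    attr(ch[[nm]], "n_replaced") <- NULL
  }
  out <- image
  out$channels <- ch
  list(image = out, shift_px = est$shift_px, n_replaced = n_repl,
       warning = est$warning)
}
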