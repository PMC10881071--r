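# Pixel-wise colocalization statistics between co-registered NLO channels:
# Pearson correlation, the pixel-frequency (quadrant) form of the Manders
# coefficients with crosshair thresholds, and the Costes randomization
# control for the significance of the observed correlation.

#' Pearson correlation between two channels over a mask
#'
#' @param ch1,ch2 numeric matrices of identical dimensions.
#' @param mask a [cell_mask()] with at least 2 pixels.
#' @return sample Pearson correlation of the in-mask pixel pairs.
#' @export
coloc_pearson <- function(ch1, ch2, mask) {
  assert_mask(ch1, mask)
  if (!identical(dim(ch1), dim(ch2))) stop("channel dimensions differ")
  if (mask$area_px < 2L) stop("mask must contain at least 2 pixels")
  x <- ch1[mask$mask]; y <- ch2[mask$mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a channel is constant within the mask")
  stats::cor(x, y)
}

#' Quadrant (pixel-frequency) Manders coefficients
#'
#' With crosshair thresholds `(t1, t2)` splitting the channel-1 vs channel-2
#' scatter into quadrants, and counting in-mask pixels,
#' `N_TR = |{ch1 > t1 & ch2 > t2}|` (co-occurring),
#' `N_BR = |{ch1 > t1 & ch2 <= t2}|`, `N_TL = |{ch1 <= t1 & ch2 > t2}|`:
#' `M1 = N_TR / (N_TR + N_BR)` is the fraction of channel-1-positive pixels
#' that are also channel-2 positive, and `M2 = N_TR / (N_TR + N_TL)` the
#' converse. This is the count-based form used for thresholded scatter
#' plots, not the classical intensity-weighted Manders coefficients (see
#' [manders_intensity()]). A coefficient whose denominator is zero is
#' reported as `NA` (missing).
#'
#' @param ch1,ch2 numeric matrices.
#' @param t1,t2 crosshair thresholds for channels 1 and 2.
#' @param mask a nonempty [cell_mask()].
#' @return list with `m1`, `m2` and the quadrant counts `n_tr`, `n_br`,
#'   `n_tl`, `n_bl`.
#' @export
manders_quadrant <- function(ch1, ch2, t1, t2, mask) {
  assert_mask(ch1, mask)
  if (!identical(dim(ch1), dim(ch2))) stop("channel dimensions differ")
  x <- ch1[mask$mask]; y <- ch2[mask$mask]
  p1 <- x > t1; p2 <- y > t2
  n_tr <- sum(p1 & p2); n_br <- sum(p1 & !p2)
  n_tl <- sum(!p1 & p2); n_bl <- sum(!p1 & !p2)
  list(m1 = if (n_tr + n_br > 0) n_tr / (n_tr + n_br) else NA_real_,
       m2 = if (n_tr + n_tl > 0) n_tr / (n_tr + n_tl) else NA_real_,
       n_tr = n_tr, n_br = n_br, n_tl = n_tl, n_bl = n_bl)
}

#' Classical intensity-weighted Manders coefficients
#'
#' The original definition: `M1 = sum(ch1 over pixels with ch2 > t2) /
#' sum(ch1)`, and symmetrically for `M2`, over in-mask pixels. Provided as a
#' clearly named alternative to the quadrant form ([manders_quadrant()]).
#'
#' @inheritParams manders_quadrant
#' @return list with `m1`, `m2`.
#' @export
manders_intensity <- function(ch1, ch2, t1, t2, mask) {
  assert_mask(ch1, mask)
  if (!identical(dim(ch1), dim(ch2))) stop("channel dimensions differ")
  x <- ch1[mask$mask]; y <- ch2[mask$mask]
  s1 <- sum(x); s2 <- sum(y)
  list(m1 = if (s1 > 0) sum(x[y > t2]) / s1 else NA_real_,
       m2 = if (s2 > 0) sum(y[x > t1]) / s2 else NA_real_)
}

#' Costes randomization significance test
#'
#' Permutation control for the observed Pearson correlation: channel 2 is
#' spatially randomized `n_rand` times (channel 1 fixed) and the one-sided
#' p-value is `(1 + #{PCC_rand >= PCC_obs}) / (1 + n_rand)`. With
#' `block_px = 1` the in-mask pixels of channel 2 are permuted; with
#' `block_px > 1` square blocks of the mask bounding box are permuted
#' instead, preserving correlations shorter than the block size (use blocks
#' about the size of the point-spread function when pixels oversample it; at
#' the 350 nm pitch of the default geometry the PSF is below one pixel, so
#' 1 is the default).
#'
#' @inheritParams coloc_pearson
#' @param n_rand number of randomizations (at least 20).
#' @param block_px side of the permuted blocks, in pixels.
#' @param seed integer seed for the permutations; the caller's RNG state is
#'   left untouched.
#' @return one-sided p-value.
#' @export
costes_significance <- function(ch1, ch2, mask, n_rand = 200L, block_px = 1L,
                                seed = 1L) {
  if (n_rand < 20L) stop("n_rand must be at least 20 for a stable p-value")
  obs <- coloc_pearson(ch1, ch2, mask)
  x <- ch1[mask$mask]
  with_local_seed(seed, {
    if (block_px <= 1L) {
      y <- ch2[mask$mask]
      ge <- 0L
      for (i in seq_len(n_rand)) {
        r <- stats::cor(x, sample(y))
        if (r >= obs) ge <- ge + 1L
      }
      (1 + ge) / (1 + n_rand)
    } else {
      idx <- which(mask$mask, arr.ind = TRUE)
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      # block grid over the bounding box; incomplete edge blocks included
      br <- ((idx[, 1] - r0) %/% block_px)
      bc <- ((idx[, 2] - c0) %/% block_px)
      blk <- br * (((c1 - c0) %/% block_px) + 1L) + bc
      blocks <- split(seq_len(nrow(idx)), blk)
      y <- ch2[mask$mask]
      ge <- 0L
      for (i in seq_len(n_rand)) {
        perm <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
        r <- stats::cor(x, y[perm])
        if (r >= obs) ge <- ge + 1L
      }
      (1 + ge) / (1 + n_rand)
    }
  })
}

default_crosshair <- function(channel_name, values) {
  if (channel_name == "TPEF") return(0.25)
  if (channel_name == "SRS") return(2.2e-4)
  # CARS thresholds are not fixed by the acquisition; Otsu on in-mask pixels
  rg <- range(values)
  if (diff(rg) == 0) return(rg[1])
  norm <- (values - rg[1]) / diff(rg)
  as.numeric(EBImage::otsu(EBImage::Image(matrix(norm, nrow = 1)),
                           range = c(0, 1))) * diff(rg) + rg[1]
}

#' Full colocalization report for a channel pair
#'
#' Bundles the Pearson correlation, the quadrant Manders coefficients and
#' the Costes significance for one named channel pair of a multimodal image,
#' together with the scatter data used for plotting.
#'
#' @param image a [multimodal_image()].
#' @param mask a nonempty [cell_mask()].
#' @param pair character length-2: names of channel 1 and channel 2.
#' @param thresholds optional numeric length-2 crosshair `(t1, t2)`; by
#'   default 0.25 a.u. for TPEF, 2.2e-4 for SRS, and in-mask Otsu for the
#'   CARS channels.
#' @param n_rand,block_px,seed passed to [costes_significance()]; set
#'   `n_rand = 0` to skip the Costes control.
#' @return object of class `coloc_result`: list with `pcc`, `m1`, `m2`,
#'   `t1`, `t2`, `n_pixels`, `costes_p`, `channel_pair` and `scatter` (a
#'   two-column data frame of in-mask pixel pairs).
#' @export
coloc_report <- function(image, mask, pair, thresholds = NULL,
                         n_rand = 200L, block_px = 1L, seed = 1L) {
  stopifnot(inherits(image, "multimodal_image"), length(pair) == 2L)
  missing_ch <- setdiff(pair, names(image$channels))
  if (length(missing_ch))
    stop("unknown channel name(s): ", paste(missing_ch, collapse = ", "))
  ch1 <- image$channels[[pair[1]]]
  ch2 <- image$channels[[pair[2]]]
  if (is.null(thresholds))
    thresholds <- c(default_crosshair(pair[1], ch1[mask$mask]),
                    default_crosshair(pair[2], ch2[mask$mask]))
  pcc <- coloc_pearson(ch1, ch2, mask)
  mq <- manders_quadrant(ch1, ch2, thresholds[1], thresholds[2], mask)
  cp <- if (n_rand >= 20L)
    costes_significance(ch1, ch2, mask, n_rand = n_rand,
                        block_px = block_px, seed = seed)
  else NA_real_
  structure(list(pcc = pcc, m1 = mq$m1, m2 = mq$m2,
                 t1 = thresholds[1], t2 = thresholds[2],
                 n_pixels = mask$area_px, costes_p = cp,
                 channel_pair = paste(pair, collapse = ":"),
                 scatter = data.frame(ch1 = ch1[mask$mask],
                                      ch2 = ch2[mask$mask])),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s: PCC=%.3f M1=%.3f M2=%.3f (t1=%.3g t2=%.3g, n=%d)%s\n",
              x$channel_pair, x$pcc, x$m1, x$m2, x$t1, x$t2, x$n_pixels,
              if (is.na(x$costes_p)) "" else sprintf(" Costes p=%.4g", x$costes_p)))
  invisible(x)
}
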