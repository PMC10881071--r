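# Connected-component labeling and digital shape measures shared by the 2D
# droplet analysis and the 3D tomogram segmentation.

neighbor_offsets <- function(ndim, connectivity) {
  grid <- as.matrix(do.call(expand.grid, rep(list(-1:1), ndim)))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  if (connectivity %in% c(4L, 6L))
    grid <- grid[rowSums(abs(grid)) == 1L, , drop = FALSE]
  # keep one of each +/- pair; undirected edges need each pair once
  keep <- apply(grid, 1L, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  grid[keep, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Labels foreground elements of a 2D or 3D logical array. Connectivity
#' follows the usual digital-topology conventions: 8 (default) or 4 neighbors
#' in 2D, 26 (default) or 6 in 3D. Components are numbered in order of their
#' smallest linear index, so labeling is deterministic.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4/8 for 2D, 6/26 for 3D.
#' @return integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  d <- dim(mask)
  ndim <- length(d)
  stopifnot(is.logical(mask), ndim %in% c(2L, 3L))
  if (ndim == 2L) stopifnot(connectivity %in% c(4L, 8L))
  else stopifnot(connectivity %in% c(6L, 26L))
  lab <- array(0L, d)
  fg <- which(mask)
  n_fg <- length(fg)
  if (n_fg == 0L) return(lab)
  idx <- arrayInd(fg, d)
  key <- integer(prod(d))
  key[fg] <- seq_len(n_fg)
  offs <- neighbor_offsets(ndim, connectivity)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2L, offs[i, ], "+")
    ok <- rep(TRUE, n_fg)
    for (j in seq_len(ndim)) ok <- ok & nb[, j] >= 1L & nb[, j] <= d[j]
    if (!any(ok)) next
    nbo <- nb[ok, , drop = FALSE]
    lin <- nbo[, 1L]
    mult <- d[1L]
    for (j in 2:ndim) {
      lin <- lin + (nbo[, j] - 1L) * mult
      mult <- mult * d[j]
    }
    tgt <- key[lin]
    hit <- tgt > 0L
    if (any(hit))
      edges[[i]] <- cbind(key[fg][ok][hit], tgt[hit])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    memb <- seq_len(n_fg)  # all isolated
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n_fg)
      g <- igraph::add_vertices(g, n_fg - igraph::vcount(g))
    memb <- igraph::components(g)$membership
  }
  # renumber by smallest linear index for determinism
  first <- tapply(fg, memb, min)
  ord <- rank(first)
  lab[fg] <- as.integer(ord[as.character(memb)])
  lab
}

#' Crack-edge perimeter of a labeled component
#'
#' Counts the exposed unit pixel edges between the component and anything
#' outside it (background or other labels), i.e. the length of the crack
#' boundary walked along pixel borders. For a w x h solid rectangle this is
#' 2(w + h); a digitally convex set has perimeter equal to twice the sum of
#' its bounding extents.
#'
#' @param mask logical matrix, `TRUE` on the component.
#' @return perimeter in pixel units.
#' @export
crack_perimeter <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(inner & !pad[1:nr, 2:(nc + 1L)]) +
    sum(inner & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(inner & !pad[2:(nr + 1L), 1:nc]) +
    sum(inner & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

# Per-label geometry: area, crack perimeter, circularity 4*pi*A/P^2, centroid.
component_shapes <- function(lab) {
  labels <- sort(unique(lab[lab > 0L]))
  if (length(labels) == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  idx <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  out <- lapply(labels, function(l) {
    sel <- lv == l
    m <- lab == l
    p <- crack_perimeter(m)
    a <- sum(sel)
    data.frame(label = l, area_px = a, perimeter_px = p,
               circularity = 4 * pi * a / p^2,
               centroid_row = mean(idx[sel, 1L]),
               centroid_col = mean(idx[sel, 2L]))
  })
  do.call(rbind, out)
}

# 3D morphological closing with a (2r+1)^3 cube structuring element, done as
# a dilation (running pmax over shifted copies) followed by erosion.
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (j in 1:3) {
    o <- off[j]
    if (o >= 0) { src[[j]] <- seq_len(d[j] - o); dst[[j]] <- src[[j]] + o }
    else        { src[[j]] <- (1 - o):d[j];      dst[[j]] <- src[[j]] + o }
    if (d[j] + min(0, o) < max(1, 1 + o)) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

close_3d <- function(mask, radius = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  offs <- as.matrix(expand.grid(-radius:radius, -radius:radius, -radius:radius))
  dil <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs)))
    dil <- dil | shift_array(mask, offs[i, ], FALSE)
  ero <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs)))
    ero <- ero & shift_array(dil, offs[i, ], TRUE)
  ero
}
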