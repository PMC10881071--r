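# On-disk formats. Channel rasters and tomogram slices go into multi-page
# TIFF; because TIFF pages here store [0,1] samples, each page is written
# through an affine map recorded in a JSON sidecar (<file>.json), together
# with the pixel/voxel geometry and labels. Ground truth is JSON, manifests
# are CSV. Round-trips are exact to 32-bit sample quantization.

page_encode <- function(m) {
  rg <- range(m)
  sc <- diff(rg)
  if (sc == 0) sc <- 1
  list(page = (m - rg[1]) / sc, offset = rg[1], scale = sc)
}

#' Write / read a multimodal image as multi-page TIFF + JSON sidecar
#'
#' One TIFF page per channel (32-bit samples, affine-mapped to `[0,1]`);
#' the sidecar `<path>.json` records channel names, the per-page affine
#' coefficients, the pixel size and the FOV labels.
#'
#' @param image a [multimodal_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_multimodal_tiff <- function(image, path) {
  stopifnot(inherits(image, "multimodal_image"))
  enc <- lapply(image$channels, page_encode)
  suppressWarnings(tiff::writeTIFF(lapply(enc, `[[`, "page"), path,
                                   bits.per.sample = 32L))
  meta <- list(channels = names(image$channels),
               offset = vapply(enc, `[[`, numeric(1), "offset"),
               scale = vapply(enc, `[[`, numeric(1), "scale"),
               pixel_size_um = image$pixel_size_um,
               fov_id = image$fov_id, condition = image$condition,
               time_point = image$time_point)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_multimodal_tiff
#' @export
read_multimodal_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("missing TIFF or JSON sidecar for ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("corrupted image file ", path, ": page count does not match sidecar")
  ch <- stats::setNames(vector("list", length(pages)), meta$channels)
  for (i in seq_along(pages))
    ch[[i]] <- pages[[i]] * meta$scale[i] + meta$offset[i]
  multimodal_image(ch, pixel_size_um = meta$pixel_size_um,
                   fov_id = meta$fov_id %||% NA_character_,
                   condition = meta$condition %||% NA_character_,
                   time_point = meta$time_point %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write / read a tomogram as a multi-page TIFF z-stack + JSON sidecar
#'
#' One TIFF page per z slice under a single global affine map; the sidecar
#' records grid dimensions, voxel size, medium RI, the affine coefficients
#' and labels.
#'
#' @param tomo a [tomogram()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tomogram_tiff <- function(tomo, path) {
  stopifnot(inherits(tomo, "tomogram"))
  rg <- range(tomo$ri)
  sc <- diff(rg); if (sc == 0) sc <- 1
  d <- dim(tomo$ri)
  pages <- lapply(seq_len(d[3]), function(z) (tomo$ri[, , z] - rg[1]) / sc)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  meta <- list(dim = d, voxel_size_um = tomo$voxel_size_um,
               n_medium = tomo$n_medium, offset = rg[1], scale = sc,
               cell_id = tomo$cell_id, condition = tomo$condition,
               time_point = tomo$time_point)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tomogram_tiff
#' @export
read_tomogram_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("missing TIFF or JSON sidecar for ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$dim[3])
    stop("corrupted tomogram file ", path, ": page count does not match sidecar")
  ri <- array(0, meta$dim)
  for (z in seq_along(pages)) ri[, , z] <- pages[[z]] * meta$scale + meta$offset
  tomogram(ri, voxel_size_um = meta$voxel_size_um, n_medium = meta$n_medium,
           cell_id = meta$cell_id %||% NA_character_,
           condition = meta$condition %||% NA_character_,
           time_point = meta$time_point %||% NA_character_)
}

truth_to_json <- function(truth, path) {
  slim <- truth[setdiff(names(truth), c("cell_mask", "clean", "params"))]
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Generate a full time-course dataset on disk
#'
#' Runs the FOV or tomogram generator for every plate of a design, writes
#' the images (TIFF + sidecar), ground-truth JSONs and a manifest CSV, and
#' returns the manifest. Per-file seeds are derived deterministically from
#' `seed`, so identical `(design, seed)` reproduce the dataset exactly.
#'
#' @param design nonempty list of entries, each a list with elements
#'   `params` (a [phenotype_params()]) and `n_fovs` (images for that plate);
#'   an optional `plate` label defaults to `"P<i>"`. The params' `modality`
#'   decides whether NLO FOVs or tomograms are produced.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @return data frame manifest with columns `condition`, `time_point`,
#'   `plate`, `fov`, `modality`, `path`, `truth_path`, `seed`.
#' @export
generate_timecourse <- function(design, out_dir, seed) {
  if (!is.list(design) || length(design) == 0L)
    stop("design must be a nonempty list")
  if (missing(seed)) stop("a seed is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(design), function(i) {
    e <- design[[i]]
    if (!inherits(e$params, "phenotype_params") || is.null(e$n_fovs) ||
        e$n_fovs < 1L)
      stop("design entry ", i, " needs a phenotype_params `params` and `n_fovs` >= 1")
    e$plate <- e$plate %||% paste0("P", i)
    e
  })
  keys <- unlist(lapply(entries, function(e)
    paste(e$params$condition, e$params$time_point, e$plate,
          seq_len(e$n_fovs), sep = "|")))
  if (anyDuplicated(keys))
    stop("duplicate (condition, time_point, plate, fov) keys in design")

  rows <- list()
  idx <- 0L
  for (e in entries) {
    for (j in seq_len(e$n_fovs)) {
      idx <- idx + 1L
      fov_seed <- as.integer((as.numeric(seed) * 7919 + idx) %%
                               (.Machine$integer.max - 1)) + 1L
      stub <- sprintf("%s_%s_%s_fov%02d", e$params$condition,
                      gsub("[^A-Za-z0-9]", "", e$params$time_point),
                      e$plate, j)
      path <- file.path(out_dir, paste0(stub, ".tif"))
      tpath <- file.path(out_dir, paste0(stub, "_truth.json"))
      if (e$params$modality == "nlo") {
        g <- generate_nlo_fov(e$params, seed = fov_seed)
        g$image$fov_id <- stub
        write_multimodal_tiff(g$image, path)
      } else {
        g <- generate_qpi_tomogram(e$params, seed = fov_seed)
        g$tomo$cell_id <- stub
        write_tomogram_tiff(g$tomo, path)
      }
      truth_to_json(g$truth, tpath)
      rows[[idx]] <- data.frame(condition = e$params$condition,
                                time_point = e$params$time_point,
                                plate = e$plate, fov = j,
                                modality = e$params$modality,
                                path = path, truth_path = tpath,
                                seed = fov_seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
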