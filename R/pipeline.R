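# End-to-end orchestration: simulate (or ingest) -> preprocess ->
# NLO quantification -> colocalization -> QPI morphometrics -> statistics,
# with every intermediate written to the output directory and a provenance
# log recording seeds, package version and the configuration.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Reshape per-FOV metric rows into the long metrics table
#'
#' @param df wide data frame with key columns `fov_id`/`cell_id`,
#'   `condition`, `time_point` plus numeric metric columns.
#' @param metrics which columns to keep; default all numeric non-key ones.
#' @return long data frame with columns `condition`, `time_point`, `id`,
#'   `metric`, `value`.
#' @export
metrics_long <- function(df, metrics = NULL) {
  idcol <- intersect(c("fov_id", "cell_id"), names(df))[1]
  if (is.na(idcol)) stop("no fov_id/cell_id column")
  keys <- c(idcol, "condition", "time_point")
  if (is.null(metrics))
    metrics <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], keys)
  out <- do.call(rbind, lapply(metrics, function(m)
    data.frame(condition = df$condition, time_point = df$time_point,
               id = df[[idcol]], metric = m, value = df[[m]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      nlo = list(time_points = c("0h", "72h"), n_plates = 2L, n_fovs = 2L,
                 override = list()),
      qpi = list(time_points = c("0h", "72h"), n_per_condition = 2L,
                 override = list())
    ),
    preprocess = list(z_thresh = 5, max_shift = 10L),
    nlo = list(tpef_threshold = 0.25, srs_threshold = 2.2e-4,
               min_area_px = 5L, circ_range = c(0.3, 1.0)),
    coloc = list(pairs = list(c("SRS", "FCARS"), c("TPEF", "ECARS")),
                 n_rand = 99L, block_px = 1L),
    qpi = list(delta_n = 0.003, min_voxels = 100L),
    stats = list(baseline = "0h", min_n = 3L)
  )
}

merge_config <- function(user) {
  cfg <- utils::modifyList(default_config(), user, keep.null = TRUE)
  # sections explicitly absent in the user config stay absent
  for (sec in c("nlo", "qpi"))
    if (!is.null(user$simulate) && is.null(user$simulate[[sec]]))
      cfg$simulate[[sec]] <- NULL
  cfg
}

nlo_design_from_config <- function(sim, seed_unused) {
  design <- list()
  for (tp in sim$time_points)
    for (cond in c("control", "TIS"))
      for (p in seq_len(sim$n_plates)) {
        params <- do.call(nlo_preset,
                          c(list(condition = cond, time_point = tp),
                            sim$override))
        design[[length(design) + 1L]] <-
          list(params = params, n_fovs = sim$n_fovs,
               plate = sprintf("%s%s_P%d", cond, gsub("\\W", "", tp), p))
      }
  design
}

qpi_design_from_config <- function(sim) {
  design <- list()
  for (tp in sim$time_points)
    for (cond in c("control", "TIS")) {
      params <- do.call(qpi_preset,
                        c(list(condition = cond, time_point = tp),
                          sim$override))
      design[[length(design) + 1L]] <-
        list(params = params, n_fovs = sim$n_per_condition,
             plate = sprintf("%s%s", cond, gsub("\\W", "", tp)))
    }
  design
}

#' Run the full analysis pipeline
#'
#' Simulates (or, with `simulate` replaced by pre-existing manifests,
#' ingests) a time-course dataset, preprocesses every NLO FOV, computes the
#' NLO metric rows and colocalization reports, computes QPI metric rows when
#' a `qpi` simulation section is present, runs the time-course statistics,
#' and writes all tables plus a provenance log under `out_dir`.
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure; unset keys fall back to defaults (see the package vignette).
#' @param out_dir output directory.
#' @param seed master seed; defaults to `config$seed`.
#' @return list with `nlo_metrics`, `coloc`, `qpi_metrics`, `tests`,
#'   `summary`, `out_dir` (data frames are also written as CSV).
#' @export
run_all <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config))
    config <- stage("config", yaml::read_yaml(config))
  cfg <- merge_config(config)
  if (is.null(seed)) seed <- cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  nlo_tab <- coloc_tab <- qpi_tab <- NULL

  if (!is.null(cfg$simulate$nlo)) {
    manifest <- stage("simulate-nlo", generate_timecourse(
      nlo_design_from_config(cfg$simulate$nlo), file.path(out_dir, "nlo_raw"),
      seed = seed))
    rows <- list(); crows <- list()
    for (i in seq_len(nrow(manifest))) {
      img <- stage("read-nlo", read_multimodal_tiff(manifest$path[i]))
      pp <- stage("preprocess", preprocess_image(
        img, z_thresh = cfg$preprocess$z_thresh,
        max_shift = cfg$preprocess$max_shift))
      mask <- segment_cells(pp$image$channels$transmission,
                            pixel_size_um = pp$image$pixel_size_um)
      rows[[i]] <- stage("quantify-nlo", nlo_metrics(
        pp$image, mask = mask,
        tpef_threshold = cfg$nlo$tpef_threshold,
        srs_threshold = cfg$nlo$srs_threshold,
        min_area_px = cfg$nlo$min_area_px,
        circ_range = cfg$nlo$circ_range))
      if (mask$area_px >= 2L) {
        for (pr in cfg$coloc$pairs) {
          cr <- stage("coloc", coloc_report(
            pp$image, mask, pr, n_rand = cfg$coloc$n_rand,
            block_px = cfg$coloc$block_px, seed = manifest$seed[i]))
          crows[[length(crows) + 1L]] <- data.frame(
            fov_id = manifest$path[i], condition = manifest$condition[i],
            time_point = manifest$time_point[i],
            channel_pair = cr$channel_pair, pcc = cr$pcc, m1 = cr$m1,
            m2 = cr$m2, t1 = cr$t1, t2 = cr$t2, costes_p = cr$costes_p,
            stringsAsFactors = FALSE)
        }
      }
    }
    nlo_tab <- do.call(rbind, rows)
    coloc_tab <- if (length(crows)) do.call(rbind, crows) else NULL
    utils::write.csv(nlo_tab, file.path(out_dir, "nlo_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(coloc_tab))
      utils::write.csv(coloc_tab, file.path(out_dir, "coloc.csv"),
                       row.names = FALSE)
  }

  if (!is.null(cfg$simulate$qpi)) {
    manifest <- stage("simulate-qpi", generate_timecourse(
      qpi_design_from_config(cfg$simulate$qpi), file.path(out_dir, "qpi_raw"),
      seed = seed + 1L))
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      tomo <- stage("read-qpi", read_tomogram_tiff(manifest$path[i]))
      stage("quantify-qpi", qpi_metrics(tomo, delta_n = cfg$qpi$delta_n,
                                        min_voxels = cfg$qpi$min_voxels))
    })
    qpi_tab <- do.call(rbind, rows)
    utils::write.csv(qpi_tab, file.path(out_dir, "qpi_metrics.csv"),
                     row.names = FALSE)
  }

  long <- rbind(
    if (!is.null(nlo_tab)) metrics_long(nlo_tab) else NULL,
    if (!is.null(qpi_tab)) metrics_long(qpi_tab) else NULL)
  report <- stage("stats", timecourse_report(
    long, baseline = cfg$stats$baseline, min_n = cfg$stats$min_n))
  utils::write.csv(report$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_path)
  jsonlite::write_json(
    list(seed = seed,
         package_version = as.character(utils::packageVersion("tismorph")),
         r_version = R.version.string,
         config_md5 = unname(tools::md5sum(cfg_path)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)

  list(nlo_metrics = nlo_tab, coloc = coloc_tab, qpi_metrics = qpi_tab,
       tests = report$tests, summary = report$summary, out_dir = out_dir)
}
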