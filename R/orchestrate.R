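# Automation loop over the instrument contract plus the end-to-end pipeline:
# z-scan -> autofocus -> mosaic -> detect -> isolate -> geometry -> route ->
# acquire, then cosmic-ray removal -> references -> EMSC -> denoise -> crop
# -> cull -> cross-validated classification.

#' Screening run configuration
#'
#' Collects and validates every tunable of a run. A single master seed fans
#' out to per-stage seeds through a fixed derivation, so whole runs are
#' reproducible; all resolved defaults are carried in the run manifest.
#'
#' @param z_range Scan range around focus for the variance z-scan (um).
#' @param z_step Scan step (um).
#' @param grid Tile grid `c(rows, cols)` for the mosaic.
#' @param overlap Nominal tile overlap fraction, in (0, 0.5).
#' @param fov Tile size `c(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_targets Preset number of isolated cells to keep.
#' @param t_acq Cell acquisition time (s); 10 s per nucleus.
#' @param n_substrate,t_substrate Substrate acquisitions (20 spectra, 30 s
#'   each).
#' @param laser_offset Calibrated laser-spot offset applied to stage targets
#'   (um); `NULL` reads the instrument's own calibration.
#' @param detect_sigma,min_distance,prominence Bright-spot detector
#'   parameters (px, px, fraction of dynamic range).
#' @param variance_def Contrast definition for [variance_metric()].
#' @param emsc_order EMSC polynomial order.
#' @param sg_window,sg_order Denoising Savitzky-Golay parameters.
#' @param glass_sg_window,glass_sg_order Substrate-reference smoothing.
#' @param qc_threshold Pearson cull threshold.
#' @param ref_k Spectra averaged into the cell reference.
#' @param cr_k_sigma,cr_max_width Cosmic-ray detection parameters.
#' @param fingerprint Fingerprint crop bounds (cm^-1).
#' @param folds CV folds.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(z_range = c(-10, 30), z_step = 2, grid = c(2, 2),
                       overlap = 0.1, fov = c(256, 256), pixel_size = 0.5,
                       n_targets = 40, t_acq = 10, n_substrate = 20,
                       t_substrate = 30, laser_offset = NULL,
                       detect_sigma = 4, min_distance = 8, prominence = 0.25,
                       variance_def = "var_over_mean", emsc_order = 5,
                       sg_window = 7, sg_order = 3, glass_sg_window = 9,
                       glass_sg_order = 3, qc_threshold = 0.99, ref_k = 50,
                       cr_k_sigma = 8, cr_max_width = 3,
                       fingerprint = c(600, 1800), folds = 10, seed = 1) {
  if (z_step <= 0) stop("z_step must be positive", call. = FALSE)
  if (overlap <= 0 || overlap >= 0.5) {
    stop("overlap must lie in (0, 0.5)", call. = FALSE)
  }
  if (t_acq <= 0 || t_substrate <= 0) {
    stop("acquisition times must be positive", call. = FALSE)
  }
  if (sg_window %% 2 == 0 || glass_sg_window %% 2 == 0) {
    stop("Savitzky-Golay windows must be odd", call. = FALSE)
  }
  if (sg_window <= sg_order || glass_sg_window <= glass_sg_order) {
    stop("Savitzky-Golay window must exceed its polynomial order",
         call. = FALSE)
  }
  if (fingerprint[2] <= fingerprint[1]) {
    stop("fingerprint bounds must be increasing", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the automated acquisition loop on an instrument
#'
#' Executes the full targeting routine: a variance z-scan and autofocus at
#' the field centre, imaging of the overlapping tile grid in the bright-spot
#' plane, stitching, bright-spot detection, isolation filtering to
#' `n_targets`, the pixel-to-stage affine fit from tile-centre
#' correspondences, the laser offset, nearest-neighbour route ordering, and
#' per-target spectral acquisition in the focal plane, plus the configured
#' substrate spectra from cell-free positions. Every action is recorded in
#' the manifest.
#'
#' @param instr A [simulated_instrument()] (anything honouring the same
#'   contract works).
#' @param cfg A [run_config()].
#' @return A list of class `acquisition_run`: `targets` (a `target_list`),
#'   `spectra` (cell `spectrum_set` with ground-truth labels in the
#'   simulator), `substrate` (`spectrum_set`), `focus` (`focus_result`),
#'   `map` (`affine_map_2d`), `candidates`, `manifest` (tibble action log).
#' @export
run_acquisition <- function(instr, cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- tibble::tibble(
      step = length(log) + 1, stage = stage, detail = paste0(...))
  }
  field <- instr$ph$params$field_extent
  centre <- c(field / 2, field / 2)

  # 1. variance z-scan + autofocus at the field centre
  instr$move_stage(centre[1], centre[2])
  zs <- seq(cfg$z_range[1], cfg$z_range[2], by = cfg$z_step)
  metric <- vapply(zs, function(z) {
    instr$set_z(z)
    variance_metric(instr$snap_image(), definition = cfg$variance_def)
  }, numeric(1))
  prof <- variance_profile(zs, metric)
  focus <- tryCatch(autofocus(prof), error = function(e) {
    stop("autofocus failed: ", conditionMessage(e), "; profile: ",
         paste(sprintf("%g:%0.3g", zs, metric), collapse = " "),
         call. = FALSE)
  })
  note("autofocus", "bright-spot ", focus$z_bright_spot, " um, focus ",
       focus$z_focus, " um")

  # 2. overlapping tile grid in the bright-spot plane
  instr$set_z(focus$z_bright_spot)
  pitch <- cfg$fov * (1 - cfg$overlap) * cfg$pixel_size
  rows <- seq_len(cfg$grid[1])
  cols <- seq_len(cfg$grid[2])
  cy <- centre[2] + (mean(rows) - rows) * pitch[1]   # row 1 at top (max y)
  cx <- centre[1] + (cols - mean(cols)) * pitch[2]
  tiles <- list()
  for (i in rows) {
    for (j in cols) {
      instr$move_stage(cx[j], cy[i])
      tile <- instr$snap_image()
      tile$stage_xy <- c(cx[j], cy[i])   # software knows the command only
      tiles[[length(tiles) + 1]] <- tile
    }
  }
  note("imaging", length(tiles), " tiles at z = ", focus$z_bright_spot)

  # 3-4. stitch + detect
  mos <- stitch_grid(tiles, nominal_overlap = cfg$overlap)
  cand <- detect_bright_spots(mos, sigma = cfg$detect_sigma,
                              min_distance = cfg$min_distance,
                              prominence = cfg$prominence)
  note("detect", nrow(cand), " candidates")

  # 5. isolation filter
  kept <- select_isolated(cand, cfg$n_targets)

  # 6. pixel -> stage map from tile-centre correspondences
  dims <- mos$tile_dims
  px_pts <- cbind(mos$offsets$row_off + (dims[1] - 1) / 2,
                  mos$offsets$col_off + (dims[2] - 1) / 2)
  map <- fit_pixel_to_stage(px_pts,
                            cbind(mos$offsets$stage_x, mos$offsets$stage_y))
  note("geometry", "affine rms residual ",
       signif(map$rms_residual, 3), " um")

  stage_pts <- pixel_to_stage(map, cbind(kept$row, kept$col))
  targets <- dplyr::bind_cols(stage_pts,
                              tibble::tibble(px_row = kept$row,
                                             px_col = kept$col,
                                             isolation_px = kept$isolation))

  # 7. laser offset + route
  offset <- cfg$laser_offset
  if (is.null(offset)) offset <- -instr$laser_offset
  if (nrow(targets) > 0) {
    route <- order_route(targets, start = instr$position())
    route <- apply_laser_offset(route, offset)
  } else {
    route <- dplyr::bind_cols(tibble::tibble(order = integer(0)), targets)
    class(route) <- c("target_list", class(tibble::tibble()))
  }
  note("route", "nearest-neighbour tour of ", nrow(route), " targets")

  # 8. spectral acquisition in the focal plane
  instr$set_z(focus$z_focus)
  spectra <- NULL
  truth_rows <- list()
  skipped <- 0
  for (i in seq_len(nrow(route))) {
    ok <- tryCatch({
      instr$move_stage(route$x_um[i], route$y_um[i])
      TRUE
    }, error = function(e) {
      note("skip", "target ", i, ": ", conditionMessage(e))
      FALSE
    })
    if (!ok) {
      skipped <- skipped + 1
      next
    }
    s <- instr$acquire_spectrum(cfg$t_acq)
    tr <- attr(s, "truth")
    truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
      order = route$order[i], x_um = route$x_um[i], y_um = route$y_um[i],
      class = if (is.null(tr$class)) NA_character_ else tr$class,
      nucleus = tr$nucleus, cr = tr$cr, cb = tr$cb,
      cosmic_channels = list(tr$cosmic_channels), id = s$id)
    spectra <- rbind(spectra, s$intensities)
  }
  truth <- dplyr::bind_rows(truth_rows)
  cells <- NULL
  if (!is.null(spectra)) {
    rownames(spectra) <- truth$id
    cells <- spectrum_set(instr$axis, spectra, labels = truth$class,
                          meta = truth)
  }
  note("acquire", nrow(truth), " cell spectra (", skipped, " skipped)")

  # 9. substrate spectra from cell-free positions
  sub_mat <- NULL
  cand_stage <- pixel_to_stage(map, cbind(cand$row, cand$col))
  grid_pts <- expand.grid(
    x = seq(instr$ph$params$margin, field - instr$ph$params$margin,
            length.out = 12),
    y = seq(instr$ph$params$margin, field - instr$ph$params$margin,
            length.out = 12))
  dmin <- vapply(seq_len(nrow(grid_pts)), function(i) {
    if (nrow(cand_stage) == 0) return(Inf)
    min(sqrt((cand_stage$x_um - grid_pts$x[i])^2 +
               (cand_stage$y_um - grid_pts$y[i])^2))
  }, numeric(1))
  empty <- grid_pts[order(-dmin), ][seq_len(min(cfg$n_substrate,
                                                nrow(grid_pts))), ]
  for (i in seq_len(nrow(empty))) {
    instr$move_stage(empty$x[i], empty$y[i])
    s <- instr$acquire_spectrum(cfg$t_substrate)
    sub_mat <- rbind(sub_mat, s$intensities)
  }
  rownames(sub_mat) <- sprintf("glass%03d", seq_len(nrow(sub_mat)))
  substrate <- spectrum_set(instr$axis, sub_mat)
  note("substrate", nrow(sub_mat), " glass spectra at ", cfg$t_substrate,
       " s")

  manifest <- dplyr::bind_rows(log)
  structure(list(targets = route, spectra = cells, substrate = substrate,
                 focus = focus, map = map, candidates = cand,
                 manifest = manifest, config = cfg),
            class = "acquisition_run")
}

#' @export
print.acquisition_run <- function(x, ...) {
  cat("<acquisition_run> ", nrow(x$targets), " targets, ",
      if (is.null(x$spectra)) 0 else n_spectra(x$spectra),
      " cell spectra, bright-spot plane ", x$focus$z_bright_spot, " um\n",
      sep = "")
  invisible(x)
}

#' Run pre-processing and classification end to end
#'
#' Applies the whole analysis chain to a labelled spectrum set: cosmic-ray
#' removal, cell-reference construction (from `reference_set` when given,
#' following the practice of recording a dedicated clean reference dataset;
#' otherwise from the data), substrate-reference construction, EMSC,
#' Savitzky-Golay denoising, fingerprint crop, Pearson quality cull, and
#' stratified cross-validated classification with the eleven pipeline
#' configurations.
#'
#' @param spectra Labelled raw `spectrum_set` (two classes).
#' @param glass `spectrum_set` of substrate spectra, or `NULL` to skip the
#'   substrate component (CaF2 case).
#' @param cfg A [run_config()].
#' @param reference_set Optional dedicated `spectrum_set` for the cell
#'   reference.
#' @param specs Pipeline specs for [crossvalidate()].
#' @param out_dir Optional directory; when given, processed spectra (CSV),
#'   QC/cosmic reports, MR scores, PCA scores/loadings, the metrics table
#'   and per-fold accuracies (JSON/CSV) are written there.
#' @return A list of class `screen_report`: `cv` (`cv_report`), `processed`
#'   (`spectrum_set`), `qc`, `cosmic`, `reference`, `substrate_ref`,
#'   `mr` (`mr_scores` on the processed data), `pca` (scores/loadings
#'   tibbles), `retention`.
#' @export
run_full_pipeline <- function(spectra, glass = NULL, cfg = run_config(),
                              reference_set = NULL, specs =
                                default_pipeline_specs(), out_dir = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (is.null(spectra$labels)) {
    stop("spectra must carry class labels for classification", call. = FALSE)
  }
  cr_res <- remove_cosmic_rays(spectra, k_sigma = cfg$cr_k_sigma,
                               max_width = cfg$cr_max_width)
  clean <- cr_res$spectra
  ref_src <- if (!is.null(reference_set)) reference_set else clean
  ref <- build_reference(ref_src, k = min(cfg$ref_k, n_spectra(ref_src)))
  sub_ref <- if (!is.null(glass)) {
    build_substrate_reference(glass, window = cfg$glass_sg_window,
                              order = cfg$glass_sg_order)
  } else NULL
  emsc <- emsc_correct_set(clean, ref, sub_ref, order = cfg$emsc_order)
  sg <- savitzky_golay_set(emsc$spectra, window = cfg$sg_window,
                           order = cfg$sg_order)
  fp <- crop_fingerprint(sg, cfg$fingerprint[1], cfg$fingerprint[2])
  ref_fp <- crop_fingerprint(ref, cfg$fingerprint[1], cfg$fingerprint[2])
  # cull against the EMSC-normalised reference on the fingerprint window
  qc <- quality_cull(fp, ref_fp, threshold = cfg$qc_threshold)
  kept <- qc$spectra
  if (length(unique(kept$labels)) < 2) {
    stop("quality cull removed an entire class; lower qc_threshold or noise",
         call. = FALSE)
  }
  cv <- crossvalidate(kept$matrix, kept$labels, specs = specs,
                      k = cfg$folds, seed = derive_seed(cfg$seed, 42))
  mr <- marginal_relevance(kept$matrix, kept$labels, axis = kept$axis)
  mu <- colMeans(kept$matrix)
  sv <- svd(sweep(kept$matrix, 2, mu), nu = 2, nv = 2)
  expl <- sv$d^2 / sum(sv$d^2)
  pca <- list(
    scores = tibble::tibble(id = rownames(kept$matrix),
                            label = kept$labels,
                            PC1 = sv$u[, 1] * sv$d[1],
                            PC2 = sv$u[, 2] * sv$d[2]),
    loadings = tibble::tibble(wavenumber = as.numeric(kept$axis),
                              PC1 = sv$v[, 1], PC2 = sv$v[, 2]),
    explained = expl[1:2])
  out <- structure(list(cv = cv, processed = kept, qc = qc$report,
                        cosmic = cr_res$report, reference = ref,
                        substrate_ref = sub_ref, mr = mr, pca = pca,
                        retention = attr(qc$report, "retention"),
                        emsc_coefficients = emsc$coefficients,
                        config = cfg),
                   class = "screen_report")
  if (!is.null(out_dir)) write_screen_report(out, out_dir)
  out
}

write_screen_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(report$processed, file.path(out_dir, "processed_spectra.csv"))
  readr::write_csv(report$qc, file.path(out_dir, "qc_report.csv"),
                   progress = FALSE)
  readr::write_csv(report$cosmic, file.path(out_dir, "cosmic_rays.csv"),
                   progress = FALSE)
  readr::write_csv(report$mr, file.path(out_dir, "mr_scores.csv"),
                   progress = FALSE)
  readr::write_csv(report$pca$scores, file.path(out_dir, "pca_scores.csv"),
                   progress = FALSE)
  readr::write_csv(report$pca$loadings,
                   file.path(out_dir, "pca_loadings.csv"), progress = FALSE)
  readr::write_csv(report$cv$metrics, file.path(out_dir, "metrics.csv"),
                   progress = FALSE)
  readr::write_csv(report$cv$fold_metrics,
                   file.path(out_dir, "fold_accuracies.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(retention = report$retention,
         pca_explained = report$pca$explained,
         metrics = report$cv$metrics),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 10)
  invisible(out_dir)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", n_spectra(x$processed),
      " spectra retained (retention ", round(x$retention, 3), ")\n",
      sep = "")
  print(x$cv$metrics)
  invisible(x)
}
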