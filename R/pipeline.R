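#' Pipeline orchestration and configuration
#'
#' The two entry points compose the module functions in the order of the
#' analysis: `run_imaging_pipeline` goes from a fluorescence stack plus
#' stimulus schedule to retinotopy, orientation, significance and
#' concentric-prediction maps and their comparison; `run_ephys_pipeline`
#' goes from a trial table to per-penetration columnar statistics, the
#' shuffle test and the penetration-level concentric test. Both are
#' deterministic given the configuration and seed and can write a full
#' artifact set with a manifest.
#'
#' @name cli_io
#' @keywords internal
NULL

#' Default analysis configuration
#'
#' Every analysis parameter with its standard value: 33 um map smoothing,
#' 132 um concentric-map smoothing, 0.1% patch-fit pedestal subtraction,
#' 0.4% patch inclusion threshold, 0.5% minimum mean response per condition,
#' 2 Hz minimum evoked unit response, 10,000 shuffles, alpha 0.05, 29.5 cm
#' monitor distance, 1.8 Hz frame rate, 11.04 um pixels, 3 s stimuli with
#' 9 s minimum interstimulus interval. All overridable via [load_config()]
#' or by editing the returned list.
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    sigma_map_um = 33,
    sigma_concentric_um = 132,
    patch_subtract_dff = 0.001,
    patch_include_dff = 0.004,
    min_mean_response_dff = 0.005,
    min_evoked_hz = 2,
    n_shuffles = 10000,
    alpha = 0.05,
    frame_rate_hz = 1.8,
    pixel_size_um = 11.04,
    stim_s = 3,
    isi_min_s = 9,
    monitor = list(width_cm = 93, height_cm = 52, distance_cm = 29.5,
                   center_offset_cm = c(0, 0),
                   head_pitch_deg = 0, head_roll_deg = 0,
                   hemisphere = "right"),
    seed = 1
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file, merges it onto [default_config()] (file entries win)
#' and validates types and ranges. Unknown keys are an error, so typos fail
#' fast.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        utils::modifyList(cfg[[k]], user[[k]])
      } else user[[k]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_pos <- c("sigma_map_um", "sigma_concentric_um", "frame_rate_hz",
               "pixel_size_um", "stim_s", "isi_min_s")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) stop("invalid config: ", k)
  }
  for (k in c("patch_subtract_dff", "patch_include_dff",
              "min_mean_response_dff", "min_evoked_hz", "alpha")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) stop("invalid config: ", k)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("invalid config: alpha")
  if (cfg$n_shuffles < 1) stop("invalid config: n_shuffles")
  if (!cfg$monitor$hemisphere %in% c("right", "left")) {
    stop("invalid config: monitor$hemisphere")
  }
  invisible(cfg)
}

config_geometry <- function(cfg, patch_centres_cm = NULL) {
  m <- cfg$monitor
  if (is.null(patch_centres_cm)) {
    patch_centres_cm <- patch_grid_centres(4, 4, m$width_cm, m$height_cm)
  }
  monitor_geometry(width_cm = m$width_cm, height_cm = m$height_cm,
                   distance_cm = m$distance_cm,
                   center_offset_cm = m$center_offset_cm,
                   patch_centres_cm = patch_centres_cm,
                   head_pitch_deg = m$head_pitch_deg,
                   head_roll_deg = m$head_roll_deg,
                   hemisphere = m$hemisphere)
}

#' Run the imaging pipeline
#'
#' Stack + schedule + geometry in; retinotopy, orientation, significance,
#' single-condition and concentric maps plus the measured-vs-predicted
#' comparison out. Optionally writes every artifact (float TIFF maps, HSV
#' renderings, CSV tables, JSON report) and a manifest listing each output
#' with its MD5 hash and the parameters used.
#'
#' @param stack `imaging_stack`.
#' @param schedule stimulus schedule data.frame (`onset_s`, `offset_s`,
#'   `kind`, `patch_id`, `direction_deg`).
#' @param geom `monitor_geometry` (defaults to the configuration's monitor
#'   block with a 4 x 4 patch grid).
#' @param config configuration list from [default_config()]/[load_config()].
#' @param reference_roi optional H x W logical reference region.
#' @param out_dir optional output directory for the artifact set.
#' @return list with `resp_table`, `patch_maps`, `retinotopy_argmax`,
#'   `patch_fits`, `retinotopy`, `dir_maps`, `orientation_map`,
#'   `significance`, `single_condition`, `concentric_map`,
#'   `response_mask`, `comparison`, `manifest` (NULL when `out_dir` is
#'   NULL).
#' @export
run_imaging_pipeline <- function(stack, schedule, geom = NULL,
                                 config = default_config(),
                                 reference_roi = NULL, out_dir = NULL) {
  validate_config(config)
  if (is.null(geom)) geom <- config_geometry(config)
  ## fail fast on inconsistent inputs
  dur <- dim(stack$frames)[3] / stack$frame_rate_hz
  if (any(schedule$offset_s > stack$t0_s + dur)) {
    stop("inconsistent inputs: schedule extends beyond the recording")
  }
  pids <- schedule$patch_id[schedule$kind == "patch"]
  if (length(pids) > 0 && !all(pids %in% geom$patch_centres_cm$patch_id)) {
    stop("inconsistent inputs: schedule references a patch id missing from the geometry")
  }
  px <- stack$pixel_size_um

  resp_table <- event_response_table(stack, schedule, reference_roi)
  ev <- resp_table$events
  out <- list(resp_table = resp_table)

  is_patch <- ev$kind == "patch"
  if (any(is_patch)) {
    pt <- list(resp = resp_table$resp[, , is_patch, drop = FALSE],
               events = ev[is_patch, , drop = FALSE])
    out$patch_maps <- condition_mean_maps(pt, by = "patch_id",
                                          sigma_um = config$sigma_map_um,
                                          pixel_size_um = px)
    out$retinotopy_argmax <- retinotopy_argmax_map(out$patch_maps)
    out$patch_fits <- lapply(names(out$patch_maps), function(id) {
      fit_patch_gaussian(out$patch_maps[[id]], patch_id = as.numeric(id),
                         subtract = config$patch_subtract_dff,
                         include_threshold = config$patch_include_dff)
    })
    out$retinotopy <- tryCatch(
      interpolate_retinotopy(out$patch_fits, geom, dim(stack$frames)[1:2]),
      error = function(e) { message("retinotopy: ", conditionMessage(e)); NULL })
  }

  is_grat <- ev$kind == "grating"
  if (any(is_grat)) {
    gt_tab <- list(resp = resp_table$resp[, , is_grat, drop = FALSE],
                   events = ev[is_grat, , drop = FALSE])
    out$dir_maps <- condition_mean_maps(gt_tab, by = "direction_deg",
                                        sigma_um = config$sigma_map_um,
                                        pixel_size_um = px)
    out$orientation_map <- orientation_polar_map(out$dir_maps)
    out$significance <- anova_significance_map(gt_tab, alpha = config$alpha)
    ors <- sort(unique(as.numeric(names(out$dir_maps)) %% 180))
    out$single_condition <- lapply(ors, function(o) {
      dirs <- as.numeric(names(out$dir_maps))
      single_condition_map(out$dir_maps, names(out$dir_maps)[dirs %% 180 == o])
    })
    names(out$single_condition) <- ors
    out$response_mask <- min_response_mask(out$dir_maps,
                                           config$min_mean_response_dff)
  }

  if (!is.null(out$retinotopy) && !is.null(out$orientation_map)) {
    out$concentric_map <- build_concentric_map(out$retinotopy,
                                               sigma_um = config$sigma_concentric_um,
                                               pixel_size_um = px)
    out$comparison <- tryCatch(
      compare_orientation_to_concentric(out$orientation_map,
                                        out$concentric_map,
                                        response_mask = out$response_mask,
                                        min_mean_response = config$min_mean_response_dff,
                                        seed = config$seed),
      error = function(e) { message("comparison: ", conditionMessage(e)); NULL })
  }

  out$manifest <- if (!is.null(out_dir)) {
    write_imaging_artifacts(out, out_dir, config)
  } else NULL
  out
}

write_imaging_artifacts <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(fname) files <<- c(files, fname)
  if (!is.null(res$retinotopy_argmax)) {
    write_map_tiff(res$retinotopy_argmax$patch, file.path(out_dir, "retinotopy_patch.tif"))
    put("retinotopy_patch.tif"); put("retinotopy_patch.tif.json")
    export_hsv_png(res$retinotopy_argmax, file.path(out_dir, "retinotopy_patch.png"))
    if (file.exists(file.path(out_dir, "retinotopy_patch.png"))) put("retinotopy_patch.png")
  }
  if (!is.null(res$retinotopy)) {
    write_map_tiff(res$retinotopy$azimuth, file.path(out_dir, "azimuth.tif"))
    write_map_tiff(res$retinotopy$elevation, file.path(out_dir, "elevation.tif"))
    put("azimuth.tif"); put("azimuth.tif.json")
    put("elevation.tif"); put("elevation.tif.json")
  }
  if (!is.null(res$patch_fits)) {
    pf <- do.call(rbind, lapply(res$patch_fits, function(f) {
      data.frame(patch_id = f$patch_id, row_px = f$centre_px[1],
                 col_px = f$centre_px[2], sigma_row_px = f$sigmas_px[1],
                 sigma_col_px = f$sigmas_px[2],
                 amplitude_dff = f$amplitude_dff, included = f$included)
    }))
    utils::write.csv(pf, file.path(out_dir, "patch_fits.csv"), row.names = FALSE)
    put("patch_fits.csv")
  }
  if (!is.null(res$orientation_map)) {
    write_map_tiff(res$orientation_map, file.path(out_dir, "orientation_map.tif"))
    put("orientation_map.tif"); put("orientation_map.tif.json")
    export_hsv_png(res$orientation_map, file.path(out_dir, "orientation_map.png"))
    if (file.exists(file.path(out_dir, "orientation_map.png"))) put("orientation_map.png")
  }
  if (!is.null(res$significance)) {
    write_map_tiff(res$significance$p, file.path(out_dir, "anova_p.tif"))
    put("anova_p.tif"); put("anova_p.tif.json")
  }
  if (!is.null(res$concentric_map)) {
    write_map_tiff(res$concentric_map, file.path(out_dir, "concentric_map.tif"))
    put("concentric_map.tif"); put("concentric_map.tif.json")
  }
  if (!is.null(res$comparison)) {
    cmp <- res$comparison
    jsonlite::write_json(list(n_pixels = cmp$n_pixels,
                              circ_corr = cmp$circ_corr,
                              p_value = cmp$p_value,
                              median_abs_diff_deg = stats::median(abs(cmp$differences)),
                              min_response_filter = cmp$min_response_filter),
                         file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(cmp$diff_histogram,
                     file.path(out_dir, "diff_histogram.csv"), row.names = FALSE)
    put("comparison.json"); put("diff_histogram.csv")
  }
  manifest <- list(
    parameters = config,
    outputs = lapply(files, function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Per-unit preferred orientation from a trial table
#'
#' Builds each unit's tuning curve, applies the evoked-response inclusion
#' filter, and estimates the preferred orientation by the chosen method:
#' `"argmax"` (response-weighted argmax over tested orientations, the
#' default), `"vector"` (half-argument of the orientation vector sum) or
#' `"vonmises"` (preferred angle of a von Mises fit). For drifting gratings
#' and moving dots the motion-axis label is converted to grating orientation
#' (+90 degrees); static-grating direction labels are taken as orientations
#' directly.
#'
#' @param trials trial table (`penetration_id`, `unit_id`, `depth_um`,
#'   `stimulus_kind`, `direction_deg`, `trial_index`, `response`,
#'   `baseline`).
#' @param method preference estimator.
#' @param min_evoked_hz inclusion threshold (default 2 Hz).
#' @return data.frame of included units: `penetration_id`, `unit_id`,
#'   `depth_um`, `preferred_orientation_deg`, `oi`, `dsi`, `evoked_hz`.
#' @export
unit_orientation_table <- function(trials, method = c("argmax", "vector", "vonmises"),
                                   min_evoked_hz = 2) {
  method <- match.arg(method)
  stopifnot(all(c("penetration_id", "unit_id", "direction_deg", "response")
                %in% names(trials)))
  key <- interaction(trials$penetration_id, trials$unit_id, drop = TRUE)
  dirf <- factor(trials$direction_deg %% 360)
  dirs <- as.numeric(levels(dirf))
  ## per-unit x per-direction trial means, computed in one pass
  mean_mat <- tapply(trials$response, list(key, dirf), mean)
  base_mat <- if ("baseline" %in% names(trials)) {
    tapply(trials$baseline, list(key, dirf), mean)
  } else 0 * mean_mat
  if (anyNA(mean_mat)) stop("incomplete design: a unit misses some direction")
  first <- !duplicated(key)
  meta <- data.frame(key = key[first],
                     penetration_id = trials$penetration_id[first],
                     unit_id = trials$unit_id[first],
                     depth_um = if ("depth_um" %in% names(trials)) {
                       trials$depth_um[first]
                     } else NA_real_,
                     kind = if ("stimulus_kind" %in% names(trials)) {
                       trials$stimulus_kind[first]
                     } else "grating")
  meta <- meta[match(rownames(mean_mat), meta$key), ]
  evoked <- apply(pmax(mean_mat - base_mat, 0), 1, max)
  keep <- evoked >= min_evoked_hz
  if (!any(keep)) stop("no unit passed the evoked-response inclusion filter")

  ## collapse opposing directions (pair average) onto motion-axis labels
  ors <- sort(unique(dirs %% 180))
  col_mat <- vapply(ors, function(o) {
    rowMeans(mean_mat[, dirs %% 180 == o, drop = FALSE])
  }, numeric(nrow(mean_mat)))
  pref_axis <- if (method == "argmax") {
    ors[max.col(col_mat, ties.method = "first")]
  } else {
    vapply(seq_len(nrow(col_mat)), function(i) {
      switch(method,
        vector = preferred_orientation_vector(ors, col_mat[i, ]),
        vonmises = fit_von_mises(ors, col_mat[i, ])$phi_preferred_deg)
    }, numeric(1))
  }
  pref <- ifelse(meta$kind %in% c("grating", "dots"),
                 direction_to_orientation(pref_axis),  # motion axis -> bars
                 wrap_axial(pref_axis))
  cl <- pmax(col_mat, 0)
  i_pref <- max.col(cl, ties.method = "first")
  i_ortho <- vapply(seq_along(i_pref), function(i) {
    which.min(abs(circ_diff_axial(ors, (ors[i_pref[i]] + 90) %% 180)))
  }, integer(1))
  rp <- cl[cbind(seq_len(nrow(cl)), i_pref)]
  ro <- cl[cbind(seq_len(nrow(cl)), i_ortho)]
  oi <- ifelse(rp + ro > 0, (rp - ro) / (rp + ro), NA_real_)
  rc <- pmax(mean_mat, 0)
  th <- deg2rad(dirs)
  dsi <- sqrt((rc %*% sin(th))^2 + (rc %*% cos(th))^2) / rowSums(rc)
  out <- data.frame(penetration_id = meta$penetration_id,
                    unit_id = meta$unit_id, depth_um = meta$depth_um,
                    preferred_orientation_deg = pref, oi = oi,
                    dsi = as.vector(dsi), evoked_hz = evoked)[keep, ]
  rownames(out) <- NULL
  out
}

#' Run the electrophysiology pipeline
#'
#' Trial table in; per-unit preferences, per-penetration columnar statistics
#' (circular mean/variance), the Rayleigh test on penetration means, the
#' columnar shuffle test, and (when receptive-field positions are supplied)
#' the penetration-level concentric comparison out.
#'
#' @param trials trial table as for [unit_orientation_table()].
#' @param config configuration list.
#' @param rf_table optional data.frame `penetration_id`, `rf_azimuth_deg`,
#'   `rf_elevation_deg` enabling the concentric test.
#' @param pref_method preference estimator (see
#'   [unit_orientation_table()]).
#' @param out_dir optional output directory (penetration CSV + JSON report).
#' @return list with `units`, `columnar` (see [columnar_summary()]),
#'   `concentric` (or NULL), `manifest`.
#' @export
run_ephys_pipeline <- function(trials, config = default_config(),
                               rf_table = NULL,
                               pref_method = "argmax", out_dir = NULL) {
  validate_config(config)
  if (is.null(trials) || nrow(trials) == 0L) stop("empty unit trial table")
  units <- unit_orientation_table(trials, method = pref_method,
                                  min_evoked_hz = config$min_evoked_hz)
  columnar <- columnar_summary(units, n_shuffles = config$n_shuffles,
                               seed = config$seed)
  concentric <- NULL
  if (!is.null(rf_table)) {
    summ <- merge(columnar$penetrations, rf_table, by = "penetration_id")
    concentric <- penetration_concentric_test(summ, seed = config$seed)
  }
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(columnar$penetrations,
                     file.path(out_dir, "penetrations.csv"), row.names = FALSE)
    report <- list(
      shuffle = list(real_median_cv = columnar$shuffle$real_median_cv,
                     p_value = columnar$shuffle$p_value,
                     n_shuffles = columnar$shuffle$n_shuffles,
                     seed = columnar$shuffle$seed),
      rayleigh = columnar$rayleigh,
      concentric = if (!is.null(concentric)) {
        list(circ_corr = concentric$circ_corr, p_value = concentric$p_value,
             n = nrow(concentric$table))
      })
    jsonlite::write_json(report, file.path(out_dir, "ephys_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(concentric)) {
      utils::write.csv(concentric$table,
                       file.path(out_dir, "concentric_penetrations.csv"),
                       row.names = FALSE)
    }
    files <- list.files(out_dir)
    manifest <- list(parameters = config,
                     outputs = lapply(files, function(f) {
                       list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
                     }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(units = units, columnar = columnar, concentric = concentric,
       manifest = manifest)
}
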