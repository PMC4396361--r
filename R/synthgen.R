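#' Synthetic imaging and electrophysiology datasets with known ground truth
#'
#' The generators emulate the two data modalities the pipeline analyses:
#' wide-field calcium imaging of the collicular surface under patch and
#' drifting-grating stimulation, and multi-unit recordings along electrode
#' penetrations. Ground truth (per-pixel retinotopy and preferred
#' orientation, per-unit preference, per-penetration receptive field) is
#' returned alongside, so every pipeline stage can be verified end to end.
#' All outputs are a pure function of the parameters and the seed.
#'
#' @name synthgen
#' @keywords internal
NULL

## von Mises sampler, Best & Fisher (1979) rejection method; mu in radians
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi) + mu
    return(atan2(sin(th), cos(th)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
    }
  }
  atan2(sin(out), cos(out))
}

## axial von Mises: orientation = centre + half of a VM(0, kappa) deviate
r_axial_vonmises <- function(n, centre_deg, kappa) {
  wrap_axial(centre_deg + rad2deg(rvonmises(n, 0, kappa)) / 2)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

## indicator response kernel sampled at times t (s) relative to onset:
## saturating rise during the stimulus, mono-exponential decay after offset
indicator_kernel <- function(t, dur_s, tau_rise = 0.3, tau_decay = 1.5) {
  k <- numeric(length(t))
  on <- t >= 0 & t < dur_s
  k[on] <- 1 - exp(-t[on] / tau_rise)
  post <- t >= dur_s
  k_off <- 1 - exp(-dur_s / tau_rise)
  k[post] <- k_off * exp(-(t[post] - dur_s) / tau_decay)
  k
}

## axial von Mises tuning shape on orientations (degrees)
vm_shape <- function(phi_deg, pref_deg) exp(cos(2 * deg2rad(phi_deg - pref_deg)) - 1)

#' Generate a synthetic wide-field imaging dataset
#'
#' Builds a fluorescence stack, the stimulus schedule and the ground truth
#' for a session comprising a retinotopy block (one monitor patch at a time)
#' and an orientation block (full-screen gratings drifting in
#' `length(directions)` directions). Retinotopy is an axis-aligned affine
#' map from the image onto the monitor; per-pixel orientation tuning is
#' centred on the angle given by `rule` at the pixel's retinotopic position:
#' `"concentric"` (the concentric angle, with the nasal ipsilateral field
#' horizontal), `"random_smooth"` (a smooth random orientation field
#' unrelated to retinotopy), or `"uniform_null"` (no orientation tuning at
#' all: equal expected response to every direction).
#'
#' Fluorescence is
#' `F0 * (1 + drift(t) + sum_events amp(pixel) * kernel(t - onset))` plus
#' Gaussian frame noise; the indicator kernel has a saturating rise and a
#' GCaMP6s-like mono-exponential decay.
#'
#' @param dim image (H, W) in pixels (at least 32 x 32).
#' @param rule orientation organization rule.
#' @param geom `monitor_geometry`; the default offsets the monitor into the
#'   contralateral upper visual field.
#' @param directions grating drift directions (degrees).
#' @param reps_grating,reps_patch repetitions per direction / per patch.
#' @param stim_s,isi_s stimulus duration and interstimulus interval
#'   (defaults 3 s and 9 s).
#' @param frame_rate_hz,pixel_size_um acquisition parameters.
#' @param f0 baseline fluorescence level (arbitrary camera units).
#' @param patch_amp_dff peak patch response (dF/F).
#' @param grating_amp_dff grating response scale (dF/F); the per-direction
#'   expected response is `grating_amp_dff * (tuning_dc + tuning_mod *
#'   exp(cos(2 * (phi - pref)) - 1))`.
#' @param tuning_dc,tuning_mod untuned and tuned response components
#'   (`tuning_mod` is forced to 0 under `"uniform_null"`).
#' @param frame_noise_sd Gaussian per-frame, per-pixel noise (same units as
#'   `f0`).
#' @param scatter_sigma_um Gaussian sigma of the optical/retinotopic scatter
#'   applied to every stimulus response profile (default 132 um); this is
#'   the physical blur that concentric-map smoothing is meant to emulate.
#'   Set 0 for a scatter-free preparation.
#' @param drift_amp,drift_period_s slow sinusoidal drift (fraction of `f0`;
#'   a linear trend of the same amplitude spans the recording).
#' @param tau_decay_s indicator decay time constant (default 1.5 s,
#'   GCaMP6s-like).
#' @param reference_region if TRUE a corner block is made visually
#'   non-responsive and marked in the ground truth for reference correction.
#' @param seed integer seed.
#' @return list with `stack` (`imaging_stack`), `schedule` (data.frame:
#'   `onset_s`, `offset_s`, `kind`, `patch_id`, `direction_deg`), and
#'   `ground_truth` (per-pixel `azimuth`, `elevation`, `x`, `y`,
#'   `preferred_orientation` matrices, `reference_roi`, `rule`, the
#'   geometry, the parameters and the seed).
#' @export
gen_imaging_dataset <- function(dim = c(96, 96),
                                rule = c("concentric", "random_smooth", "uniform_null"),
                                geom = monitor_geometry(center_offset_cm = c(40, 10)),
                                directions = seq(0, 315, by = 45),
                                reps_grating = 10, reps_patch = 5,
                                stim_s = 3, isi_s = 9,
                                frame_rate_hz = 1.8, pixel_size_um = 11.04,
                                f0 = 100,
                                patch_amp_dff = 0.06,
                                grating_amp_dff = 0.04,
                                tuning_dc = 0.3, tuning_mod = 1,
                                frame_noise_sd = 1.0,
                                scatter_sigma_um = 132,
                                drift_amp = 0.01, drift_period_s = 300,
                                tau_decay_s = 1.5,
                                reference_region = TRUE,
                                seed = 1) {
  rule <- match.arg(rule)
  stopifnot(all(dim >= 32), reps_grating >= 1, reps_patch >= 1, isi_s > 0)
  h <- dim[1]; w <- dim[2]
  npix <- h * w
  with_seed(seed, {
    ## retinotopy: image spans the monitor (axis-aligned affine map)
    rows <- as.vector(row(matrix(0, h, w))) - 1
    cols <- as.vector(col(matrix(0, h, w))) - 1
    mon_x <- (cols / (w - 1) - 0.5) * geom$width_cm
    mon_y <- (0.5 - rows / (h - 1)) * geom$height_cm
    xyz <- monitor_to_head_xyz(mon_x, mon_y, geom)
    sph <- xyz_to_spherical(xyz[, 1], xyz[, 2], xyz[, 3])
    az <- matrix(sph[, 1], h, w); el <- matrix(sph[, 2], h, w)
    gx <- matrix(xyz[, 1], h, w); gy <- matrix(xyz[, 2], h, w)

    ## per-pixel preferred orientation under the organization rule
    pref <- switch(rule,
      concentric = {
        a <- concentric_angle(gx, gy)
        ipsi <- if (geom$hemisphere == "right") az < 0 else az > 0
        a[ipsi] <- 0
        a[is.na(a)] <- 0
        a
      },
      random_smooth = {
        zr <- spatial_filter(matrix(stats::rnorm(npix), h, w),
                             15 * pixel_size_um, pixel_size_um)
        zi <- spatial_filter(matrix(stats::rnorm(npix), h, w),
                             15 * pixel_size_um, pixel_size_um)
        wrap_axial(rad2deg(atan2(zi, zr) / 2))
      },
      uniform_null = matrix(NA_real_, h, w))
    if (rule == "uniform_null") tuning_mod <- 0

    ## schedule: randomized patch block, then randomized grating block
    patch_seq <- sample(rep(geom$patch_centres_cm$patch_id, reps_patch))
    dir_seq <- sample(rep(directions, reps_grating))
    n_ev <- length(patch_seq) + length(dir_seq)
    onset <- 6 + (seq_len(n_ev) - 1) * (stim_s + isi_s)
    schedule <- data.frame(
      onset_s = onset, offset_s = onset + stim_s,
      kind = c(rep("patch", length(patch_seq)), rep("grating", length(dir_seq))),
      patch_id = c(patch_seq, rep(NA_real_, length(dir_seq))),
      direction_deg = c(rep(NA_real_, length(patch_seq)), dir_seq))

    ref_roi <- matrix(FALSE, h, w)
    if (reference_region) ref_roi[seq_len(min(12, h)), seq_len(min(12, w))] <- TRUE
    responsive <- !as.vector(ref_roi)

    ## patch response profile: Gaussian in retinotopic (monitor) space
    gd <- list(cols = length(unique(round(geom$patch_centres_cm$x_cm, 9))),
               rows = length(unique(round(geom$patch_centres_cm$y_cm, 9))))
    sig_x <- geom$width_cm / gd$cols / 2
    sig_y <- geom$height_cm / gd$rows / 2
    ## optical + retinotopic-position scatter applied to response profiles;
    ## the reference region stays clean (chosen away from responsive tissue)
    scatter <- function(v) {
      if (scatter_sigma_um > 0) {
        v <- as.vector(spatial_filter(matrix(v, h, w), scatter_sigma_um,
                                      pixel_size_um))
      }
      v * responsive
    }
    patch_amp_vec <- function(pid) {
      pc <- geom$patch_centres_cm[geom$patch_centres_cm$patch_id == pid, ]
      scatter(patch_amp_dff * exp(-((mon_x - pc$x_cm)^2 / (2 * sig_x^2) +
                                      (mon_y - pc$y_cm)^2 / (2 * sig_y^2))))
    }
    grating_amp_vec <- function(dir) {
      phi <- direction_to_orientation(dir)
      shape <- if (tuning_mod > 0) {
        tuning_dc + tuning_mod * vm_shape(phi, as.vector(pref))
      } else rep(tuning_dc, npix)
      scatter(grating_amp_dff * shape)
    }
    amp_cache <- new.env(parent = emptyenv())
    amp_for_event <- function(e) {
      key <- paste(schedule$kind[e],
                   schedule$patch_id[e], schedule$direction_deg[e])
      if (is.null(amp_cache[[key]])) {
        amp_cache[[key]] <- if (schedule$kind[e] == "patch") {
          patch_amp_vec(schedule$patch_id[e])
        } else {
          grating_amp_vec(schedule$direction_deg[e])
        }
      }
      amp_cache[[key]]
    }

    ## assemble fluorescence: F0 * (1 + drift + signal) + noise
    n_frames <- ceiling((max(schedule$offset_s) + 6) * frame_rate_hz)
    tmid <- (seq_len(n_frames) - 0.5) / frame_rate_hz
    total_s <- n_frames / frame_rate_hz
    drift <- drift_amp * sin(2 * pi * tmid / drift_period_s) +
      drift_amp * tmid / total_s
    S <- matrix(0, npix, n_frames)
    for (e in seq_len(n_ev)) {
      trel <- tmid - schedule$onset_s[e]
      idx <- which(trel >= 0 & trel <= stim_s + 8 * tau_decay_s)
      if (length(idx) == 0L) next
      kv <- indicator_kernel(trel[idx], stim_s, tau_decay = tau_decay_s)
      S[, idx] <- S[, idx] + outer(amp_for_event(e), kv)
    }
    F <- f0 * (1 + sweep(S, 2, drift, "+"))
    rm(S)
    if (frame_noise_sd > 0) {
      F <- F + matrix(stats::rnorm(npix * n_frames, sd = frame_noise_sd),
                      npix, n_frames)
    }
    F[F < 0] <- 0
    stack <- imaging_stack(array(F, c(h, w, n_frames)),
                           frame_rate_hz = frame_rate_hz,
                           pixel_size_um = pixel_size_um, t0_s = 0)
    gt <- list(azimuth = az, elevation = el, x = gx, y = gy,
               preferred_orientation = pref, reference_roi = ref_roi,
               rule = rule, geom = geom, seed = seed,
               params = list(patch_amp_dff = patch_amp_dff,
                             grating_amp_dff = grating_amp_dff,
                             tuning_dc = tuning_dc, tuning_mod = tuning_mod,
                             frame_noise_sd = frame_noise_sd, f0 = f0,
                             scatter_sigma_um = scatter_sigma_um,
                             drift_amp = drift_amp,
                             drift_period_s = drift_period_s,
                             tau_decay_s = tau_decay_s,
                             stim_s = stim_s, isi_s = isi_s,
                             directions = directions,
                             reps_grating = reps_grating,
                             reps_patch = reps_patch))
    list(stack = stack, schedule = schedule, ground_truth = gt)
  })
}

#' Generate a synthetic electrode-penetration dataset
#'
#' Per penetration a receptive-field position is drawn in the contralateral
#' visual field; each unit's preferred orientation is drawn from an axial
#' von Mises around the penetration's centre orientation, which is set by
#' `rule`: `"columnar_concentric"` (the concentric angle at the
#' penetration's receptive field), `"columnar_random"` (uniform per
#' penetration), or `"null"` (every unit independent and uniform; no
#' columnar structure). Per-trial firing rates are Poisson spike counts over
#' the stimulus window at rate
#' `baseline + amplitude * exp(cos(2 * (phi - pref)) - 1)` with `phi` the
#' grating orientation of the drifting stimulus.
#'
#' @param n_penetrations,units_per_pen ensemble size.
#' @param within_kappa concentration of unit preferences around the
#'   penetration centre (doubled-angle von Mises kappa).
#' @param rule columnar organization rule.
#' @param directions drift directions shown (degrees).
#' @param n_trials trials per direction.
#' @param baseline_hz,amplitude_hz tuning-curve baseline and amplitude.
#' @param stim_s stimulus duration used for the Poisson window.
#' @param az_range,el_range receptive-field azimuth/elevation ranges
#'   (degrees; the defaults stay in the contralateral upper field).
#' @param seed integer seed.
#' @return list with `trials` (data.frame: `penetration_id`, `unit_id`,
#'   `depth_um`, `stimulus_kind`, `direction_deg`, `trial_index`,
#'   `response`, `baseline`) and `ground_truth` (per-penetration receptive
#'   fields and centre orientations, per-unit preferred orientations,
#'   parameters, seed).
#' @export
gen_ephys_dataset <- function(n_penetrations = 20, units_per_pen = 8,
                              within_kappa = 8,
                              rule = c("columnar_concentric", "columnar_random", "null"),
                              directions = seq(0, 337.5, by = 22.5),
                              n_trials = 5,
                              baseline_hz = 2, amplitude_hz = 10,
                              stim_s = 3,
                              az_range = c(5, 60), el_range = c(-10, 40),
                              seed = 1) {
  rule <- match.arg(rule)
  stopifnot(n_penetrations >= 1, units_per_pen >= 1, n_trials >= 1)
  with_seed(seed, {
    rf_az <- stats::runif(n_penetrations, az_range[1], az_range[2])
    rf_el <- stats::runif(n_penetrations, el_range[1], el_range[2])
    xyz <- spherical_to_xyz(rf_az, rf_el)
    centre <- switch(rule,
      columnar_concentric = concentric_angle(xyz[, "x"], xyz[, "y"]),
      columnar_random = stats::runif(n_penetrations, 0, 180),
      null = rep(NA_real_, n_penetrations))
    n_units <- n_penetrations * units_per_pen
    pen_of_unit <- rep(seq_len(n_penetrations), each = units_per_pen)
    prefs <- if (rule == "null") {
      stats::runif(n_units, 0, 180)
    } else {
      unlist(lapply(seq_len(n_penetrations), function(p) {
        r_axial_vonmises(units_per_pen, centre[p], within_kappa)
      }))
    }
    units <- data.frame(penetration_id = pen_of_unit,
                        unit_id = rep(seq_len(units_per_pen), n_penetrations),
                        depth_um = rep((seq_len(units_per_pen) - 1) * 50,
                                       n_penetrations),
                        preferred_orientation_deg = prefs)
    design <- expand.grid(trial_index = seq_len(n_trials),
                          direction_deg = directions)
    n_des <- nrow(design)
    ui <- rep(seq_len(n_units), each = n_des)
    phi <- direction_to_orientation(design$direction_deg)
    lam <- baseline_hz +
      amplitude_hz * vm_shape(rep(phi, n_units), prefs[ui])
    trials <- data.frame(
      penetration_id = units$penetration_id[ui],
      unit_id = units$unit_id[ui],
      depth_um = units$depth_um[ui],
      stimulus_kind = "grating",
      direction_deg = rep(design$direction_deg, n_units),
      trial_index = rep(design$trial_index, n_units),
      response = stats::rpois(n_units * n_des, lam * stim_s) / stim_s,
      baseline = stats::rpois(n_units * n_des, baseline_hz * stim_s) / stim_s)
    list(trials = trials,
         ground_truth = list(
           penetrations = data.frame(penetration_id = seq_len(n_penetrations),
                                     rf_azimuth_deg = rf_az,
                                     rf_elevation_deg = rf_el,
                                     centre_orientation_deg = centre),
           units = units, rule = rule, seed = seed,
           params = list(within_kappa = within_kappa,
                         directions = directions, n_trials = n_trials,
                         baseline_hz = baseline_hz,
                         amplitude_hz = amplitude_hz, stim_s = stim_s)))
  })
}
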