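#' Retinotopic geometry
#'
#' From patch-wise response maps to per-pixel azimuth/elevation in visual
#' space, and from retinotopy to the predicted concentric-orientation map.
#' Head-centred coordinates put `z` along the body axis (straight ahead of
#' the nose), `x` to the animal's right and `y` above the animal.
#'
#' @name retino_geometry
#' @keywords internal
NULL

#' Monitor and head geometry
#'
#' @param width_cm,height_cm monitor dimensions.
#' @param distance_cm monitor distance from the nose along the body axis
#'   (default 29.5 cm).
#' @param center_offset_cm length-2 numeric: horizontal/vertical offset of
#'   the monitor centre from the nose axis (cm; right and up positive).
#' @param patch_centres_cm data.frame with `patch_id`, `x_cm`, `y_cm` giving
#'   each stimulus patch centre on the monitor relative to the monitor
#'   centre (right and up positive). See [patch_grid_centres()].
#' @param head_pitch_deg,head_roll_deg head orientation; positive pitch
#'   rotates the gaze axis downward (so a point straight ahead of the body
#'   appears above the nose axis), roll rotates about the body axis.
#' @param hemisphere imaged/recorded hemisphere, "right" or "left";
#'   determines which azimuth sign is the ipsilateral visual field.
#' @return object of class `monitor_geometry`.
#' @export
monitor_geometry <- function(width_cm = 93, height_cm = 52, distance_cm = 29.5,
                             center_offset_cm = c(0, 0),
                             patch_centres_cm = patch_grid_centres(4, 4, width_cm, height_cm),
                             head_pitch_deg = 0, head_roll_deg = 0,
                             hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(distance_cm > 0, length(center_offset_cm) == 2L,
            all(c("patch_id", "x_cm", "y_cm") %in% names(patch_centres_cm)),
            all(abs(patch_centres_cm$x_cm) <= width_cm / 2 + 1e-9),
            all(abs(patch_centres_cm$y_cm) <= height_cm / 2 + 1e-9))
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 distance_cm = distance_cm,
                 center_offset_cm = center_offset_cm,
                 patch_centres_cm = patch_centres_cm,
                 head_pitch_deg = head_pitch_deg,
                 head_roll_deg = head_roll_deg,
                 hemisphere = hemisphere),
            class = "monitor_geometry")
}

#' Patch centres for a rows x cols monitor partition
#'
#' Splits the monitor into a regular grid of patches. Patch ids are
#' row-major starting at 1 from the top-left patch.
#'
#' @param rows,cols grid dimensions.
#' @param width_cm,height_cm monitor size.
#' @return data.frame with `patch_id`, `x_cm`, `y_cm` (monitor-centre
#'   relative, right/up positive).
#' @export
patch_grid_centres <- function(rows, cols, width_cm, height_cm) {
  pw <- width_cm / cols; ph <- height_cm / rows
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  data.frame(patch_id = seq_len(rows * cols),
             x_cm = -width_cm / 2 + (g$col - 0.5) * pw,
             y_cm = height_cm / 2 - (g$row - 0.5) * ph)
}

#' Monitor-plane point to head-centred cartesian coordinates
#'
#' The monitor plane is orthogonal to the body axis at `distance_cm`;
#' a monitor point at `(x_cm, y_cm)` relative to the monitor centre maps to
#' body-frame coordinates, which are then rotated into the head frame by the
#' head pitch followed by the head roll.
#'
#' @param x_cm,y_cm monitor coordinates (vectors; right/up positive,
#'   monitor-centre relative).
#' @param geom `monitor_geometry`.
#' @return matrix with columns `x`, `y`, `z` (cm).
#' @export
monitor_to_head_xyz <- function(x_cm, y_cm, geom) {
  p <- rbind(x = geom$center_offset_cm[1] + x_cm,
             y = geom$center_offset_cm[2] + y_cm,
             z = rep(geom$distance_cm, length(x_cm)))
  ## pitch about the x-axis, then roll about the z-axis
  Rp <- matrix(c(1, 0, 0,
                 0, cos(deg2rad(geom$head_pitch_deg)), sin(deg2rad(geom$head_pitch_deg)),
                 0, -sin(deg2rad(geom$head_pitch_deg)), cos(deg2rad(geom$head_pitch_deg))),
               3, 3, byrow = TRUE)
  Rr <- matrix(c(cos(deg2rad(geom$head_roll_deg)), sin(deg2rad(geom$head_roll_deg)), 0,
                 -sin(deg2rad(geom$head_roll_deg)), cos(deg2rad(geom$head_roll_deg)), 0,
                 0, 0, 1),
               3, 3, byrow = TRUE)
  out <- t(Rr %*% Rp %*% p)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Cartesian head coordinates to visual-field angles
#'
#' `azimuth = arctan(x / z)`, `elevation = arctan(y / sqrt(x^2 + z^2))`,
#' both in degrees. Valid for points in front of the animal (`z > 0`).
#'
#' @param x,y,z head-centred coordinates (vectors).
#' @return matrix with columns `azimuth_deg`, `elevation_deg`.
#' @export
xyz_to_spherical <- function(x, y, z) {
  if (any(z <= 0)) stop("point behind the animal: z must be positive")
  cbind(azimuth_deg = rad2deg(atan(x / z)),
        elevation_deg = rad2deg(atan(y / sqrt(x^2 + z^2))))
}

#' Visual-field angles to a unit direction vector
#'
#' Inverse of [xyz_to_spherical()] up to scale.
#'
#' @param azimuth_deg,elevation_deg angles in degrees.
#' @return matrix with columns `x`, `y`, `z` (unit vectors).
#' @export
spherical_to_xyz <- function(azimuth_deg, elevation_deg) {
  az <- deg2rad(azimuth_deg); el <- deg2rad(elevation_deg)
  cbind(x = cos(el) * sin(az), y = sin(el), z = cos(el) * cos(az))
}

#' Concentric grating orientation at a visual-field position
#'
#' The orientation tangent to the circle centred on the centre of vision
#' through the point `(x, y)` (the projection of the receptive field onto
#' the plane orthogonal to the body axis): `(90 - atan2(y, x)) mod 180`
#' degrees, with 0 = horizontal grating. On the temporal horizontal axis
#' (`x > 0, y = 0`) this is 90 (vertical); directly above the nose it is 0
#' (horizontal). Undefined at the origin (returns NA).
#'
#' @param x,y head-centred coordinates orthogonal to the body axis.
#' @return orientation in degrees, `[0, 180)`; NA at the origin.
#' @export
concentric_angle <- function(x, y) {
  ang <- wrap_axial(90 - rad2deg(atan2(y, x)))
  ang[x == 0 & y == 0] <- NA_real_
  ang
}

#' Fit a 2D Gaussian to a patch response map
#'
#' Subtracts a small pedestal (0.1 dF/F percentage points by default, i.e.
#' 0.001) from the response map, floors at 0, and least-squares fits an
#' elliptical 2D Gaussian (amplitude, centre, per-axis sigmas; offset fixed
#' at 0), initialised from the thresholded centroid and second moments. The
#' patch is included for retinotopy when its peak response
#' (fitted amplitude + pedestal) reaches `include_threshold` (0.4%
#' by default).
#'
#' @param resp_map `scalar_map` or matrix of per-pixel mean dF/F.
#' @param patch_id identifier carried through to the result.
#' @param subtract pedestal subtracted before fitting; interpreted per
#'   `subtract_mode`.
#' @param subtract_mode "absolute" (dF/F units, default) or
#'   "fraction_of_max" (`subtract` times the map maximum).
#' @param include_threshold minimum fitted peak response (dF/F) for
#'   inclusion.
#' @return object of class `patch_fit`: `patch_id`, `centre_px` (0-based
#'   (row, col)), `sigmas_px`, `amplitude_dff`, `included`, `converged`,
#'   `rss`.
#' @export
fit_patch_gaussian <- function(resp_map, patch_id = NA,
                               subtract = 0.001,
                               subtract_mode = c("absolute", "fraction_of_max"),
                               include_threshold = 0.004) {
  subtract_mode <- match.arg(subtract_mode)
  if (inherits(resp_map, "scalar_map")) {
    m <- resp_map$values; mask <- resp_map$mask
  } else {
    m <- resp_map; mask <- !is.na(m)
  }
  if (sum(mask) < 25L) stop("too few unmasked pixels (< 25) for a patch fit")
  ped <- if (subtract_mode == "absolute") subtract else subtract * max(m[mask])
  v <- pmax(m - ped, 0)
  v[!mask] <- 0
  fail <- function() structure(list(patch_id = patch_id,
                                    centre_px = c(NA_real_, NA_real_),
                                    sigmas_px = c(NA_real_, NA_real_),
                                    amplitude_dff = 0, included = FALSE,
                                    converged = FALSE, rss = NA_real_),
                               class = "patch_fit")
  if (max(v) <= 0) return(fail())
  rows <- row(m) - 1; cols <- col(m) - 1          # 0-based pixel coordinates
  w <- v * (v >= 0.5 * max(v))                    # moments of the bright core
  cr <- sum(rows * w) / sum(w); cc <- sum(cols * w) / sum(w)
  sr <- sqrt(sum((rows - cr)^2 * w) / sum(w)); sr <- max(sr, 0.5)
  sc <- sqrt(sum((cols - cc)^2 * w) / sum(w)); sc <- max(sc, 0.5)
  idx <- which(mask)
  rr <- rows[idx]; cc_ <- cols[idx]; vv <- v[idx]
  resid_fun <- function(p) {
    vv - p[1] * exp(-((rr - p[2])^2 / (2 * p[4]^2) +
                        (cc_ - p[3])^2 / (2 * p[5]^2)))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(max(v), cr, cc, sr, sc), fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(fail())
  p <- fit$par
  amp <- p[1] + ped
  structure(list(patch_id = patch_id,
                 centre_px = c(row = p[2], col = p[3]),
                 sigmas_px = c(abs(p[4]), abs(p[5])),
                 amplitude_dff = amp,
                 included = amp >= include_threshold,
                 converged = TRUE,
                 rss = sum(fit$fvec^2)),
            class = "patch_fit")
}

#' Interpolate dense retinotopy from patch fits
#'
#' Piecewise-linearly interpolates, on the Delaunay triangulation of the
#' included patch centres in pixel space, each patch's monitor coordinates;
#' the interpolant is defined only inside the convex hull of the centres.
#' The interpolated monitor positions are then mapped through
#' [monitor_to_head_xyz()] and [xyz_to_spherical()] per pixel.
#'
#' @param fits list of `patch_fit` objects (ids must match
#'   `geom$patch_centres_cm$patch_id`).
#' @param geom `monitor_geometry`.
#' @param dim length-2 integer, image (H, W) in pixels.
#' @return object of class `retinotopy_maps`: `azimuth`, `elevation`
#'   (`scalar_map`s), `hull_mask`, and per-pixel `x`, `y`, `z`,
#'   `monitor_x_cm`, `monitor_y_cm` matrices.
#' @export
interpolate_retinotopy <- function(fits, geom, dim) {
  inc <- Filter(function(f) isTRUE(f$included), fits)
  if (length(inc) < 3L) stop("insufficient retinotopy: fewer than 3 included patches")
  pr <- vapply(inc, function(f) f$centre_px[1], numeric(1))
  pc <- vapply(inc, function(f) f$centre_px[2], numeric(1))
  ids <- vapply(inc, function(f) as.numeric(f$patch_id), numeric(1))
  mon <- geom$patch_centres_cm[match(ids, geom$patch_centres_cm$patch_id), ]
  if (any(is.na(mon$patch_id))) stop("patch fit id missing from geometry patch grid")
  h <- dim[1]; w <- dim[2]
  q <- expand.grid(row = seq_len(h) - 1, col = seq_len(w) - 1)
  vi <- interp_barycentric(pc, pr, cbind(mon$x_cm, mon$y_cm), q$col, q$row)
  inside <- attr(vi, "inside")
  hull_mask <- matrix(inside, h, w)
  mx <- matrix(vi[, 1], h, w); my <- matrix(vi[, 2], h, w)
  xyz <- matrix(NA_real_, h * w, 3)
  xyz[inside, ] <- monitor_to_head_xyz(vi[inside, 1], vi[inside, 2], geom)
  sph <- matrix(NA_real_, h * w, 2)
  sph[inside, ] <- xyz_to_spherical(xyz[inside, 1], xyz[inside, 2], xyz[inside, 3])
  structure(list(
    azimuth = scalar_map(matrix(sph[, 1], h, w), hull_mask, units = "deg"),
    elevation = scalar_map(matrix(sph[, 2], h, w), hull_mask, units = "deg"),
    hull_mask = hull_mask,
    x = matrix(xyz[, 1], h, w), y = matrix(xyz[, 2], h, w),
    z = matrix(xyz[, 3], h, w),
    monitor_x_cm = mx, monitor_y_cm = my,
    geom = geom), class = "retinotopy_maps")
}

#' Predicted concentric-orientation map from retinotopy
#'
#' Per pixel, the concentric angle of the represented visual-field position
#' `(x, y)`; pixels representing the ipsilateral (nasal) hemifield are set
#' to the horizontal orientation (0 degrees). The map is then smoothed
#' axially (complex-field convolution) with `sigma_um` to emulate
#' receptive-field position scatter and light scatter.
#'
#' @param retino `retinotopy_maps`.
#' @param sigma_um smoothing sigma (default 132 um); 0 disables.
#' @param pixel_size_um pixel pitch.
#' @return `axial_map` of the predicted orientation, amplitude 1 inside the
#'   hull.
#' @export
build_concentric_map <- function(retino, sigma_um = 132, pixel_size_um = 11.04) {
  mask <- retino$hull_mask
  ang <- concentric_angle(retino$x, retino$y)
  az <- retino$azimuth$values
  ipsi <- if (retino$geom$hemisphere == "right") az < 0 else az > 0
  ang[mask & ipsi %in% TRUE] <- 0
  mask <- mask & !is.na(ang)
  ang[!mask] <- NA_real_
  amp <- matrix(0, nrow(ang), ncol(ang)); amp[mask] <- 1
  m <- axial_map(ang, amp, mask)
  if (sigma_um > 0) m <- spatial_filter(m, sigma_um, pixel_size_um)
  m
}

#' Recover head pitch and roll by fitting the concentric-map hypothesis
#'
#' For sessions where head pitch/roll were not recorded: exhaustive grid
#' search over candidate (pitch, roll), rebuilding the concentric map under
#' each and scoring its agreement with the measured orientation map by the
#' mean resultant of the axial angular differences,
#' `mean(cos(2 * (measured - predicted)))` (1 = identical maps, 0 = no
#' relation). Agreement, not circular correlation, is the objective because
#' the Fisher-Lee correlation is invariant under a global rotation of either
#' map and a head roll rotates the whole predicted field by a constant, so
#' roll would be invisible to it. The agreement profile over the grid is
#' returned for sensitivity assessment, together with the circular
#' correlation at the chosen angles; a flat or uniformly low profile is
#' flagged unidentifiable.
#'
#' @param fits list of `patch_fit`s (as for [interpolate_retinotopy()]).
#' @param geom `monitor_geometry` (its pitch/roll entries are overridden).
#' @param measured measured `axial_map` of orientation preference.
#' @param pitch_grid,roll_grid candidate angles in degrees.
#' @param sigma_um smoothing applied to each candidate concentric map.
#' @param pixel_size_um pixel pitch.
#' @return list with `pitch_deg`, `roll_deg`, `agreement`, `correlation`
#'   (circular correlation at the chosen angles), `profile` (agreement
#'   matrix, pitch x roll), `identifiable`.
#' @export
fit_head_angles <- function(fits, geom, measured,
                            pitch_grid = seq(-20, 20, by = 5),
                            roll_grid = seq(-20, 20, by = 5),
                            sigma_um = 132, pixel_size_um = 11.04) {
  stopifnot(length(pitch_grid) >= 1L, length(roll_grid) >= 1L)
  prof <- matrix(NA_real_, length(pitch_grid), length(roll_grid),
                 dimnames = list(pitch_grid, roll_grid))
  for (i in seq_along(pitch_grid)) {
    for (j in seq_along(roll_grid)) {
      g <- geom
      g$head_pitch_deg <- pitch_grid[i]
      g$head_roll_deg <- roll_grid[j]
      pred <- tryCatch({
        r <- interpolate_retinotopy(fits, g, dim(measured$angle_deg))
        build_concentric_map(r, sigma_um, pixel_size_um)
      }, error = function(e) NULL)
      if (is.null(pred)) next
      ok <- measured$mask & pred$mask
      if (sum(ok) < 10L) next
      d <- circ_diff_axial(measured$angle_deg[ok], pred$angle_deg[ok])
      prof[i, j] <- mean(cos(2 * deg2rad(d)))
    }
  }
  if (all(is.na(prof))) stop("head-angle fit failed on the whole grid")
  best <- which(prof == max(prof, na.rm = TRUE), arr.ind = TRUE)[1, ]
  rng <- diff(range(prof, na.rm = TRUE))
  identifiable <- max(prof, na.rm = TRUE) > 0.5 && rng > 0.05
  g <- geom
  g$head_pitch_deg <- pitch_grid[best[1]]
  g$head_roll_deg <- roll_grid[best[2]]
  pred <- build_concentric_map(interpolate_retinotopy(fits, g, dim(measured$angle_deg)),
                               sigma_um, pixel_size_um)
  ok <- measured$mask & pred$mask
  corr <- tryCatch(circ_corr_axial(measured$angle_deg[ok], pred$angle_deg[ok]),
                   error = function(e) NA_real_)
  list(pitch_deg = pitch_grid[best[1]], roll_deg = roll_grid[best[2]],
       agreement = max(prof, na.rm = TRUE), correlation = corr,
       profile = prof, identifiable = identifiable)
}
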