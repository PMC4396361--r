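#' Imaging stacks and per-pixel maps
#'
#' Containers and map constructors for wide-field calcium imaging:
#' stimulus-triggered dF/F, reference-region correction, mask-aware Gaussian
#' filtering, and the retinotopy / polar orientation / ANOVA significance /
#' single-condition maps.
#'
#' @name imaging_maps
#' @keywords internal
NULL

#' Imaging stack container
#'
#' @param frames numeric array H x W x T of nonnegative intensities.
#' @param frame_rate_hz acquisition rate (default 1.8 Hz).
#' @param pixel_size_um pixel pitch (default 11.04 um).
#' @param t0_s acquisition start time in seconds.
#' @return object of class `imaging_stack`.
#' @export
imaging_stack <- function(frames, frame_rate_hz = 1.8, pixel_size_um = 11.04,
                          t0_s = 0) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            frame_rate_hz > 0, pixel_size_um > 0)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, t0_s = t0_s),
            class = "imaging_stack")
}

#' @export
print.imaging_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("imaging_stack: %d x %d pixels, %d frames @ %.2f Hz (%.1f s), %.2f um/px\n",
              d[1], d[2], d[3], x$frame_rate_hz, d[3] / x$frame_rate_hz,
              x$pixel_size_um))
  invisible(x)
}

#' Scalar map container
#' @param values H x W numeric matrix.
#' @param mask H x W logical matrix of valid pixels.
#' @param units unit label.
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask = NULL, units = "") {
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask, units = units),
            class = "scalar_map")
}

#' Axial (orientation) map container
#' @param angle_deg H x W matrix of orientations in `[0, 180)`.
#' @param amplitude H x W matrix of nonnegative amplitudes.
#' @param mask H x W logical matrix.
#' @return object of class `axial_map`.
#' @export
axial_map <- function(angle_deg, amplitude, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(angle_deg)
  stopifnot(identical(dim(angle_deg), dim(amplitude)),
            identical(dim(angle_deg), dim(mask)))
  structure(list(angle_deg = angle_deg, amplitude = amplitude, mask = mask),
            class = "axial_map")
}

## per-frame weights: the fraction of each frame's exposure interval that
## overlaps [start, end); the windowed mean is then the exact time average of
## the frame-wise-constant intensity trace over the window, so it does not
## depend on how the window happens to be phased against the frame clock
frame_window_weights <- function(stack, start_s, end_s) {
  n <- dim(stack$frames)[3]
  lo <- stack$t0_s + (seq_len(n) - 1) / stack$frame_rate_hz
  hi <- lo + 1 / stack$frame_rate_hz
  pmax(0, pmin(hi, end_s) - pmax(lo, start_s)) * stack$frame_rate_hz
}

#' Stimulus-triggered dF/F response to one event
#'
#' The response window runs from 0.3 s after stimulus onset to 2 s after
#' offset; the baseline window from 3 s before onset to 0.3 s after onset.
#' Frames contribute to a window in proportion to the fraction of their
#' exposure interval inside it, so the windowed mean is the exact time
#' average of the (frame-wise constant) intensity trace over the window and
#' is insensitive to how stimulus onsets are phased against the frame
#' clock. The response is `(R_s - R_0) / R_0` with `R_s`, `R_0` the
#' windowed mean intensities, per pixel (or averaged over a region of
#' interest first).
#'
#' @param stack `imaging_stack`.
#' @param onset_s,offset_s stimulus onset and offset times (seconds).
#' @param region optional H x W logical ROI; when given a single scalar
#'   response for the region is returned.
#' @return H x W matrix of dF/F (NA where baseline intensity <= 0), or a
#'   scalar for an ROI; NULL (with a message) when either window contains no
#'   frames.
#' @export
event_response <- function(stack, onset_s, offset_s, region = NULL) {
  stopifnot(offset_s > onset_s)
  w_resp <- frame_window_weights(stack, onset_s + 0.3, offset_s + 2)
  w_base <- frame_window_weights(stack, onset_s - 3, onset_s + 0.3)
  covered <- function(w, len_s) sum(w) >= 0.99 * len_s * stack$frame_rate_hz
  if (!covered(w_resp, offset_s + 2 - onset_s - 0.3) || !covered(w_base, 3.3)) {
    message(sprintf("event at %.1f s skipped: window outside recording", onset_s))
    return(NULL)
  }
  d <- dim(stack$frames)
  fr <- matrix(stack$frames, d[1] * d[2], d[3])
  i_r <- which(w_resp > 0); i_b <- which(w_base > 0)
  r_s <- as.vector(fr[, i_r, drop = FALSE] %*% w_resp[i_r]) / sum(w_resp)
  r_0 <- as.vector(fr[, i_b, drop = FALSE] %*% w_base[i_b]) / sum(w_base)
  if (!is.null(region)) {
    stopifnot(identical(dim(region), d[1:2]))
    rs <- mean(r_s[as.vector(region)]); r0 <- mean(r_0[as.vector(region)])
    if (r0 <= 0) stop("non-positive baseline intensity in region")
    return((rs - r0) / r0)
  }
  resp <- (r_s - r_0) / r_0
  resp[r_0 <= 0] <- NA_real_
  matrix(resp, d[1], d[2])
}

#' Reference-region correction of a dF/F response
#'
#' Divides a response by `1 + ref_resp`, the dF/F of a visually
#' non-responsive reference region, to correct for slow fluorescence changes
#' unrelated to neuronal activity.
#'
#' @param resp dF/F matrix or scalar.
#' @param ref_resp scalar dF/F of the reference region (must be > -1).
#' @return corrected dF/F of the same shape.
#' @export
reference_correct <- function(resp, ref_resp) {
  if (!is.finite(ref_resp) || ref_resp <= -1) {
    stop("invalid reference response (must be > -1)")
  }
  resp / (1 + ref_resp)
}

#' dF/F responses for every event in a schedule
#'
#' Computes `event_response` for each schedule row, optionally applying the
#' reference-region correction with the same event's response in
#' `reference_roi`. Events whose windows fall outside the recording are
#' dropped (and reported).
#'
#' @param stack `imaging_stack`.
#' @param schedule data.frame with columns `onset_s`, `offset_s`, `kind` and
#'   `patch_id` / `direction_deg` as applicable.
#' @param reference_roi optional H x W logical; when NULL the correction is
#'   skipped (and noted).
#' @return list with `resp` (H x W x n_kept array), `events` (kept schedule
#'   rows), `skipped` (dropped row indices).
#' @export
event_response_table <- function(stack, schedule, reference_roi = NULL) {
  stopifnot(all(c("onset_s", "offset_s") %in% names(schedule)))
  d <- dim(stack$frames)
  resp <- array(NA_real_, c(d[1], d[2], nrow(schedule)))
  keep <- logical(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    r <- event_response(stack, schedule$onset_s[i], schedule$offset_s[i])
    if (is.null(r)) next
    if (!is.null(reference_roi)) {
      ref <- event_response(stack, schedule$onset_s[i], schedule$offset_s[i],
                            region = reference_roi)
      r <- reference_correct(r, ref)
    }
    resp[, , i] <- r
    keep[i] <- TRUE
  }
  if (is.null(reference_roi)) {
    message("no reference region supplied: reference correction skipped")
  }
  list(resp = resp[, , keep, drop = FALSE],
       events = schedule[keep, , drop = FALSE],
       skipped = which(!keep))
}

## 1D Gaussian kernel, sum normalised to 1; radius 3 sigma (min 1 px)
gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

## zero-padded separable convolution of a matrix via banded kernel matrices
conv_separable <- function(m, kernel) {
  band <- function(n) {
    r <- (length(kernel) - 1L) / 2L
    K <- matrix(0, n, n)
    for (j in seq_along(kernel)) {
      off <- j - r - 1L
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1L & src <= n
      K[cbind(idx[ok], src[ok])] <- kernel[j]
    }
    K
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Mask-aware Gaussian spatial filtering of a map
#'
#' Scalar maps are smoothed by normalised convolution
#' (`conv(values * mask) / conv(mask)`), so masked-out pixels neither
#' receive nor contribute weight. Axial maps are smoothed in the complex
#' orientation domain: the field `amplitude * exp(2i * angle)` is convolved
#' and the half-angle and modulus are retaken, which avoids wrap artifacts
#' at the 0/180 boundary. `sigma_um = 0` is the identity.
#'
#' @param map `scalar_map`, `axial_map`, or plain matrix.
#' @param sigma_um Gaussian sigma in micrometres.
#' @param pixel_size_um pixel pitch used to convert the sigma to pixels.
#' @return filtered map of the same class.
#' @export
spatial_filter <- function(map, sigma_um, pixel_size_um = 11.04) {
  stopifnot(sigma_um >= 0)
  if (sigma_um == 0) return(map)
  k <- gaussian_kernel_1d(sigma_um / pixel_size_um)
  if (is.matrix(map)) return(conv_separable(map, k))
  if (inherits(map, "scalar_map")) {
    w <- conv_separable(map$mask * 1, k)
    v <- map$values
    v[!map$mask] <- 0
    sv <- conv_separable(v, k)
    out <- ifelse(w > 1e-12, sv / w, NA_real_)
    return(scalar_map(out, map$mask, map$units))
  }
  if (inherits(map, "axial_map")) {
    a <- map$amplitude
    a[!map$mask] <- 0
    ang0 <- map$angle_deg
    ang0[!map$mask | is.na(ang0)] <- 0   # zero-amplitude pixels contribute nothing
    z_re <- conv_separable(a * cos(2 * deg2rad(ang0)), k)
    z_im <- conv_separable(a * sin(2 * deg2rad(ang0)), k)
    w <- conv_separable(map$mask * 1, k)
    amp <- sqrt(z_re^2 + z_im^2) / pmax(w, 1e-12)
    ang <- wrap_axial(rad2deg(atan2(z_im, z_re) / 2))
    mask <- map$mask & amp > 0
    ang[!mask] <- NA_real_
    return(axial_map(ang, amp, mask))
  }
  stop("unsupported map type")
}

#' Per-condition trial-mean response maps
#'
#' Averages event responses over trials within each condition (patch id or
#' drift direction) and spatially filters each mean map.
#'
#' @param resp_table output of [event_response_table()].
#' @param by grouping column: "patch_id" or "direction_deg".
#' @param sigma_um smoothing sigma (default 33 um); 0 disables.
#' @param pixel_size_um pixel pitch.
#' @return named list of H x W matrices, one per condition level (names are
#'   the condition values).
#' @export
condition_mean_maps <- function(resp_table, by = c("patch_id", "direction_deg"),
                                sigma_um = 33, pixel_size_um = 11.04) {
  by <- match.arg(by)
  stopifnot(by %in% names(resp_table$events))
  g <- resp_table$events[[by]]
  levels <- sort(unique(g))
  out <- lapply(levels, function(lv) {
    i <- which(g == lv)
    m <- apply(resp_table$resp[, , i, drop = FALSE], c(1, 2), mean)
    spatial_filter(m, sigma_um, pixel_size_um)
  })
  names(out) <- as.character(levels)
  out
}

#' Retinotopy map by patch argmax
#'
#' Assigns to each pixel the patch to which it responded most (trial-mean
#' dF/F after correction and filtering); the map's amplitude is that maximal
#' response. Ties go to the lowest patch id (reported); pixels with no
#' positive response to any patch are masked.
#'
#' @param patch_maps named list of per-patch mean response matrices
#'   ([condition_mean_maps()] with `by = "patch_id"`).
#' @return list with `patch` (`scalar_map` of best patch id) and `amplitude`
#'   (`scalar_map` of the maximal response).
#' @export
retinotopy_argmax_map <- function(patch_maps) {
  stopifnot(length(patch_maps) >= 1L)
  ids <- as.numeric(names(patch_maps))
  o <- order(ids)
  arr <- simplify2array(patch_maps[o])
  best <- apply(arr, c(1, 2), which.max)
  amp <- apply(arr, c(1, 2), max)
  n_tie <- sum(apply(arr, c(1, 2), function(v) sum(v == max(v)) > 1L) & amp > 0)
  if (n_tie > 0) message(sprintf("%d pixels tied; assigned lowest patch id", n_tie))
  mask <- amp > 0
  patch_id <- matrix(ids[o][best], nrow(amp), ncol(amp))
  patch_id[!mask] <- NA_real_
  list(patch = scalar_map(patch_id, mask, units = "patch_id"),
       amplitude = scalar_map(amp, mask, units = "dF/F"))
}

#' Polar orientation preference map
#'
#' For each pixel, the response `R(phi)` to each grating orientation is the
#' larger of the trial-mean responses to the two opposing drift directions
#' (clamped at 0); the preferred orientation is half the argument of
#' `sum R(phi) exp(2i phi)`. Orientations follow the grating convention:
#' orientation = (drift direction + 90) mod 180. The amplitude channel is the
#' mean response over all directions (used for saturation scaling on export).
#'
#' @param dir_maps named list of per-direction mean response matrices
#'   ([condition_mean_maps()] with `by = "direction_deg"`); an even number of
#'   directions, each with its opposite present.
#' @return `axial_map`; pixels with zero resultant or no positive response
#'   are masked.
#' @export
orientation_polar_map <- function(dir_maps) {
  dirs <- as.numeric(names(dir_maps))
  if (length(dirs) %% 2L != 0L ||
      !all((dirs + 180) %% 360 %in% (dirs %% 360))) {
    stop("directions must come in opposing pairs")
  }
  ors <- sort(unique(direction_to_orientation(dirs)))
  h <- nrow(dir_maps[[1]]); w <- ncol(dir_maps[[1]])
  z_re <- matrix(0, h, w); z_im <- matrix(0, h, w); r_sum <- matrix(0, h, w)
  for (o in ors) {
    pair <- which(direction_to_orientation(dirs) == o)
    stopifnot(length(pair) == 2L)
    r <- pmax(pmax(dir_maps[[pair[1]]], dir_maps[[pair[2]]]), 0)
    z_re <- z_re + r * cos(2 * deg2rad(o))
    z_im <- z_im + r * sin(2 * deg2rad(o))
    r_sum <- r_sum + r
  }
  all_mean <- Reduce(`+`, dir_maps) / length(dir_maps)
  res <- sqrt(z_re^2 + z_im^2)
  mask <- r_sum > 0 & res > 1e-12 * pmax(r_sum, 1e-300)
  ang <- wrap_axial(rad2deg(atan2(z_im, z_re) / 2))
  ang[!mask] <- NA_real_
  axial_map(ang, pmax(all_mean, 0), mask)
}

#' Per-pixel ANOVA significance map across orientations
#'
#' One-way fixed-effects ANOVA of the per-trial dF/F across the four
#' orientation groups (opposing drift directions pooled), computed per pixel.
#' Degenerate pixels (zero within-group variance) get p = 0 when the group
#' means differ and p = 1 when they do not.
#'
#' @param resp_table output of [event_response_table()] restricted to grating
#'   events; `events$direction_deg` defines the groups via
#'   `direction mod 180`.
#' @param alpha significance level for the thresholded mask (default 0.05).
#' @return list with `p` (`scalar_map` of p-values) and `significant`
#'   (`scalar_map`, 1 where p < alpha).
#' @export
anova_significance_map <- function(resp_table, alpha = 0.05) {
  g <- factor(resp_table$events$direction_deg %% 180)
  if (any(table(g) < 2L)) stop("need at least 2 trials per orientation group")
  d <- dim(resp_table$resp)
  M <- matrix(resp_table$resp, d[1] * d[2], d[3])
  p <- anova_p_rows(M, g)
  pm <- matrix(p, d[1], d[2])
  mask <- matrix(rowSums(is.na(M)) == 0, d[1], d[2])
  pm[!mask] <- NA_real_
  list(p = scalar_map(pm, mask, units = "p"),
       significant = scalar_map((pm < alpha) * 1, mask, units = ""))
}

## vectorised one-way ANOVA p for each row of M with grouping g
anova_p_rows <- function(M, g) {
  g <- factor(g)
  n <- ncol(M)
  k <- nlevels(g)
  ni <- as.vector(table(g))
  G <- stats::model.matrix(~ g - 1)          # n x k indicator
  gs <- M %*% G                              # row group sums
  gm <- sweep(gs, 2, ni, "/")
  grand <- rowMeans(M)
  ssb <- as.vector(sweep(gm, 1, grand, "-")^2 %*% ni)
  sst <- rowSums(sweep(M, 1, grand, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb > 1e-300] <- 0
  p[ssw == 0 & ssb <= 1e-300] <- 1
  p
}

#' Single-condition response map
#'
#' Mean response over a selected set of directions minus the mean response
#' over all directions (cocktail-blank subtraction).
#'
#' @param dir_maps named list of per-direction mean response matrices.
#' @param selected character or numeric vector naming the selected
#'   directions (must be a non-empty subset of `names(dir_maps)`).
#' @return H x W matrix.
#' @export
single_condition_map <- function(dir_maps, selected) {
  sel <- as.character(selected)
  stopifnot(length(sel) >= 1L, all(sel %in% names(dir_maps)))
  m_sel <- Reduce(`+`, dir_maps[sel]) / length(sel)
  m_all <- Reduce(`+`, dir_maps) / length(dir_maps)
  m_sel - m_all
}
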