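#' Tuning curves and selectivity indices
#'
#' Functions operating on per-trial unit responses to drifting/static gratings
#' or moving-dot stimuli: per-direction tuning curves, orientation and
#' direction selectivity indices, vector-sum preferred orientation and von
#' Mises fits.
#'
#' @name tuning
#' @keywords internal
NULL

#' Build a direction tuning curve from a trial table
#'
#' Averages per-trial responses within each stimulus direction and applies the
#' minimum-evoked-response inclusion filter: a unit is included when the
#' largest baseline-subtracted mean response over directions, floored at 0, is
#' at least `min_evoked_hz` (default 2 Hz, the standard unit-inclusion
#' criterion for these recordings).
#'
#' @param trial_table data.frame with columns `direction_deg`, `response`
#'   and optionally `baseline` (same units as `response`; 0 when absent).
#' @param min_evoked_hz inclusion threshold on the evoked response.
#' @return object of class `direction_tuning`: list with `directions`,
#'   `mean_response`, `sem`, `n_trials`, `trial_matrix` (list of per-direction
#'   trial vectors), `evoked`, `included`.
#' @export
trials_to_tuning <- function(trial_table, min_evoked_hz = 2.0) {
  stopifnot(is.data.frame(trial_table),
            all(c("direction_deg", "response") %in% names(trial_table)))
  base <- if ("baseline" %in% names(trial_table)) trial_table$baseline else 0
  dirs <- sort(unique(trial_table$direction_deg %% 360))
  sp <- split(seq_len(nrow(trial_table)), trial_table$direction_deg %% 360)
  mean_r <- vapply(sp, function(i) mean(trial_table$response[i]), numeric(1))
  n_tr <- vapply(sp, length, integer(1))
  sem <- vapply(sp, function(i) {
    if (length(i) < 2L) return(0)
    stats::sd(trial_table$response[i]) / sqrt(length(i))
  }, numeric(1))
  if (any(n_tr < 2L)) {
    warning("single trial for some directions: sem reported as 0")
  }
  mean_b <- vapply(sp, function(i) mean(rep(base, length.out = nrow(trial_table))[i]),
                   numeric(1))
  evoked <- max(pmax(mean_r - mean_b, 0))
  structure(list(directions = dirs,
                 mean_response = unname(mean_r[as.character(dirs)]),
                 sem = unname(sem[as.character(dirs)]),
                 n_trials = unname(n_tr[as.character(dirs)]),
                 trial_matrix = lapply(sp, function(i) trial_table$response[i])[as.character(dirs)],
                 evoked = evoked,
                 included = evoked >= min_evoked_hz),
            class = "direction_tuning")
}

#' Collapse direction responses onto orientations
#'
#' Pairs each direction with its opposite (180 degrees apart) and combines the
#' two responses, yielding orientation responses `R(phi)` labelled by the
#' motion axis `direction mod 180`. `mode = "average"` takes the mean of the
#' opposing pair (the convention behind the orientation index);
#' `mode = "max"` takes the larger of the two (the convention used for
#' per-pixel polar maps).
#'
#' @param tuning `direction_tuning` object, or a list with `directions` and
#'   `mean_response`.
#' @param mode "average" or "max".
#' @return list with `orientations` (degrees in `[0, 180)`) and `response`.
#' @export
collapse_directions <- function(tuning, mode = c("average", "max")) {
  mode <- match.arg(mode)
  dirs <- tuning$directions %% 360
  r <- tuning$mean_response
  if (length(dirs) %% 2L != 0L) stop("unpaired directions: odd direction count")
  ors <- sort(unique(dirs %% 180))
  resp <- vapply(ors, function(o) {
    i <- which(dirs %% 180 == o)
    if (length(i) != 2L) stop("unpaired directions: ", o, " lacks its opposite")
    if (mode == "average") mean(r[i]) else max(r[i])
  }, numeric(1))
  list(orientations = ors, response = resp)
}

#' Orientation index
#'
#' `OI = (R_pref - R_ortho) / (R_pref + R_ortho)` where `R_pref` is the
#' largest orientation response (argmax over tested orientations) and
#' `R_ortho` the response at the orthogonal orientation. Responses are clamped
#' at 0 first so the index lies in `[0, 1]`.
#'
#' @param orientations tested orientations in degrees, `[0, 180)`.
#' @param response orientation responses `R(phi)` (same length).
#' @return orientation index in `[0, 1]`.
#' @examples
#' orientation_index(c(0, 45, 90, 135), c(8, 5, 2, 5)) # 0.6
#' @export
orientation_index <- function(orientations, response) {
  stopifnot(length(orientations) == length(response))
  r <- pmax(response, 0)
  i_pref <- which.max(r)
  ortho <- (orientations[i_pref] + 90) %% 180
  i_ortho <- which(abs(circ_diff_axial(orientations, ortho)) < 1e-6)
  if (length(i_ortho) == 0L) {
    stop("orthogonal of the preferred orientation was not tested")
  }
  rp <- r[i_pref]; ro <- r[i_ortho[1]]
  if (rp + ro == 0) stop("unresponsive: R_pref + R_ortho is zero")
  (rp - ro) / (rp + ro)
}

#' Direction selectivity index
#'
#' Normalised vector sum over direction responses,
#' `DSI = |sum R(phi) exp(i phi)| / sum R(phi)`, with negative responses
#' clamped to 0. Units with `DSI > 0.5` are flagged direction selective.
#'
#' @param tuning `direction_tuning` object (or list with `directions`,
#'   `mean_response`).
#' @return list with `dsi` in `[0, 1]` and `is_direction_selective`.
#' @export
direction_selectivity_index <- function(tuning) {
  r <- pmax(tuning$mean_response, 0)
  if (sum(r) == 0) stop("unresponsive: all direction responses zero")
  th <- deg2rad(tuning$directions)
  dsi <- sqrt(sum(r * sin(th))^2 + sum(r * cos(th))^2) / sum(r)
  list(dsi = dsi, is_direction_selective = dsi > 0.5)
}

#' Vector-sum preferred orientation
#'
#' Half the argument of `sum R(phi) exp(2i phi)` over the tested orientations,
#' with responses clamped at 0; the standard polar-map preference estimator.
#'
#' @inheritParams orientation_index
#' @return preferred orientation in degrees, `[0, 180)`.
#' @export
preferred_orientation_vector <- function(orientations, response) {
  r <- pmax(response, 0)
  if (sum(r) == 0) stop("unresponsive: all orientation responses zero")
  circ_mean_axial(orientations, weights = r)
}

#' Fit a von Mises orientation tuning curve
#'
#' Least-squares fit of `R(phi) = baseline + amplitude *
#' exp(cos(2*(phi - phi_pref)) - 1)` with concentration fixed at 1 (the
#' standard narrow-band orientation tuning shape). For a candidate
#' `phi_pref` the model is linear in `(baseline, amplitude)`, so the fit
#' profiles the preferred angle: a 1-degree grid solve followed by golden
#' section refinement around the best grid point. Setting `free_kappa = TRUE`
#' additionally profiles the concentration over a log-spaced grid.
#'
#' @inheritParams orientation_index
#' @param free_kappa if TRUE the concentration is fitted too (default fixed
#'   at 1).
#' @return object of class `von_mises_fit`: `phi_preferred_deg`, `amplitude`,
#'   `baseline`, `kappa`, `rss`, `reliable` (FALSE when the fitted amplitude
#'   is not positive).
#' @export
fit_von_mises <- function(orientations, response, free_kappa = FALSE) {
  stopifnot(length(orientations) == length(response))
  if (length(orientations) < 4L) stop("need at least 4 tested orientations")
  kappas <- if (free_kappa) exp(seq(log(0.25), log(8), length.out = 13)) else 1
  best <- NULL
  for (k in kappas) {
    basis <- function(phi0) exp(k * (cos(2 * deg2rad(orientations - phi0)) - 1))
    ## linear solve in (baseline, amplitude) with the amplitude constrained
    ## nonnegative (a tuning curve modulates upward from its baseline)
    solve_at <- function(phi0) {
      X <- cbind(1, basis(phi0))
      cf <- stats::lm.fit(X, response)$coefficients
      if (is.na(cf[2]) || cf[2] < 0) cf <- c(mean(response), 0)
      list(coef = cf, rss = sum((response - X %*% cf)^2))
    }
    rss_at <- function(phi0) solve_at(phi0)$rss
    grid <- seq(0, 179, by = 1)
    rs <- vapply(grid, rss_at, numeric(1))
    p0 <- grid[which.min(rs)]
    opt <- stats::optimize(rss_at, interval = c(p0 - 1, p0 + 1))
    phi <- wrap_axial(opt$minimum)
    cf <- solve_at(opt$minimum)$coef
    cand <- list(phi_preferred_deg = phi, amplitude = unname(cf[2]),
                 baseline = unname(cf[1]), kappa = k, rss = opt$objective)
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  best$reliable <- is.finite(best$amplitude) && best$amplitude > 0
  if (!best$reliable) best$phi_preferred_deg <- NA_real_
  class(best) <- "von_mises_fit"
  best
}

#' Orientation change rate along a horizontal track
#'
#' Mean over consecutive recording positions of the absolute axial
#' orientation difference per unit distance, scaled to degrees per 100
#' micrometres. Wrap across the 0/180 boundary is handled axially (170 to 10
#' degrees counts as a 20-degree change).
#'
#' @param position_um strictly increasing recording positions (micrometres).
#' @param angle_deg preferred orientations at those positions, `[0, 180)`.
#' @return rate of change in degrees per 100 um.
#' @export
orientation_gradient <- function(position_um, angle_deg) {
  stopifnot(length(position_um) == length(angle_deg))
  if (length(position_um) < 2L) stop("need at least 2 positions")
  if (any(diff(position_um) <= 0)) stop("invalid track: positions must strictly increase")
  d_ang <- abs(circ_diff_axial(angle_deg[-1], angle_deg[-length(angle_deg)]))
  d_pos <- diff(position_um)
  mean(d_ang / d_pos) * 100
}

#' Direction of motion to grating orientation
#'
#' A grating drifting in direction `d` (degrees; 0 = nasal-to-temporal,
#' 90 = upward) has its bars oriented at `(d + 90) mod 180`, so an
#' upward-drifting grating is horizontal (0 degrees).
#'
#' @param direction_deg drift direction(s) in degrees.
#' @return grating orientation(s) in `[0, 180)`.
#' @export
direction_to_orientation <- function(direction_deg) (direction_deg + 90) %% 180
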