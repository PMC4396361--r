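#' Axial circular statistics
#'
#' Orientations are axial data: angles with period 180 degrees. All axial
#' statistics here follow the standard angle-doubling construction: each
#' orientation `phi` is mapped to the unit vector `exp(2i*phi)`, resultants are
#' formed on the doubled circle, and mean angles are halved back into
#' `[0, 180)`.
#'
#' @name circstats
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 180 into `[0, 180)`.
#' @export
wrap_axial <- function(x) x %% 180

## complex resultant of doubled angles; weights default to 1
axial_resultant <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) < 1L) stop("at least one angle is required")
  if (any(!is.finite(angles_deg))) stop("angles must be finite")
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (length(weights) != length(angles_deg)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  sum(weights * exp(2i * deg2rad(angles_deg)))
}

#' Axial circular mean
#'
#' Half the argument of the resultant of doubled angles,
#' `0.5 * arg(sum w * exp(2i*phi))`, mapped into `[0, 180)`.
#'
#' @param angles_deg orientations in degrees, each in `[0, 180)`.
#' @param weights optional nonnegative weights (default all 1).
#' @return the mean orientation in degrees, in `[0, 180)`.
#' @examples
#' circ_mean_axial(c(0, 40))   # 20
#' circ_mean_axial(c(10, 170)) # 0
#' @export
circ_mean_axial <- function(angles_deg, weights = NULL) {
  z <- axial_resultant(angles_deg, weights)
  if (Mod(z) < 1e-12 * max(1, sum(abs(weights %||% rep(1, length(angles_deg)))))) {
    stop("undefined axial mean: resultant of doubled angles is zero")
  }
  wrap_axial(rad2deg(Arg(z) / 2))
}

#' Axial circular variance
#'
#' `1 - |sum w * exp(2i*phi)| / sum w`: 0 when all orientations coincide,
#' 1 when the doubled angles balance exactly (e.g. two orthogonal
#' orientations with equal weight).
#'
#' @inheritParams circ_mean_axial
#' @return circular variance in `[0, 1]`.
#' @examples
#' circ_var_axial(c(77, 77, 77)) # 0
#' circ_var_axial(c(0, 90))      # 1
#' circ_var_axial(c(0, 45))      # 1 - sqrt(2)/2
#' @export
circ_var_axial <- function(angles_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  z <- axial_resultant(angles_deg, weights)
  v <- 1 - Mod(z) / sum(weights)
  min(max(v, 0), 1)
}

#' Signed minimal axial difference
#'
#' Difference `a - b` between two orientations, wrapped to `[-90, 90]`.
#' The antipodal case (difference exactly 90 degrees) returns +90 by
#' convention.
#'
#' @param a,b orientations in degrees (vectorised, recycled).
#' @return signed difference in degrees, `|result| <= 90`.
#' @examples
#' circ_diff_axial(10, 170)  # 20
#' circ_diff_axial(45, 135)  # 90 (tie-break)
#' @export
circ_diff_axial <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Fisher-Lee circular correlation for orientations
#'
#' The Fisher-Lee circular-circular correlation applied to doubled angles
#' (axial to directional). Computed through the O(n) resultant identity
#' \deqn{\sum_{i<j}\sin(\alpha_i-\alpha_j)\sin(\beta_i-\beta_j)
#'   = \tfrac12\left(|\textstyle\sum e^{i(\alpha-\beta)}|^2
#'   - |\sum e^{i(\alpha+\beta)}|^2\right)/1}
#' with \eqn{\alpha = 2a}, \eqn{\beta = 2b} in radians, and analogous
#' identities for the denominator terms.
#'
#' @param a,b equal-length vectors of orientations in degrees, `n >= 3`.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
circ_corr_axial <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  al <- deg2rad(2 * a)
  be <- deg2rad(2 * b)
  denom_a <- n^2 - Mod(sum(exp(2i * al)))^2
  denom_b <- n^2 - Mod(sum(exp(2i * be)))^2
  if (denom_a < 1e-9 * n^2 || denom_b < 1e-9 * n^2) {
    stop("degenerate (zero circular variance) input to circ_corr_axial")
  }
  num <- Mod(sum(exp(1i * (al - be))))^2 - Mod(sum(exp(1i * (al + be))))^2
  num / sqrt(denom_a * denom_b)
}

#' Rayleigh test for circular non-uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle. For axial data (`period_deg = 180`) angles are doubled first.
#' Uses the statistic `Z = n * R^2` (R the mean resultant length) with the
#' finite-sample series correction of Zar (1999, eq. 27.4).
#'
#' @param angles_deg angles in degrees.
#' @param period_deg 360 for directional data, 180 for axial data.
#' @return list with `p_value`, `z` (the Rayleigh statistic) and `n`.
#' @export
rayleigh_test <- function(angles_deg, period_deg = 360) {
  n <- length(angles_deg)
  if (n < 5L) stop("insufficient data for the Rayleigh test (n < 5)")
  if (!period_deg %in% c(180, 360)) stop("period_deg must be 180 or 360")
  th <- deg2rad(angles_deg) * (360 / period_deg)
  R <- Mod(sum(exp(1i * th))) / n
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(p_value = min(max(p, .Machine$double.xmin), 1), z = z, n = n)
}

## circular variance per penetration for a pooled angle vector + grouping;
## groups with zero resultant contribute cv = 1 by construction of the formula
penetration_cvs <- function(angles_deg, group) {
  vapply(split(angles_deg, group), circ_var_axial, numeric(1))
}

#' Permutation test for columnar clustering of orientation preference
#'
#' The observed statistic is the median over penetrations of the axial
#' circular variance of the unit orientation preferences recorded on each
#' penetration. The null distribution is obtained by repeatedly redistributing
#' the pooled preferences at random over all recording positions on all
#' penetrations (the penetration sizes are preserved) and recomputing the
#' median. Low observed medians indicate that units on a penetration share an
#' orientation preference more than chance allows.
#'
#' @param penetrations list of numeric vectors, one per penetration, each the
#'   preferred orientations (degrees, `[0, 180)`) of its units; at least two
#'   penetrations with at least two units each.
#' @param n_shuffles number of random redistributions (default 10000).
#' @param seed integer seed; the test is bit-reproducible given the seed.
#' @return object of class `shuffle_test` with fields `real_median_cv`,
#'   `null_median_cvs`, `p_value`, `n_shuffles`, `seed`. The p-value uses the
#'   add-one estimator `(1 + #\{null <= real\}) / (1 + n_shuffles)`.
#' @export
shuffle_columnar_test <- function(penetrations, n_shuffles = 10000, seed = 1) {
  stopifnot(is.list(penetrations))
  if (length(penetrations) < 2L) stop("need at least 2 penetrations")
  sizes <- lengths(penetrations)
  if (any(sizes < 2L)) stop("each penetration needs at least 2 angles")
  pooled <- unlist(penetrations, use.names = FALSE)
  n_tot <- length(pooled)
  if (n_tot < 4L) stop("need at least 4 angles in total")
  group <- rep(seq_along(penetrations), sizes)

  real_median <- stats::median(penetration_cvs(pooled, group))

  ## vectorised null: one column per shuffle of the pooled doubled-angle
  ## vectors; per-penetration resultants via rowsum over the fixed grouping.
  ## Pool and sizes are put in canonical (sorted) order first so the null --
  ## and hence the p-value -- is invariant to penetration and unit ordering.
  pooled <- sort(pooled)
  sizes <- sort(sizes)
  group <- rep(seq_along(sizes), sizes)
  z <- exp(2i * deg2rad(pooled))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perms <- vapply(seq_len(n_shuffles), function(i) sample.int(n_tot),
                  integer(n_tot))
  zp <- matrix(z[perms], nrow = n_tot)
  re <- rowsum(Re(zp), group)
  im <- rowsum(Im(zp), group)
  cvs <- 1 - sqrt(re^2 + im^2) / sizes
  null_medians <- apply(cvs, 2, stats::median)

  p <- (1 + sum(null_medians <= real_median)) / (1 + n_shuffles)
  structure(list(real_median_cv = real_median,
                 null_median_cvs = null_medians,
                 p_value = p, n_shuffles = n_shuffles, seed = seed),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat("Columnar shuffle test\n")
  cat(sprintf("  real median circular variance: %.4f\n", x$real_median_cv))
  cat(sprintf("  null median (of %d shuffles):  %.4f\n",
              x$n_shuffles, stats::median(x$null_median_cvs)))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
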