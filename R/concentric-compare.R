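#' Measured-versus-predicted orientation comparison
#'
#' Quantitative comparison of measured orientation preference with the
#' concentric prediction, for imaging maps and for electrode penetrations,
#' plus per-penetration columnar summaries.
#'
#' @name concentric_compare
#' @keywords internal
NULL

#' Minimum-response pixel filter
#'
#' A pixel qualifies when its per-condition mean response reaches
#' `threshold` (default 0.5% dF/F). The strict reading requires every
#' condition to pass (`mode = "all"`); `mode = "any"` is the lenient
#' alternative.
#'
#' @param dir_maps named list of per-direction mean response matrices.
#' @param threshold minimum mean dF/F per condition (default 0.005).
#' @param mode "all" (every condition, default) or "any".
#' @return H x W logical matrix.
#' @export
min_response_mask <- function(dir_maps, threshold = 0.005,
                              mode = c("all", "any")) {
  mode <- match.arg(mode)
  passes <- lapply(dir_maps, function(m) m >= threshold)
  if (mode == "all") Reduce(`&`, passes) else Reduce(`|`, passes)
}

#' Compare a measured orientation map with the concentric prediction
#'
#' Pixels passing both map masks and the minimum-response filter enter the
#' axial circular correlation and a histogram of the signed angular
#' differences (measured minus predicted, 18 bins of 10 degrees over
#' [-90, 90]). An optional permutation test shuffles the pixel pairing to
#' attach a p-value to the correlation.
#'
#' @param measured,predicted `axial_map`s of equal dimension.
#' @param response_mask optional H x W logical from [min_response_mask()];
#'   TRUE everywhere when NULL.
#' @param min_mean_response recorded in the result for provenance (the mask
#'   itself must be computed upstream where the per-condition responses
#'   live).
#' @param n_perm permutations for the correlation p-value (0 disables).
#' @param seed permutation seed.
#' @return object of class `map_comparison`: `n_pixels`, `circ_corr`,
#'   `p_value` (NA when `n_perm = 0`), `diff_histogram` (data.frame with
#'   `mid`, `lower`, `upper`, `count`), `min_response_filter`, `differences`.
#' @export
compare_orientation_to_concentric <- function(measured, predicted,
                                              response_mask = NULL,
                                              min_mean_response = 0.005,
                                              n_perm = 1000, seed = 1) {
  stopifnot(inherits(measured, "axial_map"), inherits(predicted, "axial_map"),
            identical(dim(measured$angle_deg), dim(predicted$angle_deg)))
  ok <- measured$mask & predicted$mask
  if (!is.null(response_mask)) ok <- ok & response_mask
  n <- sum(ok)
  if (n < 10L) stop("insufficient overlap: fewer than 10 qualifying pixels")
  a <- measured$angle_deg[ok]
  b <- predicted$angle_deg[ok]
  rho <- circ_corr_axial(a, b)
  d <- circ_diff_axial(a, b)
  edges <- seq(-90, 90, by = 10)
  cut_i <- pmin(findInterval(d, edges, rightmost.closed = TRUE), 18L)
  counts <- tabulate(cut_i, nbins = 18L)
  hist_df <- data.frame(lower = edges[-19], upper = edges[-1],
                        mid = (edges[-19] + edges[-1]) / 2, count = counts)
  p <- NA_real_
  if (n_perm > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    null_rho <- vapply(seq_len(n_perm), function(i) {
      circ_corr_axial(a, b[sample.int(n)])
    }, numeric(1))
    p <- (1 + sum(abs(null_rho) >= abs(rho))) / (1 + n_perm)
  }
  structure(list(n_pixels = n, circ_corr = rho, p_value = p,
                 diff_histogram = hist_df, differences = d,
                 min_response_filter = min_mean_response),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat("Orientation map vs concentric prediction\n")
  cat(sprintf("  qualifying pixels: %d\n", x$n_pixels))
  cat(sprintf("  circular correlation: %.3f", x$circ_corr))
  if (!is.na(x$p_value)) cat(sprintf("  (permutation p = %.4g)", x$p_value))
  cat(sprintf("\n  median |angle difference|: %.1f deg\n",
              stats::median(abs(x$differences))))
  invisible(x)
}

#' Concentric-orientation test across electrode penetrations
#'
#' For each penetration the concentric angle at its receptive-field position
#' is computed through the geometry transforms and compared with the
#' penetration's circular-mean preferred orientation.
#'
#' @param summaries data.frame with columns `penetration_id`,
#'   `circ_mean_deg`, `rf_azimuth_deg`, `rf_elevation_deg`.
#' @param n_perm permutations for the correlation p-value (0 disables).
#' @param seed permutation seed.
#' @return list with `table` (per-penetration measured and predicted
#'   orientation plus their axial difference), `circ_corr`, `p_value`,
#'   `degenerate` (TRUE when the predictor is constant, in which case the
#'   correlation is NA), `excluded` (penetration ids with a receptive field
#'   at the origin).
#' @export
penetration_concentric_test <- function(summaries, n_perm = 1000, seed = 1) {
  need <- c("penetration_id", "circ_mean_deg", "rf_azimuth_deg", "rf_elevation_deg")
  stopifnot(all(need %in% names(summaries)))
  xyz <- spherical_to_xyz(summaries$rf_azimuth_deg, summaries$rf_elevation_deg)
  pred <- concentric_angle(xyz[, "x"], xyz[, "y"])
  excl <- summaries$penetration_id[is.na(pred)]
  if (length(excl) > 0) {
    message("penetrations at the centre of vision excluded: ",
            paste(excl, collapse = ", "))
  }
  keep <- !is.na(pred)
  tab <- data.frame(penetration_id = summaries$penetration_id[keep],
                    measured_deg = summaries$circ_mean_deg[keep],
                    predicted_deg = pred[keep],
                    diff_deg = circ_diff_axial(summaries$circ_mean_deg[keep],
                                               pred[keep]))
  rho <- NA_real_; p <- NA_real_; degenerate <- FALSE
  res <- tryCatch(circ_corr_axial(tab$measured_deg, tab$predicted_deg),
                  error = function(e) e)
  if (inherits(res, "error")) {
    degenerate <- TRUE
    message("constant predictor or measurement: correlation degenerate")
  } else {
    rho <- res
    if (n_perm > 0) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      null <- vapply(seq_len(n_perm), function(i) {
        circ_corr_axial(tab$measured_deg, tab$predicted_deg[sample.int(nrow(tab))])
      }, numeric(1))
      p <- (1 + sum(abs(null) >= abs(rho))) / (1 + n_perm)
    }
  }
  list(table = tab, circ_corr = rho, p_value = p, degenerate = degenerate,
       excluded = excl)
}

#' Per-penetration columnar statistics and shuffle test
#'
#' Groups a unit table by penetration, computes the circular mean and
#' circular variance of the unit orientation preferences per penetration,
#' runs a Rayleigh test (period 180) on the circular means to check whether
#' all orientations are represented across penetrations, and runs the
#' columnar shuffle test on the ensemble.
#'
#' @param units data.frame with columns `penetration_id` and
#'   `preferred_orientation_deg` (units should already have passed the
#'   evoked-response inclusion filter).
#' @param n_shuffles shuffle count (default 10000).
#' @param seed shuffle seed.
#' @return list with `penetrations` (data.frame: id, circ_mean_deg,
#'   circ_var, n_units), `rayleigh` (on the circular means), `shuffle`
#'   (`shuffle_test`).
#' @export
columnar_summary <- function(units, n_shuffles = 10000, seed = 1) {
  stopifnot(all(c("penetration_id", "preferred_orientation_deg") %in% names(units)))
  if (nrow(units) == 0L) stop("empty unit table")
  sp <- split(units$preferred_orientation_deg, units$penetration_id)
  pens <- data.frame(
    penetration_id = names(sp),
    circ_mean_deg = vapply(sp, function(a) {
      tryCatch(circ_mean_axial(a), error = function(e) NA_real_)
    }, numeric(1)),
    circ_var = vapply(sp, circ_var_axial, numeric(1)),
    n_units = lengths(sp), row.names = NULL)
  ray <- if (sum(!is.na(pens$circ_mean_deg)) >= 5L) {
    rayleigh_test(pens$circ_mean_deg[!is.na(pens$circ_mean_deg)], period_deg = 180)
  } else NULL
  sh <- shuffle_columnar_test(sp, n_shuffles = n_shuffles, seed = seed)
  list(penetrations = pens, rayleigh = ray, shuffle = sh)
}
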