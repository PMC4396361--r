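test_that("event responses are exact windowed means at 1.8 Hz", {
  # constant stack: dF/F identically zero
  const <- imaging_stack(array(100, c(3, 4, 40)))
  r <- event_response(const, onset_s = 10, offset_s = 13)
  expect_equal(r, matrix(0, 3, 4))

  # step stack: baseline 100; frames 22-30 (covering [21, 30]/1.8 s) at 110.
  # With onset = 21/1.8 - 0.3 the response window [onset+0.3, offset+2) =
  # [11.667, 16.367) lies wholly in the high interval and the baseline
  # window ends exactly at its start: dF/F = 0.10 exactly.
  st <- step_stack(base = 100, high = 110, high_frames = 22:30)
  onset <- 21 / 1.8 - 0.3
  r <- event_response(st, onset_s = onset, offset_s = onset + 3)
  expect_equal(r, matrix(0.1, 4, 5), tolerance = 1e-12)

  # multiplicative gain leaves dF/F unchanged
  st2 <- st; st2$frames <- st$frames * 3.7
  expect_equal(event_response(st2, onset, onset + 3), r, tolerance = 1e-12)

  # event at the recording start has no baseline frames: skipped
  expect_message(out <- event_response(st, onset_s = -5, offset_s = -2),
                 "skipped")
  expect_null(out)

  # ROI variant returns the scalar response of the region
  roi <- matrix(FALSE, 4, 5); roi[1:2, 1:2] <- TRUE
  expect_equal(event_response(st, onset, onset + 3, region = roi), 0.1,
               tolerance = 1e-12)
})

test_that("reference correction divides by one plus the reference response", {
  expect_equal(reference_correct(0.05, 0), 0.05)
  expect_equal(reference_correct(0.05, 0.05), 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(reference_correct(0, 0.2), 0)
  expect_error(reference_correct(0.05, -1), "invalid reference")
})

test_that("Gaussian filtering conserves mass and respects the axial wrap", {
  m <- matrix(0, 31, 31); m[16, 16] <- 1
  sm <- spatial_filter(m, sigma_um = 3 * 11.04, pixel_size_um = 11.04)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_identical(spatial_filter(m, 0), m)

  # constant axial map at 170 degrees: no wrap artifact toward 90
  am <- axial_map(matrix(170, 20, 20), matrix(1, 20, 20))
  sm <- spatial_filter(am, sigma_um = 33, pixel_size_um = 11.04)
  expect_angle_equal(sm$angle_deg[sm$mask], rep(170, sum(sm$mask)), tol = 1e-6)

  # mask-aware scalar smoothing ignores masked pixels
  v <- matrix(5, 15, 15); mask <- matrix(TRUE, 15, 15)
  v[1, 1] <- 1e6; mask[1, 1] <- FALSE
  sm <- spatial_filter(scalar_map(v, mask), 33, 11.04)
  expect_equal(sm$values[8, 8], 5, tolerance = 1e-9)
})

test_that("retinotopy argmax recovers quadrant structure with documented tie-break", {
  h <- 10; w <- 10
  mk <- function(rsel, csel, amp) {
    m <- matrix(0.001, h, w); m[rsel, csel] <- amp; m
  }
  maps <- list("1" = mk(1:5, 1:5, 0.05), "2" = mk(1:5, 6:10, 0.05),
               "3" = mk(6:10, 1:5, 0.05), "4" = mk(6:10, 6:10, 0.05))
  rm_ <- retinotopy_argmax_map(maps)
  expect_equal(rm_$patch$values[2, 2], 1)
  expect_equal(rm_$patch$values[2, 8], 2)
  expect_equal(rm_$patch$values[8, 2], 3)
  expect_equal(rm_$patch$values[8, 8], 4)
  expect_equal(rm_$amplitude$values[2, 2], 0.05)

  # uniform response ties to the lowest patch id
  flat <- list("3" = matrix(0.01, 4, 4), "7" = matrix(0.01, 4, 4))
  expect_message(tied <- retinotopy_argmax_map(flat), "tied")
  expect_true(all(tied$patch$values == 3))

  # unresponsive pixels are masked
  neg <- list("1" = matrix(-0.01, 4, 4), "2" = matrix(-0.02, 4, 4))
  expect_true(all(!retinotopy_argmax_map(neg)$patch$mask))
})

test_that("polar orientation map follows the grating convention and masks flat pixels", {
  h <- 6; w <- 6
  dirs <- seq(0, 315, by = 45)
  # responsive only to 90/270 drift: grating orientation 0 (horizontal)
  maps <- lapply(dirs, function(d) {
    matrix(ifelse(d %in% c(90, 270), 0.05, 0.0), h, w)
  })
  names(maps) <- dirs
  om <- orientation_polar_map(maps)
  expect_angle_equal(om$angle_deg[om$mask], rep(0, sum(om$mask)), tol = 1e-9)

  # equal response to all directions: zero resultant, masked
  flat <- lapply(dirs, function(d) matrix(0.05, h, w)); names(flat) <- dirs
  expect_true(all(!orientation_polar_map(flat)$mask))

  # amplitude channel is the mean response over all stimuli
  expect_equal(orientation_polar_map(maps)$amplitude[1, 1], 0.05 / 4,
               tolerance = 1e-12)
})

test_that("per-pixel ANOVA matches anova(lm()) and calibrates under the null", {
  set.seed(31)
  # oracle comparison on single pixels, including the 2x2 minimal case
  for (spec in list(list(k = 2, n = 2), list(k = 4, n = 3), list(k = 4, n = 8))) {
    g <- rep(seq_len(spec$k), each = spec$n)
    y <- rnorm(length(g)) + 0.5 * g
    p_vec <- collimap:::anova_p_rows(matrix(y, 1), g)
    expect_equal(p_vec, oracle_anova_p(y, g), tolerance = 1e-9)
  }

  # strongly tuned, nearly noiseless pixel
  g <- rep(1:4, each = 5)
  y <- c(rep(1, 5), rep(0, 15)) + rnorm(20, sd = 1e-4)
  expect_lt(collimap:::anova_p_rows(matrix(y, 1), g), 1e-6)

  # null calibration over many simulated pixels
  M <- matrix(rnorm(2000 * 20), 2000, 20)
  p <- collimap:::anova_p_rows(M, g)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.08)

  # degenerate rules
  expect_equal(collimap:::anova_p_rows(matrix(rep(c(1, 2), each = 2), 1),
                                       c(1, 1, 2, 2)), 0)
  expect_equal(collimap:::anova_p_rows(matrix(rep(1, 4), 1), c(1, 1, 2, 2)), 1)
})

test_that("significance map groups opposing directions into orientations", {
  set.seed(41)
  h <- 5; w <- 5
  dirs <- rep(seq(0, 315, by = 45), each = 3)
  resp <- array(rnorm(h * w * length(dirs), sd = 0.01), c(h, w, length(dirs)))
  # pixel (1,1) responds to orientation 0 (drift 90/270)
  resp[1, 1, dirs %% 180 == 90] <- resp[1, 1, dirs %% 180 == 90] + 1
  sm <- anova_significance_map(list(resp = resp,
                                    events = data.frame(direction_deg = dirs)))
  expect_lt(sm$p$values[1, 1], 1e-6)
  expect_equal(sm$significant$values[1, 1], 1)
})

test_that("single-condition maps are cocktail-blank subtracted and conserve to zero", {
  set.seed(51)
  dirs <- seq(0, 315, by = 45)
  maps <- lapply(dirs, function(d) matrix(runif(16, 0, 0.05), 4, 4))
  names(maps) <- dirs
  expect_equal(single_condition_map(maps, names(maps)), matrix(0, 4, 4),
               tolerance = 1e-12)
  # the four orientation selections partition the directions: sum is zero
  parts <- lapply(c(0, 45, 90, 135), function(o) {
    single_condition_map(maps, names(maps)[dirs %% 180 == o])
  })
  expect_equal(Reduce(`+`, parts), matrix(0, 4, 4), tolerance = 1e-9)
})

test_that("orientation maps are invariant to trial order", {
  set.seed(61)
  ds <- gen_imaging_dataset(dim = c(32, 32), reps_grating = 2, reps_patch = 1,
                            seed = 5)
  rt <- suppressMessages(event_response_table(ds$stack, ds$schedule))
  grat <- rt$events$kind == "grating"
  tabs <- list(resp = rt$resp[, , grat, drop = FALSE],
               events = rt$events[grat, , drop = FALSE])
  perm <- sample(sum(grat))
  tabs_p <- list(resp = tabs$resp[, , perm, drop = FALSE],
                 events = tabs$events[perm, , drop = FALSE])
  m1 <- orientation_polar_map(condition_mean_maps(tabs, "direction_deg"))
  m2 <- orientation_polar_map(condition_mean_maps(tabs_p, "direction_deg"))
  expect_equal(m1$angle_deg, m2$angle_deg, tolerance = 1e-9)
})
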