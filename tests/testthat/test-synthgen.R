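test_that("imaging generation is a pure function of parameters and seed", {
  a <- gen_imaging_dataset(dim = c(32, 32), reps_grating = 1, reps_patch = 1,
                           seed = 7)
  b <- gen_imaging_dataset(dim = c(32, 32), reps_grating = 1, reps_patch = 1,
                           seed = 7)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$schedule, b$schedule)
  c_ <- gen_imaging_dataset(dim = c(32, 32), reps_grating = 1, reps_patch = 1,
                            seed = 8)
  expect_false(identical(a$stack$frames, c_$stack$frames))
})

test_that("the imaging schedule respects stimulus duration and interstimulus interval", {
  ds <- gen_imaging_dataset(dim = c(32, 32), reps_grating = 2, reps_patch = 1,
                            seed = 1)
  sch <- ds$schedule
  expect_true(all(sch$offset_s - sch$onset_s == 3))
  gaps <- sch$onset_s[-1] - sch$offset_s[-nrow(sch)]
  expect_true(all(gaps >= 9))
  expect_true(all(sch$offset_s <
                    dim(ds$stack$frames)[3] / ds$stack$frame_rate_hz))
  # every patch and direction appears the requested number of times
  expect_true(all(table(sch$patch_id[sch$kind == "patch"]) == 1))
  expect_true(all(table(sch$direction_deg[sch$kind == "grating"]) == 2))
  expect_true(all(ds$stack$frames >= 0))
})

test_that("the null rule produces direction-independent expected responses", {
  # short indicator decay (no tail into the next baseline) and a
  # frame-aligned event period (22 frames at 1.8 Hz) so every event sees
  # identical response windows
  ds <- gen_imaging_dataset(dim = c(32, 32), rule = "uniform_null",
                            reps_grating = 1, reps_patch = 1,
                            frame_noise_sd = 0, drift_amp = 0,
                            tau_decay_s = 0.3, isi_s = 22 / 1.8 - 3, seed = 3)
  rt <- suppressMessages(event_response_table(ds$stack, ds$schedule))
  grat <- rt$events$kind == "grating"
  dm <- condition_mean_maps(list(resp = rt$resp[, , grat, drop = FALSE],
                                 events = rt$events[grat, , drop = FALSE]),
                            "direction_deg", sigma_um = 0)
  arr <- simplify2array(dm)
  spread <- apply(arr, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6)
})

test_that("concentric ground truth matches the geometric rule at each pixel", {
  ds <- gen_imaging_dataset(dim = c(32, 32), reps_grating = 1, reps_patch = 1,
                            seed = 2)
  gt <- ds$ground_truth
  contra <- gt$azimuth > 0
  expect_angle_equal(gt$preferred_orientation[contra],
                     concentric_angle(gt$x[contra], gt$y[contra]), tol = 1e-9)
  expect_true(all(gt$preferred_orientation[gt$azimuth < 0] == 0))
})

test_that("ephys generation is reproducible with the advertised structure", {
  a <- gen_ephys_dataset(n_penetrations = 4, units_per_pen = 3, n_trials = 2,
                         seed = 5)
  b <- gen_ephys_dataset(n_penetrations = 4, units_per_pen = 3, n_trials = 2,
                         seed = 5)
  expect_identical(a$trials, b$trials)
  expect_equal(nrow(a$trials), 4 * 3 * 16 * 2)
  expect_true(all(c("penetration_id", "unit_id", "depth_um", "stimulus_kind",
                    "direction_deg", "trial_index", "response", "baseline")
                  %in% names(a$trials)))
  expect_equal(nrow(a$ground_truth$penetrations), 4)
  expect_true(all(a$trials$response >= 0))
})

test_that("a large within-penetration concentration yields columnar penetrations", {
  ds <- gen_ephys_dataset(n_penetrations = 6, units_per_pen = 6,
                          within_kappa = 1e8, rule = "columnar_random",
                          seed = 9)
  cvs <- tapply(ds$ground_truth$units$preferred_orientation_deg,
                ds$ground_truth$units$penetration_id, circ_var_axial)
  expect_lt(max(cvs), 1e-4)
})

test_that("the concentric ephys rule centres penetrations on the concentric angle", {
  ds <- gen_ephys_dataset(n_penetrations = 10, units_per_pen = 8,
                          within_kappa = 200, rule = "columnar_concentric",
                          seed = 11)
  gt <- ds$ground_truth
  xyz <- spherical_to_xyz(gt$penetrations$rf_azimuth_deg,
                          gt$penetrations$rf_elevation_deg)
  expect_angle_equal(gt$penetrations$centre_orientation_deg,
                     concentric_angle(xyz[, "x"], xyz[, "y"]), tol = 1e-9)
  # unit preferences concentrate around the penetration centre
  d <- abs(circ_diff_axial(
    gt$units$preferred_orientation_deg,
    gt$penetrations$centre_orientation_deg[gt$units$penetration_id]))
  expect_lt(median(d), 10)
})

test_that("the axial von Mises sampler concentrates around its centre", {
  set.seed(13)
  x <- collimap:::r_axial_vonmises(2000, 30, 8)
  expect_true(all(x >= 0 & x < 180))
  expect_lt(abs(circ_diff_axial(circ_mean_axial(x), 30)), 3)
  expect_lt(circ_var_axial(x), circ_var_axial(runif(2000, 0, 180)))
})
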