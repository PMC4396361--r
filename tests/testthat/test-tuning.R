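make_trials <- function(dirs, means, n_trials = 2, baseline = 0, jitter = 0) {
  do.call(rbind, lapply(seq_along(dirs), function(i) {
    data.frame(direction_deg = dirs[i], trial_index = seq_len(n_trials),
               response = means[i] + jitter * (seq_len(n_trials) - 1.5),
               baseline = baseline)
  }))
}

test_that("trial tables become tuning curves with the 2 Hz inclusion filter", {
  dirs <- seq(0, 315, by = 45)
  tt <- make_trials(dirs, rep(5, 8))
  tun <- trials_to_tuning(tt)
  expect_s3_class(tun, "direction_tuning")
  expect_equal(tun$mean_response, rep(5, 8))
  expect_true(tun$included)
  expect_equal(tun$evoked, 5)

  weak <- trials_to_tuning(make_trials(dirs, rep(1, 8)))
  expect_false(weak$included)

  # evoked is baseline-subtracted
  high_base <- trials_to_tuning(make_trials(dirs, rep(5, 8), baseline = 4))
  expect_false(high_base$included)

  expect_warning(trials_to_tuning(make_trials(dirs, rep(5, 8), n_trials = 1)),
                 "single trial")
  sem0 <- suppressWarnings(trials_to_tuning(make_trials(dirs, rep(5, 8), n_trials = 1)))
  expect_equal(sem0$sem, rep(0, 8))
})

test_that("direction responses collapse onto orientations by pair average or max", {
  tun <- list(directions = c(0, 180), mean_response = c(8, 2))
  expect_equal(collapse_directions(tun, "average")$response, 5)
  expect_equal(collapse_directions(tun, "max")$response, 8)
  tun8 <- list(directions = seq(0, 315, by = 45),
               mean_response = c(8, 5, 2, 5, 8, 5, 2, 5))
  ca <- collapse_directions(tun8, "average")
  expect_equal(ca$orientations, c(0, 45, 90, 135))
  expect_equal(ca$response, c(8, 5, 2, 5))
  expect_error(collapse_directions(list(directions = c(0, 90, 180),
                                        mean_response = 1:3), "average"),
               "unpaired")
})

test_that("orientation index matches its definition and is scale invariant", {
  expect_equal(orientation_index(c(0, 90), c(10, 0)), 1)
  expect_equal(orientation_index(c(0, 45, 90, 135), rep(3, 4)), 0)
  expect_equal(orientation_index(c(0, 45, 90, 135), c(8, 5, 2, 5)), 0.6)
  set.seed(2)
  for (i in 1:10) {
    r <- runif(4, 0.1, 10)
    oi <- orientation_index(c(0, 45, 90, 135), r)
    expect_equal(orientation_index(c(0, 45, 90, 135), 7.3 * r), oi,
                 tolerance = 1e-12)
  }
  expect_error(orientation_index(c(0, 90), c(0, 0)), "unresponsive")
})

test_that("DSI is the normalised vector sum with the 0.5 selectivity flag", {
  one <- list(directions = seq(0, 315, by = 45),
              mean_response = c(10, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(direction_selectivity_index(one)$dsi, 1)
  expect_true(direction_selectivity_index(one)$is_direction_selective)
  flat <- list(directions = seq(0, 315, by = 45), mean_response = rep(4, 8))
  expect_equal(direction_selectivity_index(flat)$dsi, 0, tolerance = 1e-12)
  opp <- list(directions = seq(0, 315, by = 45),
              mean_response = c(10, 0, 0, 0, 5, 0, 0, 0))
  expect_equal(direction_selectivity_index(opp)$dsi, 1 / 3, tolerance = 1e-12)
  expect_false(direction_selectivity_index(opp)$is_direction_selective)
})

test_that("vector-sum preferred orientation matches the complex-sum oracle", {
  expect_equal(preferred_orientation_vector(c(0, 45, 90, 135), c(0, 7, 0, 0)), 45)
  expect_equal(preferred_orientation_vector(c(0, 45, 90, 135), c(8, 5, 2, 5)), 0)
  set.seed(6)
  for (i in 1:10) {
    r <- runif(4, 0, 5)
    got <- preferred_orientation_vector(c(0, 45, 90, 135), r)
    expect_angle_equal(got, oracle_circ_mean(c(0, 45, 90, 135), r), tol = 1e-9)
  }
})

test_that("preferred orientation is equivariant under rotation of labels", {
  set.seed(8)
  ors <- c(0, 45, 90, 135)
  r <- c(9, 4, 1, 4)
  base <- preferred_orientation_vector(ors, r)
  for (delta in c(10, 60, 117)) {
    got <- preferred_orientation_vector((ors + delta) %% 180, r)
    expect_angle_equal(got, (base + delta) %% 180, tol = 1e-8)
  }
})

test_that("von Mises fits recover the generating curve", {
  ors <- seq(0, 157.5, by = 22.5)
  truth <- 1.5 + 4 * exp(cos(2 * (ors - 72.4) * pi / 180) - 1)
  fit <- fit_von_mises(ors, truth)
  expect_lt(abs(circ_diff_axial(fit$phi_preferred_deg, 72.4)), 0.5)
  expect_equal(fit$amplitude, 4, tolerance = 1e-3)
  expect_equal(fit$baseline, 1.5, tolerance = 1e-3)
  expect_true(fit$reliable)

  flat <- fit_von_mises(ors, rep(2, 8))
  expect_lt(abs(flat$amplitude), 1e-6)

  set.seed(12)
  errs <- replicate(50, {
    phi0 <- runif(1, 0, 180)
    y <- 1 + 4 * exp(cos(2 * (ors - phi0) * pi / 180) - 1) + rnorm(8, sd = 0.4)
    abs(circ_diff_axial(fit_von_mises(ors, y)$phi_preferred_deg, phi0))
  })
  expect_lt(median(errs), 5)
})

test_that("horizontal-track orientation gradient handles the axial wrap", {
  expect_equal(orientation_gradient(c(0, 100, 200), rep(40, 3)), 0)
  expect_equal(orientation_gradient(seq(0, 400, 100), seq(10, 50, 10)), 10)
  # 170 -> 10 is a 20 degree step across the wrap
  expect_equal(orientation_gradient(c(0, 100), c(170, 10)), 20)
  expect_error(orientation_gradient(c(0, 0), c(10, 20)), "invalid track")
})

test_that("drift direction converts to grating orientation", {
  expect_equal(direction_to_orientation(90), 0)   # upward drift = horizontal bars
  expect_equal(direction_to_orientation(270), 0)
  expect_equal(direction_to_orientation(0), 90)
})
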