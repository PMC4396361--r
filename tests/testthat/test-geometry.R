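test_that("barycentric interpolation reproduces affine fields exactly inside the hull", {
  set.seed(71)
  x <- c(0, 10, 0, 10, 5, 2); y <- c(0, 0, 10, 10, 5, 8)
  f <- 2 + 0.3 * x - 1.7 * y          # affine in (x, y)
  qx <- runif(200, 0, 10); qy <- runif(200, 0, 10)
  got <- interp_barycentric(x, y, f, qx, qy)
  inside <- attr(got, "inside")
  truth <- 2 + 0.3 * qx - 1.7 * qy
  expect_equal(got[inside, 1], truth[inside], tolerance = 1e-9)
  # a query far outside the hull is NA
  far <- interp_barycentric(x, y, f, 100, 100)
  expect_true(is.na(far[1, 1]))
  expect_false(attr(far, "inside"))
  expect_error(delaunay_triangulate(c(0, 1, 2), c(0, 1, 2)), "collinear")
})

test_that("monitor points map to head coordinates per the stated frame", {
  geom <- monitor_geometry()
  expect_equal(monitor_to_head_xyz(0, 0, geom)[1, ],
               c(x = 0, y = 0, z = 29.5), tolerance = 1e-12)
  p <- monitor_to_head_xyz(29.5, 0, geom)[1, ]
  expect_equal(p[["x"]], p[["z"]], tolerance = 1e-12)
  # pitch 90: a point straight ahead of the body appears straight above
  g90 <- monitor_geometry(head_pitch_deg = 90)
  p <- monitor_to_head_xyz(0, 0, g90)[1, ]
  expect_equal(unname(p), c(0, 29.5, 0), tolerance = 1e-9)
})

test_that("spherical transform matches its closed forms and rejects rear points", {
  expect_equal(xyz_to_spherical(0, 0, 29.5)[1, ],
               c(azimuth_deg = 0, elevation_deg = 0))
  expect_equal(unname(xyz_to_spherical(5, 0, 5)[1, "azimuth_deg"]), 45)
  expect_equal(unname(xyz_to_spherical(0, 5, 5)[1, "elevation_deg"]), 45)
  expect_error(xyz_to_spherical(1, 1, 0), "behind")
  # round trip through the unit direction vector
  set.seed(81)
  az <- runif(50, -80, 80); el <- runif(50, -80, 80)
  v <- spherical_to_xyz(az, el)
  back <- xyz_to_spherical(v[, "x"], v[, "y"], v[, "z"])
  expect_equal(back[, "azimuth_deg"], az, tolerance = 1e-9)
  expect_equal(back[, "elevation_deg"], el, tolerance = 1e-9)
})

test_that("the concentric angle has the stated values and symmetries", {
  expect_equal(concentric_angle(1, 0), 90)    # temporal horizontal: vertical
  expect_equal(concentric_angle(0, 1), 0)     # above the nose: horizontal
  expect_equal(concentric_angle(1, 1), 45)
  expect_true(is.na(concentric_angle(0, 0)))
  set.seed(91)
  x <- rnorm(10000); y <- rnorm(10000)
  a <- concentric_angle(x, y)
  expect_angle_equal(concentric_angle(3.7 * x, 3.7 * y), a, tol = 1e-9)
  expect_angle_equal(concentric_angle(-x, -y), a, tol = 1e-9)
})

test_that("angles of the four monitor corners agree with hand-computed geometry", {
  geom <- monitor_geometry(width_cm = 40, height_cm = 30, distance_cm = 20)
  corners <- cbind(x = c(-20, 20, -20, 20), y = c(-15, -15, 15, 15))
  got <- xyz_to_spherical(corners[, "x"], corners[, "y"],
                          rep(20, 4))
  expect_equal(got[, "azimuth_deg"], atan(c(-1, 1, -1, 1)) * 180 / pi)
  expect_equal(got[, "elevation_deg"],
               atan(c(-15, -15, 15, 15) / sqrt(20^2 + 20^2)) * 180 / pi)
})

test_that("2D Gaussian patch fits recover centres and apply the inclusion rule", {
  h <- 30; w <- 30
  blob <- function(amp, cr, cc, s = 3) {
    amp * exp(-((row(matrix(0, h, w)) - 1 - cr)^2 +
                  (col(matrix(0, h, w)) - 1 - cc)^2) / (2 * s^2))
  }
  f <- fit_patch_gaussian(blob(0.01, 14.3, 17.8), patch_id = 1)
  expect_true(f$included)
  expect_lt(abs(f$centre_px[1] - 14.3), 0.1)
  expect_lt(abs(f$centre_px[2] - 17.8), 0.1)
  # pedestal flooring biases the fitted peak slightly upward; 10% is fine
  expect_equal(f$amplitude_dff, 0.01, tolerance = 0.1)

  # 0.3% peak response is excluded by the 0.4% rule
  weak <- fit_patch_gaussian(blob(0.003, 15, 15))
  expect_false(weak$included)

  # noisy recovery stays within a pixel
  set.seed(101)
  errs <- replicate(30, {
    cr <- runif(1, 10, 20); cc <- runif(1, 10, 20)
    m <- blob(0.01, cr, cc) + matrix(rnorm(h * w, sd = 5e-4), h, w)
    ft <- fit_patch_gaussian(m)
    sqrt((ft$centre_px[1] - cr)^2 + (ft$centre_px[2] - cc)^2)
  })
  expect_lt(median(errs), 1)
})

# patch fits placed exactly at the ground-truth affine positions
affine_fits <- function(geom, h, w) {
  lapply(geom$patch_centres_cm$patch_id, function(pid) {
    pc <- geom$patch_centres_cm[geom$patch_centres_cm$patch_id == pid, ]
    col <- (pc$x_cm / geom$width_cm + 0.5) * (w - 1)
    row <- (0.5 - pc$y_cm / geom$height_cm) * (h - 1)
    structure(list(patch_id = pid, centre_px = c(row = row, col = col),
                   sigmas_px = c(2, 2), amplitude_dff = 0.02,
                   included = TRUE, converged = TRUE, rss = 0),
              class = "patch_fit")
  })
}

test_that("interpolated retinotopy reproduces an affine ground truth within 2 degrees", {
  h <- 40; w <- 40
  geom <- monitor_geometry(center_offset_cm = c(40, 10))
  retino <- interpolate_retinotopy(affine_fits(geom, h, w), geom, c(h, w))
  # ground truth from the same affine map
  rows <- as.vector(row(matrix(0, h, w))) - 1
  cols <- as.vector(col(matrix(0, h, w))) - 1
  xyz <- monitor_to_head_xyz((cols / (w - 1) - 0.5) * geom$width_cm,
                             (0.5 - rows / (h - 1)) * geom$height_cm, geom)
  sph <- xyz_to_spherical(xyz[, 1], xyz[, 2], xyz[, 3])
  ok <- retino$hull_mask
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(retino$azimuth$values[ok] - matrix(sph[, 1], h, w)[ok])), 2)
  expect_lt(max(abs(retino$elevation$values[ok] - matrix(sph[, 2], h, w)[ok])), 2)
  # outside the hull everything is masked
  expect_true(all(is.na(retino$azimuth$values[!ok])))
  expect_error(interpolate_retinotopy(affine_fits(geom, h, w)[1:2], geom, c(h, w)),
               "insufficient retinotopy")
})

test_that("the concentric map equals the pointwise angle at sigma zero", {
  h <- 30; w <- 30
  geom <- monitor_geometry(center_offset_cm = c(40, 10))
  retino <- interpolate_retinotopy(affine_fits(geom, h, w), geom, c(h, w))
  cm <- build_concentric_map(retino, sigma_um = 0)
  ok <- cm$mask & retino$azimuth$values > 0
  truth <- concentric_angle(retino$x, retino$y)
  expect_angle_equal(cm$angle_deg[ok], truth[ok], tol = 1e-9)
  # ipsilateral pixels are horizontal
  ipsi <- cm$mask & retino$azimuth$values < 0
  if (any(ipsi)) expect_true(all(cm$angle_deg[ipsi] == 0))
})

test_that("an all-ipsilateral field predicts the horizontal orientation everywhere", {
  h <- 30; w <- 30
  geom <- monitor_geometry(center_offset_cm = c(-60, 10))
  retino <- interpolate_retinotopy(affine_fits(geom, h, w), geom, c(h, w))
  cm <- build_concentric_map(retino, sigma_um = 0)
  expect_true(all(abs(cm$angle_deg[cm$mask]) < 1e-9))
})

test_that("head pitch and roll are recoverable from the concentric-map fit", {
  h <- 36; w <- 36
  geom_true <- monitor_geometry(center_offset_cm = c(40, 10),
                                head_pitch_deg = 10, head_roll_deg = 5)
  fits <- affine_fits(geom_true, h, w)
  measured <- build_concentric_map(
    interpolate_retinotopy(fits, geom_true, c(h, w)), sigma_um = 132)
  geom0 <- geom_true
  geom0$head_pitch_deg <- 0; geom0$head_roll_deg <- 0
  fit <- fit_head_angles(fits, geom0, measured,
                         pitch_grid = seq(-10, 20, by = 5),
                         roll_grid = seq(-10, 15, by = 5))
  expect_true(fit$identifiable)
  expect_lte(abs(fit$pitch_deg - 10), 5)
  expect_lte(abs(fit$roll_deg - 5), 5)
  # the profile peaks at the truth relative to a 10-degree pitch error
  i_true <- which(rownames(fit$profile) == "10")
  i_off <- which(rownames(fit$profile) == "0")
  j_true <- which(colnames(fit$profile) == "5")
  expect_gte(fit$profile[i_true, j_true], fit$profile[i_off, j_true])

  # a random orientation map is unidentifiable
  set.seed(111)
  rnd <- axial_map(matrix(runif(h * w, 0, 180), h, w), matrix(1, h, w))
  fit0 <- fit_head_angles(fits, geom0, rnd,
                          pitch_grid = c(-10, 0, 10), roll_grid = c(-10, 0, 10))
  expect_false(fit0$identifiable)
})
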