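# Single-marker and bi-planar calibration solvers.

test_that("single-marker solver inverts the forward model", {
  g <- g1150
  # on-axis round trip: marker at the hip depth
  e <- project_sphere(sphere3d(c(0, 0, 908), 32), g)
  r <- single_marker_plane_cf(e$major_axis_mm, 0, 32, g)
  expect_true(r$converged)
  expect_equal(r$cf_percent, plane_cf(908, g), tolerance = 1e-4)
  expect_equal(r$marker_plane_cf_percent, r$cf_percent)

  # off-axis round trips against the independent closed form
  set.seed(404)
  for (rep in 1:20) {
    s <- random_sphere()
    e <- project_sphere(s, g)
    rho <- sqrt(sum(e$center_xy^2))
    sol <- single_marker_plane_cf(e$major_axis_mm, rho, s$diameter_mm, g)
    cf_true <- plane_cf(s$center[3], g)
    expect_true(sol$converged)
    expect_lt(abs(sol$cf_percent - cf_true), 0.01)
    oracle <- closed_form_single_marker(e$major_axis_mm, rho,
                                        s$diameter_mm, 1150)
    expect_equal(sol$cf_percent, oracle$cf, tolerance = 1e-6)
    expect_equal(sol$est_depth_mm, oracle$depth, tolerance = 1e-4)
  }
})

test_that("on-axis closed form matches the documented arithmetic", {
  # dist = sqrt((sdd*r/rho)^2 + r^2), rho = major/2
  r <- single_marker_plane_cf(40.54, 0, 32, g1150)
  dist <- sqrt((1150 * 16 / 20.27)^2 + 16^2)
  expect_equal(r$cf_percent, 100 * 1150 / dist, tolerance = 1e-4)
  expect_gt(r$cf_percent, 126.6)
  expect_lt(r$cf_percent, 126.7)
})

test_that("infeasible measurements raise errors", {
  expect_error(single_marker_plane_cf(30, 10, 32, g1150), "infeasible")
  expect_error(single_marker_plane_cf(32, 0, 32, g1150), "infeasible")
  ap <- ap_measurements(h = 50, i = 40, k = 28, m = 215,
                        n = 30, o = 95, p = 90)
  expect_error(icm_reference_cf(ap, 32, g1150), "infeasible")
})

test_that("ICM reference recovers the hip-plane factor and is unbiased", {
  g <- g1150
  ap <- simulate_ap(phantom_config(), g)
  sol <- icm_reference_cf(ap, 32, g)
  expect_lt(abs(sol$cf_percent - plane_cf(908, g)), 0.01)

  # Monte-Carlo bias under measurement noise
  set.seed(505)
  nm <- noise_model(sd_distance_mm = 0.2, sd_axis_mm = 0.2)
  cfs <- vapply(1:1000, function(k) {
    icm_reference_cf(apply_noise(ap, nm), 32, g)$cf_percent
  }, numeric(1))
  expect_lt(abs(mean(cfs) - plane_cf(908, g)), 0.05)
})

test_that("rotation estimation inverts the simulated geometry", {
  expect_equal(estimate_rotation(0, 170, 1.3), 0)
  g <- g1150
  for (rot in c(20, 30)) {
    cfg <- phantom_config(rotation_deg = rot)
    lat <- simulate_lateral(cfg, g)
    # demagnify c with the contralateral hip's own plane magnification
    depth_lhip <- cfg$lat_hip_depth_mm +
      cfg$inter_hip_mm * cos(rot * pi / 180)
    est <- estimate_rotation(lat$c, cfg$inter_hip_mm,
                             plane_cf(depth_lhip, g) / 100)
    tol <- if (rot == 20) 0.5 else 1
    expect_lt(abs(est - rot), tol)
  }
  expect_error(estimate_rotation(300, 170, 1.3), "inconsistent")
})

test_that("anterior-offset estimation inverts the simulated geometry", {
  g <- g1150
  # pure demagnification at nominal pose
  expect_equal(estimate_anterior_offset(100, 1.25, 0, 85), 80)

  cfg <- phantom_config(ecm_anterior_mm = 80, ecm_lateral_mm = 0,
                        rotation_deg = 0)
  lat <- simulate_lateral(cfg, g)
  mag <- attr(lat, "truth")$ecm_plane_cf_percent / 100
  delta_true <- cfg$symphysis_anterior_mm + cfg$ecm_anterior_mm
  expect_lt(abs(lat$d / mag - delta_true), 0.5)

  cfg2 <- phantom_config(ecm_anterior_mm = 50, ecm_lateral_mm = 40,
                         rotation_deg = 20)
  lat2 <- simulate_lateral(cfg2, g)
  mag2 <- attr(lat2, "truth")$ecm_plane_cf_percent / 100
  sep <- cfg2$inter_hip_mm / 2 + cfg2$ecm_lateral_mm
  est <- estimate_anterior_offset(lat2$d, mag2, 20, sep)
  expect_lt(abs(est - (cfg2$symphysis_anterior_mm + cfg2$ecm_anterior_mm)), 2)
})

test_that("bi-planar solver is exact at nominal pose and robust under rotation", {
  g <- g1150
  truth <- plane_cf(908, g)
  for (lat_off in c(0, 60)) {
    cfg <- phantom_config(ecm_anterior_mm = 50, ecm_lateral_mm = lat_off,
                          rotation_deg = 0)
    ap <- simulate_ap(cfg, g)
    lat <- simulate_lateral(cfg, g)
    sol <- biplanar_hip_cf(ap, lat, 25, g, g)
    expect_true(sol$converged)
    expect_lt(abs(sol$cf_percent - truth), 0.05)
  }
  # worst-case single pose of the design, rotated
  cfg <- phantom_config(ecm_anterior_mm = 80, ecm_lateral_mm = 60,
                        rotation_deg = 20)
  sol <- biplanar_hip_cf(simulate_ap(cfg, g), simulate_lateral(cfg, g),
                         25, g, g)
  expect_lt(abs(sol$cf_percent - truth), 1.5)
})

test_that("marker in the hip plane makes target and marker factors coincide", {
  g <- g1150
  cfg <- phantom_config(symphysis_anterior_mm = 0, ecm_anterior_mm = 0,
                        ecm_lateral_mm = 0, rotation_deg = 0)
  sol <- biplanar_hip_cf(simulate_ap(cfg, g), simulate_lateral(cfg, g),
                         25, g, g)
  expect_equal(sol$cf_percent, sol$marker_plane_cf_percent, tolerance = 1e-6)
})

test_that("increasing d lowers the hip-plane estimate monotonically", {
  g <- g1150
  cfg <- phantom_config()
  ap <- simulate_ap(cfg, g)
  lat <- simulate_lateral(cfg, g)
  cfs <- vapply(c(0, 20, 40), function(extra) {
    lat2 <- lateral_measurements(lat$a, lat$b, lat$c, lat$d + extra)
    biplanar_hip_cf(ap, lat2, 25, g, g)$cf_percent
  }, numeric(1))
  expect_true(all(diff(cfs) < 0))
})

test_that("fixed-point iteration converges quickly across the design grid", {
  tab <- default_table()
  expect_true(all(tab$icm_converged))
  expect_true(all(tab$ecm_converged))
  g <- g1150
  recs <- default_records()
  lats <- Filter(function(r) r$view == "lateral", recs)
  aps <- Filter(function(r) r$view == "ap", recs)
  ap_by <- stats::setNames(lapply(aps, `[[`, "measurements"),
                           vapply(aps, `[[`, "", "series_id"))
  iters <- vapply(lats, function(r) {
    biplanar_hip_cf(ap_by[[r$series_id]], r$measurements, 25, g, g,
                    solver_settings(tol_pp = 1e-4, max_iter = 100))$iterations
  }, integer(1))
  expect_true(all(iters < 25))
})

test_that("bi-planar noise errors are centred near zero at nominal pose", {
  g <- g1150
  cfg <- phantom_config()
  ap <- simulate_ap(cfg, g)
  lat <- simulate_lateral(cfg, g)
  truth <- plane_cf(908, g)
  set.seed(606)
  nm <- noise_model(sd_distance_mm = 0.2, sd_axis_mm = 0.2)
  errs <- vapply(1:1000, function(k) {
    biplanar_hip_cf(apply_noise(ap, nm), apply_noise(lat, nm),
                    25, g, g)$cf_percent - truth
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1)
})
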