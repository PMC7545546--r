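test_that("neutral displacements give the identity pose", {
  p <- estimate_pelvic_pose(h = 0, v = 30, ssd = 100, neutral_v = 30)
  expect_equal(p$theta_deg, 0, tolerance = 1e-12)
  expect_equal(p$phi_deg, 0, tolerance = 1e-12)
})

test_that("pose estimation inverts the forward projection", {
  grid <- expand.grid(theta = c(-15, -10, -2, 0, 4, 10, 15),
                      phi = c(-10, -5, 0, 3, 10))
  for (k in seq_len(nrow(grid))) {
    f <- project_scene(cup_scene(20, 45, theta_deg = grid$theta[k],
                                 phi_deg = grid$phi[k], side = "left"))
    d <- displacements(f$landmarks, "left")
    p <- estimate_pelvic_pose(d$h_raw, d$v, ssd = 100, neutral_v = 30)
    expect_equal(p$theta_deg, grid$theta[k], tolerance = 1e-6)
    expect_equal(p$phi_deg, grid$phi[k], tolerance = 1e-6)
  }
})

test_that("inconsistent displacement geometry is rejected", {
  expect_error(estimate_pelvic_pose(h = 80, v = 80, ssd = 100, neutral_v = 30),
               "exceeds ssd")
  expect_error(planar_measurement(u = 20, w = 45, h = 90, v = 60, ssd = 100,
                                  side = "left"), "exceeds ssd")
})

test_that("tilt-solution branches select the two analytic solutions", {
  ## at a 60 deg tilt the v equation has two admissible solutions
  ## (60 and ~85 deg); the branches pick them apart
  q <- sqrt(100^2 - 30^2)
  v60 <- 30 * cos(pi / 3) + q * sin(pi / 3)
  lo <- estimate_pelvic_pose(0, v60, 100, 30, branch = "lower")
  up <- estimate_pelvic_pose(0, v60, 100, 30, branch = "upper")
  expect_equal(lo$theta_deg, 60, tolerance = 1e-6)
  expect_gt(up$theta_deg, lo$theta_deg)
  expect_lt(up$theta_deg, 90)
  mn <- estimate_pelvic_pose(0, v60, 100, 30, branch = "min_tilt")
  expect_equal(mn$theta_deg, 60, tolerance = 1e-6)
  ## for small clinical tilts only the minimal-|theta| solution is
  ## admissible; the other lies outside (-90, 90) and is rejected
  f <- project_scene(cup_scene(20, 45, theta_deg = 10, side = "left"))
  d <- displacements(f$landmarks, "left")
  expect_error(estimate_pelvic_pose(d$h_raw, d$v, 100, 30, branch = "upper"),
               "90")
})

test_that("identity pose leaves the planar anteversion unchanged", {
  pm <- planar_measurement(u = 25, w = 40, h = 0, v = 30, ssd = 100,
                           side = "left")
  expect_equal(standardized_anteversion(pm, pelvic_pose(0, 0)), 25,
               tolerance = 1e-9)
})

test_that("standardized anteversion recovers the true angle on tilted scenes", {
  f <- project_scene(cup_scene(15, 45, theta_deg = 10, phi_deg = 0,
                               side = "left"))
  rec <- measure_film(film_annotation(f))
  expect_gt(abs(rec$radiographic_anteversion - 15), 1)
  expect_equal(rec$standardized_anteversion, 15, tolerance = 0.1)
})

test_that("standardized output is constant over a tilt sweep", {
  std <- pla <- numeric(0)
  for (th in seq(-15, 15, by = 5)) {
    f <- project_scene(cup_scene(22, 50, theta_deg = th, side = "right"))
    r <- measure_film(film_annotation(f))
    std <- c(std, r$standardized_anteversion)
    pla <- c(pla, r$radiographic_anteversion)
  }
  expect_lt(max(std) - min(std), 0.1)
  expect_gt(max(pla) - min(pla), 5)
})

test_that("noiseless measurement recovers truth across the study conditions", {
  g <- scene_grid()
  for (k in seq_len(nrow(g))) {
    f <- project_scene(cup_scene(g$anteversion[k], g$inclination[k],
                                 theta_deg = g$theta[k], phi_deg = g$phi[k],
                                 side = g$side[k]))
    r <- measure_film(film_annotation(f))
    expect_equal(r$standardized_anteversion, g$anteversion[k],
                 tolerance = 0.1)
  }
})

test_that("neutral-pose measurement leaves standardized equal to planar", {
  f <- neutral_film(27, 44)
  r <- measure_film(film_annotation(f))
  expect_equal(r$standardized_anteversion, r$radiographic_anteversion,
               tolerance = 1e-6)
})

test_that("standardization is continuous under small pose perturbations", {
  base <- cup_scene(25, 45, theta_deg = 8, phi_deg = 4, side = "left")
  r0 <- measure_film(film_annotation(project_scene(base)))
  for (dth in c(-0.1, 0.1)) {
    f <- project_scene(cup_scene(25, 45, theta_deg = 8 + dth, phi_deg = 4,
                                 side = "left"))
    r <- measure_film(film_annotation(f))
    expect_lt(abs(r$standardized_anteversion - r0$standardized_anteversion), 1)
    expect_lt(abs(r$radiographic_anteversion - r0$radiographic_anteversion), 1)
  }
})
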