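test_that("zero anteversion projects the rim to a segment", {
  f <- project_scene(cup_scene(0, 45, side = "left"))
  expect_equal(f$true_ellipse$b, 0)
  expect_equal(radiographic_anteversion(f$true_ellipse), 0)
})

test_that("the analytic ellipse matches the planar formula at identity pose", {
  for (av in seq(5, 85, by = 10)) {
    for (inc in seq(30, 60, by = 10)) {
      f <- project_scene(cup_scene(av, inc, side = "right"))
      expect_equal(radiographic_anteversion(f$true_ellipse), av,
                   tolerance = 1e-6)
      expect_equal(inclination(f$true_ellipse, trans_teardrop_line(f$landmarks)),
                   inc, tolerance = 1e-6)
    }
  }
})

test_that("identity-pose projection reproduces the landmark model offsets", {
  f <- project_scene(cup_scene(30, 45, side = "left"))
  d <- displacements(f$landmarks, "left")
  expect_equal(d$h_raw, 0, tolerance = 1e-9)
  expect_equal(d$v, 30, tolerance = 1e-9)     # default neutral_v
})

test_that("noiseless rim points lie exactly on the analytic ellipse", {
  g <- scene_grid(theta = c(-12, 0, 9), phi = c(-7, 0, 7),
                  anteversion = c(10, 35, 55), inclination = c(35, 55))
  for (k in seq_len(nrow(g))) {
    f <- project_scene(cup_scene(g$anteversion[k], g$inclination[k],
                                 theta_deg = g$theta[k], phi_deg = g$phi[k],
                                 side = g$side[k]))
    resid <- cupav:::ellipse_implicit(f$true_ellipse, f$rim_points)
    expect_true(all(abs(resid) < 1e-9))
  }
})

test_that("analytic ellipse agrees with a fit to 360 projected rim points", {
  f <- project_scene(cup_scene(24, 47, theta_deg = 7, phi_deg = -4,
                               side = "left"), n_rim_points = 360)
  ft <- fit_ellipse(f$rim_points)
  expect_equal(ft$cx, f$true_ellipse$cx, tolerance = 1e-6)
  expect_equal(ft$cy, f$true_ellipse$cy, tolerance = 1e-6)
  expect_equal(ft$a, f$true_ellipse$a, tolerance = 1e-6)
  expect_equal(ft$b, f$true_ellipse$b, tolerance = 1e-6)
  expect_equal(ft$orientation_deg, f$true_ellipse$orientation_deg,
               tolerance = 1e-6)
})

test_that("brute-force projection of the rim point cloud confirms b/a", {
  ## independent oracle: project a dense 3D rim point cloud and take the
  ## extreme widths along/perpendicular to the projected axis direction
  av <- 37; inc <- 52
  f <- project_scene(cup_scene(av, inc, side = "left"), n_rim_points = 2000)
  ctr <- c(f$true_ellipse$cx, f$true_ellipse$cy)
  d <- sweep(f$rim_points, 2, ctr)
  expect_equal(max(sqrt(rowSums(d^2))), f$true_ellipse$a, tolerance = 1e-4)
  expect_equal(min(sqrt(rowSums(d^2))), f$true_ellipse$b, tolerance = 1e-4)
  expect_equal(asin(min(sqrt(rowSums(d^2))) / max(sqrt(rowSums(d^2)))) *
                 180 / pi, av, tolerance = 1e-2)
})

test_that("seeded cohorts are bit-for-bit reproducible", {
  c1 <- generate_cohort(10, seed = 42, noise_sigma = 1)
  c2 <- generate_cohort(10, seed = 42, noise_sigma = 1)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$films[[7]]$rim_points, c2$films[[7]]$rim_points)
  expect_identical(c1$films[[3]]$landmarks, c2$films[[3]]$landmarks)
  c3 <- generate_cohort(10, seed = 43, noise_sigma = 1)
  expect_false(identical(c1$films[[7]]$rim_points, c3$films[[7]]$rim_points))
})

test_that("degenerate parameter ranges pin every scene", {
  co <- generate_cohort(5, ranges = list(anteversion = c(20, 20),
                                         inclination = c(45, 45),
                                         theta = c(0, 0), phi = c(0, 0)),
                        seed = 1)
  expect_true(all(co$truth$anteversion == 20))
  expect_true(all(co$truth$theta == 0))
  expect_error(generate_cohort(0), ">= 1")
  expect_error(generate_cohort(3, ranges = list(anteversion = c(5, 1),
                                                inclination = c(30, 60),
                                                theta = c(0, 0),
                                                phi = c(0, 0))),
               "anteversion")
})

test_that("noise requires a seed and perturbs only annotations", {
  expect_error(cup_scene(20, 45, noise_sigma = 1), "seed")
  f0 <- project_scene(cup_scene(20, 45, side = "left"))
  fn <- project_scene(cup_scene(20, 45, side = "left", noise_sigma = 1,
                                seed = 9))
  expect_identical(unclass(fn$true_ellipse), unclass(f0$true_ellipse))
  expect_false(identical(fn$rim_points, f0$rim_points))
})
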