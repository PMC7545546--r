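test_that("exact rim points are recovered to 1e-6 relative error", {
  e <- ellipse2d(200, 150, a = 100, b = 50, orientation_deg = 30)
  f <- fit_ellipse(render_ellipse_polygon(e, 64))
  expect_equal(f$cx, e$cx, tolerance = 1e-6)
  expect_equal(f$cy, e$cy, tolerance = 1e-6)
  expect_equal(f$a, e$a, tolerance = 1e-6)
  expect_equal(f$b, e$b, tolerance = 1e-6)
  expect_equal(f$orientation_deg, e$orientation_deg, tolerance = 1e-6)
  expect_lt(attr(f, "fit_rms"), 1e-8)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_ellipse(matrix(runif(8), 4, 2)), "at least 5")
  line_pts <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(fit_ellipse(line_pts), "collinear")
})

test_that("noisy rim points are recovered within 2 percent", {
  e <- ellipse2d(200, 150, a = 100, b = 50, orientation_deg = 30)
  p <- render_ellipse_polygon(e, 64)
  set.seed(101)
  f <- fit_ellipse(p + matrix(rnorm(length(p), sd = 1), ncol = 2))
  expect_lt(abs(f$a - e$a) / e$a, 0.02)
  expect_lt(abs(f$b - e$b) / e$b, 0.02)
  expect_lt(sqrt((f$cx - e$cx)^2 + (f$cy - e$cy)^2) / e$a, 0.02)
})

test_that("fit-render round trip holds for random ellipses", {
  for (e in random_ellipses(30, seed = 21)) {
    if (e$b / e$a < 0.08) next    # near-flat ellipses are ill-posed by design
    f <- fit_ellipse(render_ellipse_polygon(e, 64))
    expect_equal(f$a, e$a, tolerance = 1e-6)
    expect_equal(f$b, e$b, tolerance = 1e-6)
    expect_equal(f$cx, e$cx, tolerance = 1e-5)
    expect_equal(f$cy, e$cy, tolerance = 1e-5)
  }
})

test_that("fitting is equivariant under rotation and translation", {
  e <- ellipse2d(10, -5, a = 40, b = 22, orientation_deg = 15)
  p <- render_ellipse_polygon(e, 48)
  ## translate
  ft <- fit_ellipse(sweep(p, 2, c(-33.5, 71.25), "+"))
  expect_equal(ft$cx, e$cx - 33.5, tolerance = 1e-9)
  expect_equal(ft$cy, e$cy + 71.25, tolerance = 1e-9)
  expect_equal(ft$a, e$a, tolerance = 1e-9)
  expect_equal(ft$b, e$b, tolerance = 1e-9)
  expect_equal(ft$orientation_deg, e$orientation_deg, tolerance = 1e-9)
  ## rotate about the origin by 40 degrees
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fr <- fit_ellipse(p %*% t(R))
  expect_equal(fr$a, e$a, tolerance = 1e-9)
  expect_equal(fr$b, e$b, tolerance = 1e-9)
  expect_equal(fr$orientation_deg, (e$orientation_deg + 40) %% 180,
               tolerance = 1e-6)
})

test_that("estimator bias vanishes as noise goes to zero", {
  e <- ellipse2d(200, 150, a = 100, b = 50, orientation_deg = 30)
  p <- render_ellipse_polygon(e, 64)
  err <- vapply(c(1, 0.1, 0.01), function(sigma) {
    set.seed(77)
    devs <- replicate(30, {
      f <- fit_ellipse(p + matrix(rnorm(length(p), sd = sigma), ncol = 2))
      abs(f$a - e$a) + abs(f$b - e$b)
    })
    mean(devs)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("conic-to-geometric conversion handles canonical cases", {
  circ <- conic_to_geometric(conic_coefficients(1, 0, 1, 0, 0, -1))
  expect_equal(circ$cx, 0); expect_equal(circ$cy, 0)
  expect_equal(circ$a, 1); expect_equal(circ$b, 1)
  ax <- conic_to_geometric(c(0.25, 0, 1, 0, 0, -1))
  expect_equal(ax$a, 2); expect_equal(ax$b, 1)
  expect_equal(ax$orientation_deg, 0)
  expect_error(conic_to_geometric(c(1, 0, -1, 0, 0, -1)), "not an ellipse")
  ## negative-scaled coefficients describe the same ellipse
  neg <- conic_to_geometric(-c(0.25, 0, 1, 0, 0, -1))
  expect_equal(neg$a, 2); expect_equal(neg$b, 1)
})

test_that("partial arcs fit but warn below 120 degrees of span", {
  e <- ellipse2d(0, 0, a = 80, b = 40, orientation_deg = 10)
  p <- render_ellipse_polygon(e, 360)
  expect_warning(f <- fit_ellipse(p[1:60, ]), "span")
  expect_equal(f$a, e$a, tolerance = 1e-4)
  expect_silent(fit_ellipse(p[1:240, ]))
})
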