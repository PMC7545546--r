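test_that("ellipse constructor normalizes axis order and orientation", {
  e <- ellipse2d(0, 0, a = 5, b = 10, orientation_deg = 20)
  expect_equal(e$a, 10)
  expect_equal(e$b, 5)
  expect_equal(e$orientation_deg, 110)
  expect_equal(ellipse2d(0, 0, 10, 5, 365)$orientation_deg, 5)
  expect_error(ellipse2d(0, 0, -1, 0), "non-negative")
})

test_that("radiographic anteversion follows arcsin(short/long axis)", {
  expect_equal(radiographic_anteversion(ellipse2d(0, 0, 10, 0)), 0)
  expect_equal(radiographic_anteversion(ellipse2d(0, 0, 10, 10)), 90)
  expect_equal(radiographic_anteversion(ellipse2d(0, 0, 10, 5)), 30)
  expect_error(radiographic_anteversion(ellipse2d(0, 0, 0, 0)), "degenerate")
  ## monotone in the axis ratio
  ratios <- seq(0, 1, by = 0.05)
  u <- vapply(ratios, function(r)
    radiographic_anteversion(ellipse2d(0, 0, 10, 10 * r)), 0)
  expect_true(all(diff(u) > 0))
})

test_that("beta_p and the trigonometric anteversion formula", {
  expect_equal(beta_p(ellipse2d(0, 0, 10, 10)), 45)
  expect_equal(beta_p(ellipse2d(0, 0, 10, 0)), 0)
  expect_equal(beta_p(ellipse2d(0, 0, 10, 5)), 26.565, tolerance = 1e-3)
  expect_equal(liaw_anteversion(0), 0)
  expect_equal(liaw_anteversion(45), 90)
  expect_equal(liaw_anteversion(26.565), 30, tolerance = 1e-2)
  expect_error(liaw_anteversion(46), "45")
})

test_that("the two anteversion formulations are identical on valid ellipses", {
  for (e in random_ellipses(200, seed = 11)) {
    expect_equal(liaw_anteversion(beta_p(e)), radiographic_anteversion(e),
                 tolerance = 1e-9)
  }
})

test_that("angle operations are invariant under uniform scaling", {
  for (e in random_ellipses(25, seed = 3)) {
    for (s in c(0.1, 3.7)) {
      es <- ellipse2d(e$cx, e$cy, s * e$a, s * e$b, e$orientation_deg)
      expect_equal(radiographic_anteversion(es), radiographic_anteversion(e),
                   tolerance = 1e-12)
      expect_equal(beta_p(es), beta_p(e), tolerance = 1e-12)
    }
  }
})

test_that("polygon rendering samples the parametric ellipse", {
  circ <- ellipse2d(0, 0, 1, 1)
  poly <- render_ellipse_polygon(circ)
  expect_equal(nrow(poly), 64)                        # default segment count
  expect_true(all(abs(sqrt(rowSums(poly^2)) - 1) < 1e-12))
  expect_error(render_ellipse_polygon(circ, 2), ">= 3")

  ## shoelace area of the 64-gon vs closed form pi*a*b (within 0.5%)
  e <- ellipse2d(40, -10, 10, 5, 77)
  p <- render_ellipse_polygon(e, 64)
  i2 <- c(2:nrow(p), 1)
  area <- abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
  expect_lt(abs(area - pi * 10 * 5) / (pi * 10 * 5), 0.005)

  ## every vertex satisfies the implicit equation after inverse transform
  for (e in random_ellipses(20, seed = 7)) {
    p <- render_ellipse_polygon(e, 17)
    expect_true(all(abs(cupav:::ellipse_implicit(e, p)) < 1e-9))
  }
})

test_that("inclination is the acute angle to the reference line", {
  line <- line2d(c(0, 0), c(1, 0))
  expect_equal(inclination(ellipse2d(0, 0, 10, 5, 0), line), 0)
  expect_equal(inclination(ellipse2d(0, 0, 10, 5, 45), line), 45)
  expect_equal(inclination(ellipse2d(0, 0, 10, 5, 135), line), 45)
  ## independent of which way the line is directed
  expect_equal(inclination(ellipse2d(0, 0, 10, 5, 30), line2d(c(5, 2), c(-1, 0))),
               30, tolerance = 1e-12)
})
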