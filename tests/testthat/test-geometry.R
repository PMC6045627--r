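test_that("shoelace area, perimeter and centroid are exact on simple polygons", {
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(polygonArea(sq), 10000)
  expect_equal(polygonPerimeter(sq), 400)
  expect_equal(polygonCentroid(sq), c(50, 50))
  # orientation is immaterial for the magnitude
  expect_equal(polygonArea(sq[4:1, ]), 10000)
  # concentric discs: annulus area difference pi (100^2 - 80^2)
  a_out <- polygonArea(circlePoly(100, n = 2000L))
  a_in <- polygonArea(circlePoly(80, n = 2000L))
  expect_equal(a_out - a_in, pi * (100^2 - 80^2), tolerance = 1e-4)
})

test_that("contour construction canonicalizes and rejects invalid polygons", {
  sq <- cbind(c(0, 0, 100, 100), c(0, 100, 100, 0))  # clockwise input
  ct <- makeContour(sq)
  expect_gt(airwaymorph:::signedArea(ct), 0)  # counterclockwise out
  bowtie <- cbind(c(0, 100, 20, 80), c(0, 0, 60, 60))
  expect_error(makeContour(bowtie), "self-intersecting")
  expect_error(makeContour(cbind(c(0, 1), c(0, 1))), "3 distinct")
  degenerate <- cbind(c(0, 50, 100), c(0, 0, 0))
  expect_error(makeContour(degenerate), "area is zero")
})

test_that("circularity is 1 for circles, pi/4 for squares, matches the ellipse oracle", {
  expect_equal(circularity(circlePoly(100, n = 2000L)), 1, tolerance = 1e-5)
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) * 120
  expect_equal(circularity(sq), pi / 4)
  # 2:1 ellipse: perimeter by numeric quadrature as the independent oracle
  a <- 200; b <- 100
  th <- seq(0, 2 * pi, length.out = 4001L)[-4001L]
  ell <- cbind(a * cos(th), b * sin(th))
  p_oracle <- stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                               0, 2 * pi, rel.tol = 1e-10)$value
  c_oracle <- 4 * pi * (pi * a * b) / p_oracle^2
  expect_equal(circularity(ell), c_oracle, tolerance = 1e-4)
  expect_equal(c_oracle, 0.8412, tolerance = 1e-3)
  expect_error(circularity(cbind(c(1, 1, 1), c(2, 2, 2))), "zero")
})

test_that("rasterized disc traces to the analytic area and near-unit circularity", {
  r <- 200; n <- 512
  m <- outer(seq_len(n) - 0.5, seq_len(n) - 0.5,
             function(x, y) (x - n / 2)^2 + (y - n / 2)^2 <= r^2)
  cts <- traceContours(m)
  expect_length(cts, 1L)
  expect_equal(polygonArea(cts[[1]]), pi * r^2, tolerance = 0.01)
  expect_equal(circularity(cts[[1]]), 1, tolerance = 0.02)
  # calibration round-trip: tracing in um equals tracing in px times the scale
  cts_um <- traceContours(m, um_per_px = 0.452)
  expect_equal(cts_um[[1]], cts[[1]] * 0.452)
})

test_that("Feret diameter equals the brute-force all-pairs maximum", {
  expect_equal(feretDiameter(circlePoly(150, n = 1000L)), 300, tolerance = 0.01)
  rect <- cbind(c(0, 300, 300, 0), c(0, 0, 400, 400))
  expect_equal(feretDiameter(rect), 500)
  for (seed in 1:5) {
    set.seed(seed)
    poly <- cbind(runif(50, 0, 400), runif(50, 0, 400))
    d2 <- outer(poly[, 1], poly[, 1], "-")^2 + outer(poly[, 2], poly[, 2], "-")^2
    expect_equal(feretDiameter(poly), sqrt(max(d2)))
  }
})

test_that("epithelium area is the exact bronchiole-minus-lumen difference", {
  expect_equal(epitheliumArea(10000, 6000), 4000)
  expect_equal(epitheliumArea(10000, 0), 10000)
  a_out <- polygonArea(circlePoly(100, n = 2000L))
  a_in <- polygonArea(circlePoly(80, n = 2000L))
  expect_equal(epitheliumArea(a_out, a_in), pi * (100^2 - 80^2),
               tolerance = 0.01)
  expect_error(epitheliumArea(5000, 6000), "inconsist")
  expect_error(epitheliumArea(-1, 0), "non-negative")
})

test_that("radial thickness matches analytic annulus geometry", {
  inner <- circlePoly(80, n = 720L)
  outer_ct <- circlePoly(100, n = 720L)
  th <- epitheliumThickness(inner, outer_ct)
  expect_equal(th$mean, 20, tolerance = 1e-3)
  expect_lt(th$sd, 0.01)
  expect_equal(th$n_measures, 360L)
  # identical contours: zero thickness
  th0 <- epitheliumThickness(inner, inner)
  expect_equal(th0$mean, 0, tolerance = 1e-9)
  # offset annulus: compare against the dense analytic ray oracle
  inner2 <- circlePoly(80, center = c(5, 0), n = 1440L)
  outer2 <- circlePoly(100, center = c(0, 0), n = 1440L)
  th2 <- epitheliumThickness(inner2, outer2, n_rays = 720L)
  ang <- seq(0, 2 * pi, length.out = 3601L)[-3601L]
  oracle <- rayCircleDist(c(5, 0), ang, c(0, 0), 100) -
    rayCircleDist(c(5, 0), ang, c(5, 0), 80)
  expect_equal(th2$mean, mean(oracle), tolerance = 0.005)
  expect_equal(th2$sd, sd(oracle), tolerance = 0.02)
  expect_equal(min(th2$thickness_um), 15, tolerance = 0.02)
  expect_equal(max(th2$thickness_um), 25, tolerance = 0.02)
  expect_error(epitheliumThickness(inner, outer_ct, n_rays = 50), "at least 100")
})

test_that("thickness results with too few valid measures are flagged, not fatal", {
  inner <- circlePoly(10, n = 200L)
  far <- circlePoly(1, center = c(500, 500), n = 64L)  # rays mostly miss
  expect_warning(th <- epitheliumThickness(inner, far, n_rays = 120L),
                 "unreliable")
  expect_false(th$reliable)
  expect_lt(th$n_measures, 100L)
})

test_that("polygon geometry is scale-equivariant", {
  set.seed(42)
  poly <- circlePoly(100, n = 360L) + cbind(rnorm(360, 0, 4), rnorm(360, 0, 4))
  poly <- makeContour(poly, check_simple = FALSE)
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(polygonArea(poly * k), k^2 * polygonArea(poly))
    expect_equal(polygonPerimeter(poly * k), k * polygonPerimeter(poly))
    expect_equal(feretDiameter(poly * k), k * feretDiameter(poly))
    expect_equal(circularity(poly * k), circularity(poly))
  }
})

test_that("scanline rasterization and point-in-polygon agree with analytic areas", {
  disc <- circlePoly(60, center = c(100, 100), n = 720L)
  m <- airwaymorph:::rasterizePolygon(disc, 200L, 200L)
  expect_equal(sum(m), pi * 60^2, tolerance = 0.01)
  px <- rep(seq(0.5, 199.5), times = 200)
  py <- rep(seq(0.5, 199.5), each = 200)
  inside <- pointInPolygon(px, py, disc)
  expect_equal(sum(inside), sum(m))
})
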