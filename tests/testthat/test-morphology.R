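test_that("contour geometry matches closed forms", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  g <- contour_geometry(sq)
  expect_equal(g$area, 1)
  expect_equal(g$perimeter, 4)
  expect_equal(unname(g$centroid), c(0.5, 0.5))

  gc <- contour_geometry(circle_contour(r = 10, n = 360))
  expect_equal(gc$area, pi * 100, tolerance = 1e-4)
  expect_equal(gc$perimeter, 20 * pi, tolerance = 1e-4)

  expect_error(contour_geometry(cbind(0:4, 0:4)), class = "busfusion_geometry_error")
})

test_that("compactness is the isoperimetric ratio", {
  expect_equal(compactness(pi * 25, 10 * pi), 1) # circle, analytic A and L
  expect_equal(compactness(4, 8), pi / 4) # square side 2

  # ellipse a = 2, b = 1 against the numeric-perimeter oracle
  L <- ellipse_perimeter_numeric(2, 1)
  C <- compactness(2 * pi, L)
  expect_equal(C, 4 * pi * 2 * pi / L^2)
  expect_equal(C, 0.8415, tolerance = 1e-3)

  expect_error(compactness(0, 1), class = "busfusion_param_error")
})

test_that("direct least-squares ellipse fit recovers exact and noisy ellipses", {
  pts <- ellipse_contour(3, 1.5, theta = 30 * pi / 180, center = c(10, 10), n = 50)
  f <- fit_ellipse(pts)
  expect_equal(f$a, 3, tolerance = 1e-6)
  expect_equal(f$b, 1.5, tolerance = 1e-6)
  expect_equal(unname(f$center), c(10, 10), tolerance = 1e-6)
  expect_equal(f$theta, 30 * pi / 180, tolerance = 1e-6)

  fc <- fit_ellipse(circle_contour(r = 7, n = 100, center = c(3, -2)))
  expect_equal(fc$a, 7, tolerance = 1e-6)
  expect_equal(fc$b, 7, tolerance = 1e-6)

  expect_error(fit_ellipse(pts[1:5, ]), class = "busfusion_fit_error")
  line <- cbind(1:20, 2 * (1:20) + 1)
  expect_error(fit_ellipse(line), class = "busfusion_fit_error")

  # Gaussian point noise sigma = 0.5 px on a 30 x 15 ellipse: axes within 2%
  big <- ellipse_contour(30, 15, theta = 1, center = c(100, 120), n = 200)
  withr::with_seed(21, noisy <- big + matrix(rnorm(length(big), 0, 0.5), ncol = 2))
  fn <- fit_ellipse(noisy)
  expect_equal(fn$a, 30, tolerance = 0.02)
  expect_equal(fn$b, 15, tolerance = 0.02)
})

test_that("elliptic compactness is the fitted-circumference ratio", {
  circ <- circle_contour(r = 12, n = 360)
  g <- contour_geometry(circ)
  f <- fit_ellipse(circ)
  expect_equal(elliptic_compactness(f, g$perimeter), 1, tolerance = 1e-3)
  # ratio by construction: contour perimeter twice the ellipse circumference
  expect_equal(elliptic_compactness(f, 2 * pi * (f$a + f$b) / 2 * 2), 0.5, tolerance = 1e-9)
  expect_error(elliptic_compactness(f, 0), class = "busfusion_param_error")
})

test_that("radial profile resamples by arc length and counts lobes", {
  rp <- radial_profile(circle_contour(r = 9, n = 360))
  expect_equal(rp$distances, rep(9, 128), tolerance = 1e-4)

  sq <- cbind(x = c(-1, 1, 1, -1), y = c(-1, -1, 1, 1))
  rq <- radial_profile(sq)
  expect_gte(min(rq$distances), 1 - 1e-9)
  expect_lte(max(rq$distances), sqrt(2) + 1e-9)

  th <- seq(0, 2 * pi, length.out = 241)[1:240]
  r3 <- 10 * (1 + 0.2 * cos(3 * th))
  rp3 <- radial_profile(cbind(r3 * cos(th), r3 * sin(th)))
  d <- rp3$distances
  n_max <- sum(d > c(tail(d, 1), head(d, -1)) & d > c(d[-1], d[1]))
  expect_equal(n_max, 3)
})

test_that("radial spectrum statistics isolate harmonics above the DC term", {
  const <- structure(list(distances = rep(10, 128)), class = "radial_profile")
  s0 <- radial_spectrum_features(const)
  expect_equal(unname(s0["rds_mean"]), log(1e-8))
  expect_equal(unname(s0["rds_var"]), 0)

  # single harmonic at k = 3: dominant amplitude 1 at that harmonic
  n <- 128
  d3 <- 10 + cos(2 * pi * 3 * (0:(n - 1)) / n)
  p3 <- structure(list(distances = d3), class = "radial_profile")
  amps <- 2 * Mod(fft(d3))[2:(n / 2 + 1)] / n
  expect_equal(which.max(amps), 3)
  expect_equal(max(amps), 1, tolerance = 1e-9)
  s3 <- radial_spectrum_features(p3)
  expect_gt(unname(s3["rds_var"]), unname(s0["rds_var"]))
})

test_that("morphology features are invariant to rigid motion and scale as documented", {
  th <- seq(0, 2 * pi, length.out = 181)[1:180]
  withr::with_seed(31, jag <- 10 * (1 + 0.15 * cos(4 * th) + 0.05 * cos(7 * th) +
    0.01 * rnorm(180)))
  base <- cbind(x = jag * cos(th), y = jag * sin(th))
  v <- morphology_features(base)
  expect_length(v, 4)
  expect_identical(v, morphology_features(base))

  # translation + rotation
  ang <- 0.7
  rot <- cbind(
    x = base[, 1] * cos(ang) - base[, 2] * sin(ang) + 40,
    y = base[, 1] * sin(ang) + base[, 2] * cos(ang) - 13
  )
  expect_equal(morphology_features(rot), v, tolerance = 1e-6)

  # uniform scale: C, EC, RDSvar invariant; RDSmean shifts by log(scale)
  sc <- morphology_features(base * 10)
  expect_equal(sc[c("morph_C", "morph_EC", "morph_RDSvar")],
    v[c("morph_C", "morph_EC", "morph_RDSvar")],
    tolerance = 1e-3
  )
  expect_equal(unname(sc["morph_RDSmean"] - v["morph_RDSmean"]), log(10), tolerance = 1e-3)

  # circle limit: C and EC near 1, flat spectrum near the epsilon floor
  mc <- morphology_features(circle_contour(r = 10, n = 360))
  expect_equal(unname(mc["morph_C"]), 1, tolerance = 1e-3)
  expect_equal(unname(mc["morph_EC"]), 1, tolerance = 1e-3)
})
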