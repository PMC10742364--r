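test_that("polynomial regression recovers generating polynomials", {
  # straight line y = 2x in image coordinates
  cf <- fit_interface_curve(poly_trace(c(2, 0), 0:10), frame = "image")
  expect_equal(cf$coefficients, c(0, 0, 0, 2, 0), tolerance = 1e-9)
  expect_equal(cf$degree_used, 4L)

  # noiseless quartic y = x^4/1e6 + 3 on 30 stations
  cf2 <- fit_interface_curve(poly_trace(c(1e-6, 0, 0, 0, 3),
                                        seq(0, 100, length.out = 30)),
                             frame = "image")
  expect_equal(cf2$coefficients, c(1e-6, 0, 0, 0, 3), tolerance = 1e-6)

  # exactly 5 markers in general position: the quartic interpolates
  set.seed(11)
  pts <- cbind(row = rnorm(5, 50, 10), col = c(1, 3, 7, 12, 20))
  cf3 <- fit_interface_curve(marker_trace(pts), frame = "image")
  fitted <- sapply(pts[, "col"], function(x)
    sum(cf3$coefficients * x^(4:0)))
  expect_equal(fitted, unname(pts[, "row"]), tolerance = 1e-6)
})

test_that("degree degrades gracefully with few markers and errors below 2", {
  cf <- fit_interface_curve(poly_trace(c(1, 5), c(0, 10, 20)))
  expect_equal(cf$degree_used, 2L)
  expect_lt(cf$x_lo, cf$x_hi)
  expect_error(fit_interface_curve(marker_trace(cbind(row = 1, col = 1))),
               "fewer than 2")
  expect_error(fit_interface_curve(marker_trace()), "fewer than 2")
})

test_that("arc length matches closed-form oracles", {
  # line y = x over [0, 100]: 100 * sqrt(2)
  cf <- fit_interface_curve(poly_trace(c(1, 0), 0:100), frame = "image")
  expect_equal(arc_length(cf, 0, 100), 100 * sqrt(2), tolerance = 1e-7)

  # parabola y = x^2/200 over [0, 100]: closed form
  # 100 * (u sqrt(1+u^2) + asinh u)/2 at u = 1
  cf2 <- fit_interface_curve(poly_trace(c(1 / 200, 0, 0), seq(0, 100, 2)),
                             frame = "image")
  expect_equal(arc_length(cf2, 0, 100), 50 * (sqrt(2) + asinh(1)),
               tolerance = 1e-7)

  # constant curve: flat length
  cf3 <- fit_interface_curve(line_trace(12, seq(0, 50, 5)), frame = "image")
  expect_equal(arc_length(cf3, 0, 50), 50, tolerance = 1e-9)

  expect_error(arc_length(cf, 10, 5), "x_lo")
})

test_that("arc length is additive and bounded below by the chord", {
  cf <- fit_interface_curve(poly_trace(c(2e-7, -1e-5, 3e-3, 0.2, 10),
                                       seq(0, 200, 5)), frame = "image")
  total <- arc_length(cf, 0, 200)
  expect_equal(arc_length(cf, 0, 80) + arc_length(cf, 80, 200), total,
               tolerance = 1e-6)

  chord <- function(c_, lo, hi) {
    y <- function(x) sum(c_$coefficients * x^(4:0))
    sqrt((hi - lo)^2 + (y(hi) - y(lo))^2)
  }
  expect_gt(total, chord(cf, 0, 200))
  # equality holds only for an affine fit
  aff <- fit_interface_curve(poly_trace(c(0.5, 3), seq(0, 100, 10)),
                             frame = "image")
  expect_equal(arc_length(aff, 0, 100), chord(aff, 0, 100), tolerance = 1e-6)
})

test_that("arc length is invariant under rigid rotation of the marker set", {
  cols <- seq(0, 150, 3)
  base <- poly_trace(c(0, 0, 1e-3, 0.1, 30), cols)
  s0 <- arc_length(fit_interface_curve(base))
  for (ang in c(0.3, 1.0, pi / 2, 2.4)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    xy <- cbind(base$markers[, "col"], base$markers[, "row"]) %*% R
    rot <- marker_trace(cbind(row = xy[, 2] + 500, col = xy[, 1] + 500))
    expect_equal(arc_length(fit_interface_curve(rot)), s0, tolerance = 1e-3)
  }
})

test_that("penetration measurement calibrates, caps, and flags statuses", {
  # trace whose fitted arc length is exactly 1000 px
  cf_line <- line_trace(100, seq(10, 1010, 10))
  res <- measure_penetration(cf_line)
  expect_equal(res$arc_length_px, 1000, tolerance = 1e-6)
  expect_equal(res$penetration_mm, 1000 * 0.0013028, tolerance = 1e-9)
  expect_equal(res$status, "measured")
  expect_false(res$capped)

  # doubling mm_per_pixel doubles uncapped penetration exactly
  res2 <- measure_penetration(cf_line, calibration_spec(2 * 0.0013028, 7.18))
  expect_equal(res2$penetration_mm, 2 * res$penetration_mm)

  # metric cap: arc length beyond cap_mm / mm_per_pixel
  long <- line_trace(100, seq(0, 6000, 10))
  resc <- measure_penetration(long)
  expect_true(resc$capped)
  expect_identical(resc$penetration_mm, 7.18)
  expect_equal(resc$status, "complete_penetration")

  # geometric cap: trace passes the die-center landmark
  resg <- measure_penetration(cf_line, die_center = c(100, 800))
  expect_true(resg$capped)
  expect_identical(resg$penetration_mm, 7.18)
  # landmark beyond the trace: no geometric cap
  resn <- measure_penetration(cf_line, die_center = c(100, 2000))
  expect_false(resn$capped)

  # empty / single-marker traces
  expect_equal(measure_penetration(marker_trace())$status, "no_dye")
  expect_equal(measure_penetration(marker_trace())$penetration_mm, 0)
  one <- marker_trace(cbind(row = 5, col = 5))
  expect_equal(measure_penetration(one)$status, "no_dye")

  expect_error(calibration_spec(mm_per_pixel = 0), "positive")
  expect_error(calibration_spec(cap_mm = -1), "positive")
})

test_that("appending markers that extend the trace never decreases penetration", {
  cols <- seq(0, 400, 5)
  full <- poly_trace(c(0, 1e-6, 5e-4, 0.2, 50), cols)
  pen <- sapply(seq(10, length(cols), 5), function(m)
    measure_penetration(marker_trace(full$markers[1:m, ]))$penetration_mm)
  expect_true(all(diff(pen) >= -1e-9))
})

test_that("curve overlay paints only pixels near the curve and preserves the input", {
  img <- blank_raster(120, 200, c(230, 230, 230))
  tr <- poly_trace(c(0, 0, 1e-3, 0.2, 30), seq(5, 195, 5))
  cf <- fit_interface_curve(tr)
  out <- render_overlay(img, cf)
  expect_identical(img[1, 1, ], c(230, 230, 230))   # input untouched
  diffpix <- which(apply(out != img, c(1, 2), any), arr.ind = TRUE)
  expect_gt(nrow(diffpix), 50)
  # every painted pixel lies within 1 px of the generating curve
  truth <- 1e-3 * diffpix[, 2]^2 + 0.2 * diffpix[, 2] + 30
  expect_true(all(abs(diffpix[, 1] - truth) <= 1.8))

  # degenerate two-marker curve: straight segment between endpoints
  seg <- fit_interface_curve(marker_trace(cbind(row = c(10, 20), col = c(10, 110))))
  out2 <- render_overlay(img, seg)
  d2 <- which(apply(out2 != img, c(1, 2), any), arr.ind = TRUE)
  pred <- 10 + (d2[, 2] - 10) / 10
  expect_true(all(abs(d2[, 1] - pred) <= 1))
})
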