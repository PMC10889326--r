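test_that("closed-form length, angle and area cases are exact", {
  expect_equal(measure_length(c(0, 0), c(3, 4))$raw_value, 5)
  expect_equal(measure_length(c(7, 7), c(7, 7))$raw_value, 0)
  m <- measure_length(c(0, 0), c(3, 4), calibration(0.1))
  expect_equal(m$calibrated_value, 0.5)
  expect_identical(m$calibrated_units, "mm")

  expect_equal(measure_angle(c(1, 0), c(0, 0), c(0, 1))$raw_value, 90)
  expect_equal(measure_angle(c(-1, 0), c(0, 0), c(1, 0))$raw_value, 180)
  expect_equal(measure_angle(c(2, 0), c(0, 0), c(2, 2))$raw_value, 45)
  expect_error(measure_angle(c(0, 0), c(0, 0), c(1, 1)), class = "bs_validation_error")

  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(measure_area(sq)$raw_value, 1)
  expect_equal(measure_area(sq, calibration(0.5))$calibrated_value, 0.25)
  expect_equal(measure_area(rbind(c(0, 0), c(4, 0), c(0, 3)))$raw_value, 6)
  expect_error(measure_area(rbind(c(0, 0), c(1, 1))), class = "bs_validation_error")
})

test_that("known-object calibration divides length by measured size", {
  expect_equal(calibrate_known_object(250, 25)$scale_mm_per_px, 0.1)
  expect_equal(calibrate_known_object(100, 30)$scale_mm_per_px, 0.3)
  expect_identical(calibrate_known_object(250, 25)$source, "known_object")
  expect_error(calibrate_known_object(0, 25), class = "bs_validation_error")
  expect_error(calibrate_known_object(250, -1), class = "bs_validation_error")
})

test_that("shoelace area matches the fan-triangulation oracle on seeded polygons", {
  for (seed in 1:100) {
    n <- 3L + (seed %% 10L)
    pts <- random_star_polygon(n, seed)
    shoelace <- measure_area(pts)$raw_value
    oracle <- fan_triangulation_area(pts, c(20, 20))
    expect_equal(shoelace, oracle, tolerance = 1e-9)
  }
  # axis-aligned rectangles are exact
  set.seed(99)
  for (i in 1:20) {
    w <- runif(1, 0.5, 40); h <- runif(1, 0.5, 40); x0 <- runif(1); y0 <- runif(1)
    rect <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
    expect_equal(measure_area(rect)$raw_value, w * h)
  }
})

test_that("measurements are invariant under similarity transforms", {
  set.seed(1234)
  for (trial in 1:1000) {
    pts <- matrix(runif(8, -20, 20), ncol = 2)
    k <- runif(1, 0.1, 10)
    theta <- runif(1, 0, 2 * pi)
    shift <- runif(2, -50, 50)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    tpts <- t(k * R %*% t(pts) + shift)

    # scaling coordinates by k with calibration scale/k leaves mm invariant
    s <- runif(1, 0.01, 2)
    len0 <- measure_length(pts[1, ], pts[2, ], calibration(s))$calibrated_value
    len1 <- measure_length(pts[1, ] * k, pts[2, ] * k, calibration(s / k))$calibrated_value
    expect_equal(len0, len1, tolerance = 1e-9)

    poly <- rbind(pts, pts[1, ] + c(0.5, 0.7))  # 5 points
    a0 <- measure_area(poly, calibration(s))$calibrated_value
    a1 <- measure_area(poly * k, calibration(s / k))$calibrated_value
    expect_equal(a0, a1, tolerance = 1e-9)

    # angle invariant under the full similarity transform (rotate+scale+shift)
    if (sum((pts[1, ] - pts[2, ])^2) > 1e-6 && sum((pts[3, ] - pts[2, ])^2) > 1e-6) {
      ang0 <- measure_angle(pts[1, ], pts[2, ], pts[3, ])$raw_value
      ang1 <- measure_angle(tpts[1, ], tpts[2, ], tpts[3, ])$raw_value
      # acos conditioning near 0/180 deg bounds the achievable agreement
      expect_equal(ang0, ang1, tolerance = 1e-6)
    }
  }
})

test_that("px to mm conversion round-trips within 1e-12 relative", {
  set.seed(7)
  for (i in 1:50) {
    s <- runif(1, 0.001, 5)
    px <- runif(1, 0.1, 5000)
    mm <- px * s
    expect_equal(mm / s, px, tolerance = 1e-12)
    m <- measure_length(c(0, 0), c(px, 0), calibration(s))
    expect_equal(m$calibrated_value / s, m$raw_value, tolerance = 1e-12)
  }
})

test_that("anisotropic spacing combines per axis for length, row x col for area", {
  cal <- calibration(0.2, "dicom_metadata", row_mm_per_px = 0.2, col_mm_per_px = 0.25)
  expect_true(cal$anisotropic)
  m <- measure_length(c(0, 0), c(4, 3), cal)  # dx=4 cols, dy=3 rows
  expect_equal(m$calibrated_value, sqrt((4 * 0.25)^2 + (3 * 0.2)^2))
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(measure_area(sq, cal)$calibrated_value, 100 * 0.2 * 0.25)
})

test_that("marker counting honors an inclusive rectangular ROI", {
  pts <- lapply(1:7, function(i) c(i, i))
  expect_identical(count_markers(pts)$raw_value, 7L)
  expect_identical(count_markers(list())$raw_value, 0L)
  five <- list(c(0, 0), c(2, 2), c(3, 3), c(4, 4), c(10, 10))
  expect_identical(count_markers(five, roi = c(2, 2, 4, 4))$raw_value, 3L)
  # boundary inclusive
  expect_identical(count_markers(list(c(2, 2)), roi = c(2, 2, 4, 4))$raw_value, 1L)
})

test_that("probe reports rescaled DICOM values and RGB triples", {
  syn <- make_synthetic_dicom(48, 48, n_blobs = 0, bar_px = NULL,
                              rescale = c(2, -1024), seed = 1)
  fr <- decode_frame(syn$dicom, "dicom")
  # background stored value is 0.1 * 4000 = 400 -> 400*2 - 1024 = -224
  expect_equal(probe_pixel(fr, c(5, 5))$raw_value, -224)

  png_syn <- make_synthetic_png(48, 48, n_blobs = 0, bar_px = 20, seed = 1)
  pf <- decode_frame(png_syn$png, "png")
  bar_mid <- (png_syn$truth$bar$p1 + png_syn$truth$bar$p2) / 2 + c(0, 1)
  expect_equal(unname(probe_pixel(pf, bar_mid)$raw_value), c(0, 0, 0))
})

test_that("convert applies scale to length/area and warns for scale-free kinds", {
  cal <- calibration(0.2)
  len <- measure_length(c(0, 0), c(50, 0))
  expect_equal(convert_measurement(len, cal)$calibrated_value, 10)
  area <- measure_area(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(convert_measurement(area, cal)$calibrated_value, 4)
  ang <- measure_angle(c(1, 0), c(0, 0), c(0, 1))
  expect_warning(out <- convert_measurement(ang, cal), "scale-free")
  expect_equal(out$raw_value, 90)
  expect_null(out$calibrated_value)
})

test_that("measurement JSON serialization round-trips", {
  ms <- list(measure_length(c(0, 0), c(3, 4), calibration(0.1)),
             measure_angle(c(1, 0), c(0, 0), c(0, 1)),
             count_markers(list(c(1, 1), c(2, 2))))
  back <- measurements_from_json(measurements_to_json(ms))
  expect_length(back, 3L)
  expect_equal(back[[1]]$raw_value, 5)
  expect_equal(back[[1]]$calibrated_value, 0.5)
  expect_equal(back[[2]]$raw_value, 90)
  expect_identical(back[[3]]$kind, "count")
})
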