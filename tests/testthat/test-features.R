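calib <- list(pixel_size_radial = 0.005)

test_that("lumen measures of a sampled circle match the analytic values", {
  lum <- rep(1.0 / calib$pixel_size_radial, 360)
  res <- compute_lumen(lum, calib)
  expect_equal(res$area_mm2, pi, tolerance = 1e-3)
  expect_equal(res$diameter_mm, 2.0, tolerance = 1e-3)
  expect_equal(res$perimeter_mm, 2 * pi, tolerance = 1e-3)
  expect_equal(unname(res$centroid_mm), c(0, 0), tolerance = 1e-12)
})

test_that("lumen measures of an ellipse match the dense-polygon oracle", {
  lum <- ellipse_lumen_px(0.5, 1.0, 720, calib$pixel_size_radial)
  res <- compute_lumen(lum, calib)
  expect_equal(res$area_mm2, pi * 0.5 * 1.0, tolerance = 1e-3)
  expect_equal(res$diameter_mm, 2 * sqrt(0.5), tolerance = 1e-3)
  # minimum caliper width of the ellipse is its minor axis
  res2 <- compute_lumen(lum, calib, diameter_method = "caliper")
  expect_equal(res2$diameter_mm, 1.0, tolerance = 1e-2)
})

test_that("degenerate lumen contours are rejected with a reason", {
  expect_error(compute_lumen(c(100, 100), calib),
               class = "octplaq_annotation_error", regexp = "vertices")
  expect_error(compute_lumen(c(100, -2, 100, 100), calib),
               class = "octplaq_annotation_error", regexp = "positive")
})

test_that("circle-area discretization error at least halves when A-lines double", {
  err <- vapply(c(90, 180, 360, 720), function(A) {
    abs(compute_lumen(rep(200, A), calib)$area_mm2 - pi * 1.0^2)
  }, numeric(1))
  expect_true(all(err[-1] <= err[-length(err)] / 2))
})

test_that("a constant annulus deposit yields arc, thickness, and depth directly", {
  psr <- calib$pixel_size_radial
  lum <- rep(1.0 / psr, 360)
  cen <- c(0, 0)
  dep <- list(a_lines = 0:90, inner = rep(1.2 / psr, 91),
              outer = rep(1.5 / psr, 91))
  res <- compute_calcium(list(dep), lum, cen, calib)
  expect_equal(res$angle_deg, 90, tolerance = 1e-9)
  expect_equal(res$thickness_max_mm, 0.3, tolerance = 1e-12)
  expect_equal(res$thickness_min_mm, 0.3, tolerance = 1e-12)
  expect_equal(res$depth_max_mm, 0.2, tolerance = 1e-12)
  expect_equal(res$depth_min_mm, 0.2, tolerance = 1e-12)
})

test_that("disjoint deposit arcs add and wrap across the 0-degree A-line", {
  psr <- calib$pixel_size_radial
  lum <- rep(1.0 / psr, 360)
  d1 <- list(a_lines = 10:50, inner = rep(240, 41), outer = rep(280, 41))
  d2 <- list(a_lines = (c(330:359, 0:5)), inner = rep(240, 36),
             outer = rep(280, 36))  # 35-degree arc across 12 o'clock
  res <- compute_calcium(list(d1, d2), lum, c(0, 0), calib)
  expect_equal(res$angle_deg, 40 + 35, tolerance = 1e-9)
})

test_that("a deposit reaching inside the lumen is an annotation error", {
  psr <- calib$pixel_size_radial
  lum <- rep(1.0 / psr, 360)
  dep <- list(a_lines = 0:10, inner = rep(0.9 / psr, 11),
              outer = rep(1.5 / psr, 11))
  expect_error(compute_calcium(list(dep), lum, c(0, 0), calib),
               class = "octplaq_annotation_error", regexp = "A-line")
})

test_that("annular and quarter-annular caps match closed-form geometry", {
  psr <- calib$pixel_size_radial
  A <- 360
  lum <- rep(1.0 / psr, A)
  full <- list(a_lines = 0:359, abluminal = rep(1.1 / psr, A), closed = TRUE)
  res <- compute_fc(list(full), lum, c(0, 0), calib)
  expect_equal(res$angle_deg, 360)
  expect_equal(res$thickness_min_mm, 0.1, tolerance = 1e-12)
  expect_equal(res$area_mm2, pi * (1.1^2 - 1^2), tolerance = 1e-3)
  expect_equal(res$covered_arc_mm, 2 * pi, tolerance = 1e-3)

  quarter <- list(a_lines = 0:90, abluminal = rep(1.1 / psr, 91))
  resq <- compute_fc(list(quarter), lum, c(0, 0), calib)
  expect_equal(resq$angle_deg, 90, tolerance = 1e-9)
  expect_equal(resq$area_mm2, pi * (1.1^2 - 1^2) / 4, tolerance = 1e-3)
  expect_equal(resq$covered_arc_mm, pi / 2, tolerance = 1e-3)
})

test_that("an abluminal boundary crossing the lumen is an annotation error", {
  psr <- calib$pixel_size_radial
  lum <- rep(1.0 / psr, 360)
  bad <- list(a_lines = 0:10, abluminal = rep(0.95 / psr, 11))
  expect_error(compute_fc(list(bad), lum, c(0, 0), calib),
               class = "octplaq_annotation_error", regexp = "crosses")
})

test_that("lesion aggregation follows the stated min/mean/max and sum rules", {
  frames <- data.frame(
    lumen_area = c(3, 4, 5), lumen_diameter = c(1.9, 2.2, 2.5),
    lumen_perimeter = c(6, 7, 8),
    calcium_angle = c(NA, 90, 40),
    calcium_thickness_max = c(NA, 0.5, 0.3),
    calcium_thickness_min = c(NA, 0.4, 0.2),
    calcium_depth_max = c(NA, 0.25, 0.10),
    calcium_depth_min = c(NA, 0.15, 0.05),
    fc_angle = c(120, NA, 60), fc_thickness_min = c(0.06, NA, 0.09),
    fc_area = c(0.5, NA, 0.8), fc_covered_arc = c(2.0, NA, 1.0))
  v <- aggregate_lesion(frames, frame_pitch = 0.2)
  expect_equal(v[["lesion_length"]], 0.6)
  expect_equal(v[["min_lumen_area"]], 3); expect_equal(v[["mean_lumen_area"]], 4)
  expect_equal(v[["max_calcium_angle"]], 90)
  expect_equal(v[["min_calcium_angle"]], 40)   # frames without calcium excluded
  expect_equal(v[["max_calcium_thickness"]], 0.5)
  expect_equal(v[["min_calcium_thickness"]], 0.2)
  expect_equal(v[["max_fc_angle"]], 120); expect_equal(v[["min_fc_angle"]], 60)
  expect_equal(v[["min_fc_thickness"]], 0.06)
  expect_equal(v[["max_fc_area"]], 0.8)
  expect_equal(v[["fc_surface_area"]], (2.0 + 1.0) * 0.2)
  expect_equal(v[["fc_burden"]], (0.5 + 0.8) * 0.2 / ((6 + 7 + 8) * 0.2))
  expect_equal(attr(v, "fc_burden_x1000"), v[["fc_burden"]] * 1000)
  expect_error(aggregate_lesion(frames[0, ], 0.2),
               class = "octplaq_value_error")
})

test_that("component-free lesions carry missing values, never zeros", {
  pb <- generate_pullback(phantom_config(n_frames = 3, lumen_radius = 1))
  f <- extract_lesion_features(pb)
  ca_cols <- grep("calcium|fc", oct_feature_names(), value = TRUE)
  expect_true(all(is.na(unlist(f[1, ca_cols]))))
})

test_that("a 90-degree cap on a 10-frame cylinder gives the arc-times-length area", {
  cfg <- phantom_config(n_frames = 10, lumen_radius = 1.5, frame_pitch = 0.2,
                        fc_specs = list(fc_spec(1:10, 90, thickness_mm = 0.1)))
  pb <- generate_pullback(cfg)
  expect_equal(pb$ground_truth[["fc_surface_area"]],
               (pi / 2) * 1.5 * (10 * 0.2), tolerance = 1e-12)
  f <- extract_lesion_features(pb)
  expect_equal(f$fc_surface_area, 4.7124, tolerance = 5e-3)
  expect_equal(f$lesion_length, 2.0)
})

test_that("lesion length and cap surface area scale linearly with frame pitch,
           cap burden does not", {
  mk <- function(pitch) {
    cfg <- phantom_config(n_frames = 6, lumen_radius = 1.2, frame_pitch = pitch,
                          fc_specs = list(fc_spec(1:6, 120, thickness_mm = 0.1)))
    extract_lesion_features(generate_pullback(cfg))
  }
  f1 <- mk(0.1); f2 <- mk(0.2)
  expect_equal(f2$lesion_length, 2 * f1$lesion_length)
  expect_equal(f2$fc_surface_area, 2 * f1$fc_surface_area, tolerance = 1e-9)
  expect_equal(f2$fc_burden, f1$fc_burden, tolerance = 1e-9)
})

test_that("min <= mean <= max orderings hold on a mixed phantom", {
  cfg <- phantom_config(
    n_frames = 8, lumen_radius = seq(1.0, 1.6, length.out = 8), seed = 2,
    calcium_specs = list(calcium_spec(2:5, 70, center_deg = 180,
                                      depth_mm = 0.12, thickness_mm = 0.35)),
    fc_specs = list(fc_spec(1:8, 100, center_deg = 40,
                            thickness_mm = c(0.05, 0.12))))
  f <- extract_lesion_features(generate_pullback(cfg))
  expect_lte(f$min_lumen_area, f$mean_lumen_area)
  expect_lte(f$min_lumen_diameter, f$mean_lumen_diameter)
  expect_lte(f$min_calcium_angle, f$max_calcium_angle)
  expect_lte(f$min_calcium_thickness, f$max_calcium_thickness)
  expect_lte(f$min_calcium_depth, f$max_calcium_depth)
  expect_lte(f$min_fc_angle, f$max_fc_angle)
  expect_lte(f$fc_surface_area,
             f$mean_lumen_diameter * pi * f$lesion_length * 1.2)
})

test_that("extraction reproduces the analytic ground truth on a noiseless phantom", {
  cfg <- phantom_config(
    n_frames = 12, lumen_radius = 1.4, frame_pitch = 0.2, seed = 3,
    calcium_specs = list(calcium_spec(3:8, 80, center_deg = 200,
                                      depth_mm = 0.15, thickness_mm = 0.4)),
    fc_specs = list(fc_spec(1:12, 140, center_deg = 30,
                            thickness_mm = c(0.06, 0.16))))
  pb <- generate_pullback(cfg)
  f <- extract_lesion_features(pb)
  gt <- pb$ground_truth
  ang <- grep("angle", oct_feature_names(), value = TRUE)
  for (nm in oct_feature_names()) {
    if (nm %in% ang) expect_lt(abs(f[[nm]] - gt[[nm]]), 1)
    else expect_lt(abs(f[[nm]] - gt[[nm]]) / abs(gt[[nm]]), 0.01)
  }
})
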