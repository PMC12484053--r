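test_that("ring calibration reproduces direct quotients and the identity case", {
  # two rings, one seedling, perimeters {100 inner, 125 outer} -> ratio 0.8
  obs <- data.frame(seedling_id = 1, radial_px = c(10, 500),
                    perimeter_px = c(100, 125))
  m <- fit_ring_calibration(obs, n_rings = 2)
  expect_equal(m$ring_ratio, c(1, 0.8))
  # undistorted observations: every ratio is 1
  cfg0 <- scene_config(k1 = 0, seed = 5)
  cal0 <- generate_calibration_set(cfg0, n_groups = 5)
  m0 <- fit_ring_calibration(cal0, n_rings = 3)
  expect_equal(m0$ring_ratio, c(1, 1, 1), tolerance = 1e-9)
})

test_that("fitted ring ratios track the analytic warp at the ring radii", {
  cal <- fx_calibration()
  model <- fx_model()
  cfg <- fx_config()
  half_diag <- cfg$frame_px * sqrt(2) / 2
  for (r in 2:3) {
    in_ring <- cal$radial_px > model$ring_edges_px[r] &
      cal$radial_px <= model$ring_edges_px[r + 1]
    r_mean <- mean(cal$radial_px[in_ring]) / half_diag
    # calibration strokes lean along the sweep, so the warp stretches them
    # by the radial derivative 1 + 3 k1 r^2
    analytic <- 1 / (1 + 3 * cfg$k1 * r_mean^2)
    expect_equal(model$ring_ratio[r], analytic, tolerance = 0.02)
  }
  expect_true(all(diff(model$ring_ratio) < 0)) # outer < middle < 1
})

test_that("ring calibration rejects empty rings and orphan seedlings", {
  obs <- data.frame(seedling_id = c(1, 1), radial_px = c(5, 900),
                    perimeter_px = c(100, 130))
  expect_error(fit_ring_calibration(obs, n_rings = 3), "ring 2")
  obs2 <- data.frame(seedling_id = c(1, 1, 2), radial_px = c(5, 500, 600),
                     perimeter_px = c(100, 120, 115))
  expect_warning(m <- fit_ring_calibration(obs2, n_rings = 2),
                 "innermost ring")
  expect_equal(m$ring_ratio[2], 100 / 120)
})

test_that("perimeter correction picks the centroid's ring", {
  obs <- data.frame(seedling_id = 1, radial_px = c(0, 500),
                    perimeter_px = c(100, 125))
  m <- fit_ring_calibration(obs, n_rings = 2, center_px = c(800, 800))
  # at the centre: innermost ratio, unchanged
  expect_equal(correct_perimeter(50, c(800, 800), m), 50)
  # outer ring: 125 px -> 100 px
  expect_equal(correct_perimeter(125, c(800, 1200), m), 100)
  # beyond the outermost edge: outermost ratio plus a warning
  expect_warning(out <- correct_perimeter(100, c(800, 1600), m), "beyond")
  expect_equal(out, 80)
  expect_error(correct_perimeter(-1, c(800, 800), m), "non-negative")
})

test_that("angle smoothing shrinks towards the nearest prior on the circle", {
  expect_equal(smooth_angle(70, lambda = 0), 70)
  expect_equal(smooth_angle(70, lambda = 1), 45)
  expect_equal(smooth_angle(50, lambda = 1), 50)  # inside the 45 +/- 15 band
  expect_equal(smooth_angle(70, lambda = 0.5), 57.5)
  # wrap-aware: 350 degrees is 35 degrees clockwise of the 315 prior
  expect_equal(smooth_angle(350, lambda = 1), 315)
  expect_equal(smooth_angle(5, lambda = 1), 45)
  expect_warning(out <- smooth_angle(123, priors = numeric(0)), "empty")
  expect_equal(out, 123)
  expect_error(smooth_angle(10, lambda = 2), "lambda")
})

test_that("rotation alignment is an exact isometry", {
  expect_equal(as.numeric(rotate_align(data.frame(x = 1, y = 0), 90,
                                       origin = c(0, 0))),
               c(0, 1), tolerance = 1e-12)
  p <- data.frame(x = c(1, 2, 3), y = c(4, 5, 6))
  expect_equal(rotate_align(p, 0), tibble::as_tibble(p), ignore_attr = TRUE)
  set.seed(8)
  poly <- data.frame(x = cumsum(rnorm(50)), y = cumsum(rnorm(50)))
  rot <- rotate_align(poly, 37.3)
  seg <- function(d) sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
  expect_equal(seg(rot), seg(poly), tolerance = 1e-9)
  d0 <- as.matrix(dist(poly)); d1 <- as.matrix(dist(rot))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("tilt factor follows 1/sin with a lower clamp at 30 degrees", {
  expect_equal(tilt_factor(90), 1)
  expect_equal(tilt_factor(45), sqrt(2))
  expect_equal(tilt_factor(10), 2)  # clamped to 30: 1/sin(30)
  expect_equal(tilt_factor(0), tilt_factor(30))
  tt <- seq(30, 90, by = 1)
  expect_true(all(diff(tilt_factor(tt)) < 0))
  expect_true(all(tilt_factor(seq(0, 90, 5)) >= 1))
  expect_error(tilt_factor(95), "90")
})

test_that("age filter applies the 0.4 / 0.6 stage thresholds", {
  d <- data.frame(confidence = c(0.5, 0.5, 1, 0.39, 0.61),
                  age_h = c(40, 80, 80, 10, 80))
  kept <- age_filter(d, cutoff_age_h = 60)
  expect_equal(kept$confidence, c(0.5, 1, 0.61))
  expect_equal(kept$age_h, c(40, 80, 80))
  expect_error(age_filter(data.frame(confidence = 1.5, age_h = 1)), "0, 1")
})

test_that("true length composes distortion, halving, tilt and scale", {
  cfg <- scene_config()
  # perimeter 200 px at the centre, fully in-plane: 100 px * 25/1600 cm
  est <- true_length(200, c(800, 800), 90, model = NULL, config = cfg)
  expect_equal(est$length_cm, 1.5625)
  expect_equal(est$length_px, 100)
  # with a ring model and tilt: each factor enters once
  obs <- data.frame(seedling_id = 1, radial_px = c(0, 500),
                    perimeter_px = c(100, 125))
  m <- fit_ring_calibration(obs, n_rings = 2, center_px = c(800, 800))
  est2 <- true_length(125, c(800, 1200), 45, m, cfg)
  expect_equal(est2$corrected_perimeter_px, 100)
  expect_equal(est2$length_cm, 50 * sqrt(2) * 25 / 1600)
})

test_that("corrected lengths beat uncorrected ones in every outer ring", {
  pool <- fx_validation_pool()
  model <- fx_model()
  edges <- model$ring_edges_px
  for (r in 2:3) {
    in_ring <- pool$radial_px > edges[r] & pool$radial_px <= edges[r + 1]
    expect_gt(sum(in_ring), 3)
    expect_lt(median(abs(pool$err_corrected[in_ring])),
              median(abs(pool$err_uncorrected[in_ring])))
  }
})

test_that("agreement slope matches a normal-equations oracle", {
  expect_equal(agreement_slope(1:10, 1:10)$slope, 1)
  expect_equal(agreement_slope(1:10, 2 * (1:10))$slope, 2)
  set.seed(15)
  manual <- runif(20, 2, 8)
  module <- 0.95 * manual + rnorm(20, 0, 0.05)
  got <- agreement_slope(manual, module)
  # independent closed-form oracle
  sxx <- sum((manual - mean(manual))^2)
  slope_o <- sum((manual - mean(manual)) * (module - mean(module))) / sxx
  inter_o <- mean(module) - slope_o * mean(manual)
  se_o <- sqrt(sum((module - inter_o - slope_o * manual)^2) / 18 / sxx)
  expect_equal(got$slope, slope_o, tolerance = 1e-12)
  expect_equal(got$intercept, inter_o, tolerance = 1e-12)
  expect_lt(abs(got$slope - 0.95), 3 * se_o)
  expect_error(agreement_slope(rep(2, 5), 1:5), "constant")
})

test_that("measurement conserves records through the age filter", {
  run <- fx_pipeline()
  scene <- run$res$scene
  kept <- age_filter(scene$instances, cutoff_age_h = 60)
  expect_equal(nrow(run$res$lengths), nrow(kept))
  expect_equal(run$res$manifest$counts$lengths, nrow(kept))
})
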