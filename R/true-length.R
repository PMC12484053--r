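#' Fit a ring-stratified perimeter-correction model
#'
#' Radial pincushion distortion magnifies objects far from the optical
#' centre, so their mask perimeters are over-measured. This calibrates an
#' empirical correction from repeated captures of the same physical
#' seedlings at different radial distances: observations are stratified into
#' concentric rings around the calibration point, and for each ring the
#' correction is the median, across seedlings, of the ratio (perimeter
#' observed in the innermost ring) / (perimeter observed in that ring). The
#' innermost ratio is 1 by construction; for a pincushion lens outer ratios
#' are below 1. The corrector never assumes knowledge of the lens
#' coefficient - it is purely empirical, anchored at the central seedling.
#'
#' @param observations Data frame with columns `seedling_id`, `radial_px`
#'   and `perimeter_px` (e.g. from [generate_calibration_set()]).
#' @param n_rings Number of equal-width radial rings. Default 3.
#' @param center_px Optical centre; stored for later radial lookups.
#' @param ring_edges_px Optional explicit increasing ring boundaries
#'   (length `n_rings + 1`); defaults to equal widths over
#'   `[0, max(radial_px)]`.
#' @return A `ring_calibration` object: list with `center_px`,
#'   `ring_edges_px`, `ring_ratio` (length `n_rings`), `n_obs` per ring and
#'   the per-seedling ratio table used for the medians.
#' @examples
#' obs <- data.frame(seedling_id = 1, radial_px = c(0, 500),
#'                   perimeter_px = c(100, 125))
#' fit_ring_calibration(obs, n_rings = 2)$ring_ratio # 1, 0.8
#' @export
fit_ring_calibration <- function(observations, n_rings = 3,
                                 center_px = NULL, ring_edges_px = NULL) {
  obs <- as_tibble(observations)
  need <- c("seedling_id", "radial_px", "perimeter_px")
  if (!all(need %in% names(obs))) {
    abort(paste("observations need columns:", paste(need, collapse = ", ")))
  }
  if (any(obs$perimeter_px <= 0)) abort("perimeters must be positive")
  if (is.null(ring_edges_px)) {
    ring_edges_px <- seq(0, max(obs$radial_px) + 1e-9, length.out = n_rings + 1)
  }
  if (any(diff(ring_edges_px) <= 0)) abort("ring edges must be strictly increasing")
  n_rings <- length(ring_edges_px) - 1L

  obs$ring <- findInterval(obs$radial_px, ring_edges_px,
                           rightmost.closed = TRUE, all.inside = TRUE)
  n_obs <- tabulate(obs$ring, nbins = n_rings)
  if (any(n_obs == 0)) {
    abort(sprintf("ring %s has no observations",
                  paste(which(n_obs == 0), collapse = ", ")))
  }

  per_ring <- obs |>
    group_by(.data$seedling_id, .data$ring) |>
    summarise(perimeter_px = mean(.data$perimeter_px), .groups = "drop")
  # the model is anchored at the central calibration point: each seedling's
  # reference is its most central observation within the innermost ring,
  # not the ring average (ring-1 spans a range of radii)
  inner <- obs |>
    filter(.data$ring == 1L) |>
    group_by(.data$seedling_id) |>
    arrange(.data$radial_px, .by_group = TRUE) |>
    summarise(inner_perimeter_px = dplyr::first(.data$perimeter_px),
              .groups = "drop")
  missing_inner <- setdiff(unique(per_ring$seedling_id), inner$seedling_id)
  if (length(missing_inner) > 0) {
    warn(sprintf("%d seedling(s) never observed in the innermost ring; excluded",
                 length(missing_inner)))
  }
  ratios <- per_ring |>
    dplyr::inner_join(inner, by = "seedling_id") |>
    mutate(ratio = .data$inner_perimeter_px / .data$perimeter_px)

  ring_ratio <- rep(NA_real_, n_rings)
  ring_ratio[1] <- 1
  for (r in seq_len(n_rings)[-1]) {
    rr <- ratios$ratio[ratios$ring == r]
    if (length(rr) == 0) abort(sprintf("ring %d has no usable seedling ratios", r))
    ring_ratio[r] <- median(rr)
  }
  structure(list(center_px = center_px, ring_edges_px = ring_edges_px,
                 ring_ratio = ring_ratio, n_obs = n_obs, ratios = ratios),
            class = "ring_calibration")
}

#' @export
print.ring_calibration <- function(x, ...) {
  cat("<ring_calibration>\n")
  for (r in seq_along(x$ring_ratio)) {
    cat(sprintf("  ring %d [%.0f, %.0f) px: ratio %.4f (n = %d)\n", r,
                x$ring_edges_px[r], x$ring_edges_px[r + 1],
                x$ring_ratio[r], x$n_obs[r]))
  }
  invisible(x)
}

#' @describeIn fit_ring_calibration One row per ring: edges, ratio, n.
#' @param x A `ring_calibration`.
#' @param ... Ignored.
#' @export
tidy.ring_calibration <- function(x, ...) {
  tibble(ring = seq_along(x$ring_ratio),
         inner_edge_px = x$ring_edges_px[-length(x$ring_edges_px)],
         outer_edge_px = x$ring_edges_px[-1],
         ring_ratio = x$ring_ratio, n_obs = x$n_obs)
}

#' @describeIn fit_ring_calibration One-row model summary.
#' @export
glance.ring_calibration <- function(x, ...) {
  tibble(n_rings = length(x$ring_ratio), n_obs = sum(x$n_obs),
         outer_ratio = x$ring_ratio[length(x$ring_ratio)])
}

#' @describeIn fit_ring_calibration Ratio-versus-radius diagnostic plot.
#' @param object A `ring_calibration`.
#' @export
autoplot.ring_calibration <- function(object, ...) {
  td <- tidy(object)
  td$mid <- (td$inner_edge_px + td$outer_edge_px) / 2
  ggplot(td, aes(x = .data$mid, y = .data$ring_ratio)) +
    geom_col(width = diff(object$ring_edges_px), alpha = 0.4) +
    geom_point() +
    labs(x = "radial distance (px)", y = "perimeter correction ratio",
         title = "Ring-stratified distortion correction") +
    theme_minimal()
}

#' Correct an observed perimeter for radial lens distortion
#'
#' Multiplies the observed perimeter by the calibrated ratio of the ring
#' containing the instance centroid's radial distance. Centroids beyond the
#' outermost calibrated ring use the outermost ratio, with a warning.
#'
#' @param perimeter_px Observed perimeter(s), px.
#' @param centroid_px Data frame/matrix of centroids with `x`, `y` columns
#'   (one row per perimeter), or a length-2 vector for a single instance.
#' @param model A fitted `ring_calibration`.
#' @param center_px Optical centre; defaults to the model's.
#' @return Corrected perimeter(s) in px.
#' @examples
#' obs <- data.frame(seedling_id = 1, radial_px = c(0, 500),
#'                   perimeter_px = c(100, 125))
#' m <- fit_ring_calibration(obs, n_rings = 2, center_px = c(0, 0))
#' correct_perimeter(125, c(400, 300), m) # 100
#' @export
correct_perimeter <- function(perimeter_px, centroid_px, model,
                              center_px = model$center_px) {
  if (any(perimeter_px < 0)) abort("perimeters must be non-negative")
  if (is.null(center_px)) abort("no optical centre available; supply `center_px`")
  if (is.null(dim(centroid_px)) && length(centroid_px) == 2) {
    centroid_px <- matrix(centroid_px, ncol = 2)
  }
  ctr <- as_xy(centroid_px)
  radial <- sqrt((ctr$x - center_px[1])^2 + (ctr$y - center_px[2])^2)
  edges <- model$ring_edges_px
  n_rings <- length(model$ring_ratio)
  beyond <- radial > edges[length(edges)]
  if (any(beyond)) {
    warn(sprintf("%d centroid(s) beyond the outermost ring; using its ratio",
                 sum(beyond)))
  }
  ring <- pmin(pmax(findInterval(radial, edges, rightmost.closed = TRUE), 1L),
               n_rings)
  perimeter_px * model$ring_ratio[ring]
}

#' Shrink a raw lean azimuth towards the nearest lighting prior
#'
#' Phototropic lean follows the lighting direction, so raw detector angles
#' are smoothed towards the nearest prior azimuth: angles already within the
#' tolerance band of the prior pass through unchanged; outside the band the
#' smoothed angle is `(1 - lambda) * raw + lambda * prior`, computed on the
#' circle (wrap-aware, along the shorter arc).
#'
#' @param raw_azimuth_deg Raw angle(s), degrees clockwise from image-up.
#' @param priors Prior azimuths, degrees. Default `c(45, 135, 225, 315)`.
#' @param lambda Shrinkage weight in `[0, 1]`.
#' @param tolerance_deg Pass-through band half-width. Default 15.
#' @return Smoothed azimuth(s) in `[0, 360)`.
#' @examples
#' smooth_angle(70, lambda = 1) # 45
#' smooth_angle(50, lambda = 1) # 50: within the 45 +/- 15 band
#' @export
smooth_angle <- function(raw_azimuth_deg, priors = c(45, 135, 225, 315),
                         lambda = 0.7, tolerance_deg = 15) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must lie in [0, 1]")
  if (length(priors) == 0) {
    warn("empty prior set: returning raw angles unchanged")
    return(raw_azimuth_deg %% 360)
  }
  vapply(raw_azimuth_deg, function(a) {
    d <- angle_diff(a, priors)
    i <- which.min(abs(d))
    if (abs(d[i]) <= tolerance_deg) return(a %% 360)
    (priors[i] + (1 - lambda) * d[i]) %% 360
  }, numeric(1))
}

#' Tilt foreshortening multiplier
#'
#' A seedling leaning at `tilt_deg` from the vertical appears foreshortened
#' by `sin(tilt)` in a top-down view; the correction multiplier is
#' `1 / sin(tilt)` after clamping the tilt into `[clamp[1], clamp[2]]`.
#' The default lower clamp at 30 degrees caps the amplification at 2 (the
#' measured lighting elevations are 45 +/- 15 degrees, so steeper apparent
#' tilts are treated as angle-estimation noise); a fully in-plane seedling
#' (tilt 90) needs no correction.
#'
#' @param tilt_deg Tilt(s) from vertical, in `[0, 90]`.
#' @param clamp Two-sided clamp on the tilt before inversion.
#'   Default `c(30, 90)`.
#' @return Multiplier(s) `>= 1`.
#' @examples
#' tilt_factor(90) # 1
#' tilt_factor(45) # sqrt(2)
#' tilt_factor(10) # 2: clamped at 30 degrees
#' @export
tilt_factor <- function(tilt_deg, clamp = c(30, 90)) {
  if (any(tilt_deg < 0 | tilt_deg > 90)) abort("`tilt_deg` must lie in [0, 90]")
  t <- pmin(pmax(tilt_deg, clamp[1]), clamp[2])
  1 / sin(t * pi / 180)
}

#' Age-dependent confidence filter
#'
#' Young seedlings (tillering) are kept at a soft confidence threshold of
#' 0.4 so weak shoots are retained; once past `cutoff_age_h` (jointing) the
#' threshold rises to 0.6 to filter noise.
#'
#' @param instances Data frame with `confidence` and `age_h` columns.
#' @param cutoff_age_h Age (h) separating the two stages. Default 60.
#' @param young_threshold,old_threshold Confidence thresholds. Defaults 0.4
#'   and 0.6.
#' @return The retained rows, as a tibble.
#' @examples
#' d <- data.frame(confidence = c(0.5, 0.5, 1), age_h = c(40, 80, 80))
#' nrow(age_filter(d)) # 2
#' @export
age_filter <- function(instances, cutoff_age_h = 60,
                       young_threshold = 0.4, old_threshold = 0.6) {
  inst <- as_tibble(instances)
  if (any(inst$confidence < 0 | inst$confidence > 1)) {
    abort("confidences must lie in [0, 1]")
  }
  thr <- ifelse(inst$age_h < cutoff_age_h, young_threshold, old_threshold)
  inst[inst$confidence >= thr, , drop = FALSE]
}

#' Physical seedling length from a mask perimeter
#'
#' The full length estimate: the observed closed-contour perimeter is
#' distortion-corrected by the ring model, halved (a thin seedling's
#' outline runs up one side and down the other, so its midline length is
#' half the closed perimeter), amplified by the tilt foreshortening factor,
#' and scaled from pixels to centimetres. Composition order is fixed:
#' distortion -> halve -> tilt -> scale.
#'
#' @param perimeter_px Observed perimeter(s), px.
#' @param centroid_px Centroid(s): data frame with `x`, `y` or length-2
#'   vector.
#' @param tilt_deg Tilt(s) from vertical, degrees.
#' @param model A `ring_calibration` (or `NULL` to skip distortion
#'   correction).
#' @param config A [scene_config()] supplying `box_cm` / `frame_px`.
#' @param clamp Tilt clamp, passed to [tilt_factor()].
#' @return Tibble: `perimeter_px`, `corrected_perimeter_px`, `length_px`,
#'   `tilt_factor`, `length_cm`.
#' @examples
#' cfg <- scene_config()
#' true_length(200, c(800, 800), 90, model = NULL, config = cfg)$length_cm
#' # 100 px * 25/1600 = 1.5625 cm
#' @export
true_length <- function(perimeter_px, centroid_px, tilt_deg, model, config,
                        clamp = c(30, 90)) {
  corrected <- if (is.null(model)) {
    perimeter_px
  } else {
    correct_perimeter(perimeter_px, centroid_px, model,
                      center_px = model$center_px %||%
                        rep((config$frame_px - 1) / 2, 2))
  }
  tf <- tilt_factor(tilt_deg, clamp = clamp)
  length_px <- corrected / 2 * tf
  tibble(perimeter_px = perimeter_px,
         corrected_perimeter_px = corrected,
         length_px = length_px,
         tilt_factor = tf,
         length_cm = length_px * config$box_cm / config$frame_px)
}

#' Measure every instance of a synthetic scene
#'
#' Runs the measurement chain on a `seedling_scene`: age/confidence
#' filtering, per-instance contour extraction and perimeter measurement,
#' lighting-prior angle smoothing (diagnostic), then
#' [true_length()] with the given ring calibration. Ground-truth lengths are
#' joined in so recovery error is directly inspectable.
#'
#' @param scene A `seedling_scene` from [generate_scene()].
#' @param model A `ring_calibration`, or `NULL` for no distortion
#'   correction.
#' @param cutoff_age_h,lambda,clamp Filtering/smoothing/tilt parameters.
#' @param filter_age If `FALSE`, measure all instances regardless of
#'   confidence.
#' @return Tibble with one row per retained instance: contour perimeter,
#'   corrected perimeter, smoothed azimuth, estimated and true length, and
#'   the relative error `rel_error`.
#' @export
measure_scene <- function(scene, model = NULL, cutoff_age_h = 60,
                          lambda = 0.7, clamp = c(30, 90),
                          filter_age = TRUE) {
  cfg <- scene$config
  inst <- scene$instances
  if (filter_age) inst <- age_filter(inst, cutoff_age_h = cutoff_age_h)
  if (nrow(inst) == 0) abort("no instances retained by the age filter")
  rows <- vector("list", nrow(inst))
  for (k in seq_len(nrow(inst))) {
    i <- inst$id[k]
    msk <- scene$masks[[i]]
    per <- perimeter(extract_contour(msk$m, i, x0 = msk$x0, y0 = msk$y0))
    est <- true_length(per, c(inst$centroid_x_px[k], inst$centroid_y_px[k]),
                       inst$tilt_deg[k], model, cfg, clamp = clamp)
    rows[[k]] <- mutate(est, id = i,
                        smoothed_azimuth_deg = smooth_angle(
                          inst$azimuth_deg[k], cfg$lighting_azimuths_deg,
                          lambda = lambda,
                          tolerance_deg = cfg$lighting_tolerance_deg),
                        tilt_deg = inst$tilt_deg[k],
                        radial_px = sqrt(
                          (inst$centroid_x_px[k] - (cfg$frame_px - 1) / 2)^2 +
                          (inst$centroid_y_px[k] - (cfg$frame_px - 1) / 2)^2),
                        true_length_cm = inst$length_cm[k])
  }
  bind_rows(rows) |>
    mutate(rel_error = (.data$length_cm - .data$true_length_cm) /
             .data$true_length_cm) |>
    select("id", "perimeter_px", "corrected_perimeter_px", "length_px",
           "tilt_deg", "tilt_factor", "smoothed_azimuth_deg", "radial_px",
           "length_cm", "true_length_cm", "rel_error")
}

#' Agreement slope between manual and module measurements
#'
#' Ordinary least-squares regression of the module's lengths on the manual
#' (reference) lengths; a slope near 1 indicates agreement.
#'
#' @param manual_cm,module_cm Paired length measurements (cm), at least 2
#'   pairs with non-degenerate manual variance.
#' @return Tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' agreement_slope(1:10, 2 * (1:10))$slope # 2
#' @export
agreement_slope <- function(manual_cm, module_cm) {
  if (length(manual_cm) != length(module_cm) || length(manual_cm) < 2) {
    abort("need >= 2 paired measurements")
  }
  if (stats::var(manual_cm) < .Machine$double.eps) {
    abort("manual measurements are constant: slope undefined")
  }
  fit <- lm(module_cm ~ manual_cm)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((module_cm - mean(module_cm))^2)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = length(manual_cm))
}
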