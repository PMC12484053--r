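#' Sample ground-truth seedlings for a scene
#'
#' Draws one seedling per grid cell with the geometry the imaging rig
#' produces: midlines are gently bent quadratic Bezier curves; each seedling
#' leans phototropically towards the nearest corner light, so its azimuth is
#' that light's prior plus uniform noise within the tolerance band; tilt
#' from vertical is uniform on \[30, 60\] degrees (the measured lighting
#' elevation band); lengths are uniform on 12.8-15.2% of the box side
#' (3.2-3.8 cm in the default 25 cm box); detection confidences are uniform
#' on \[0.45, 1\] and ages uniform over the second half of the horizon. The
#' planting grid is inset 16% of the box side from the walls so leaning
#' shoots stay inside the frame.
#'
#' @param config A [scene_config()].
#' @param width_px Stroke width of the rasterised seedling in px. Default 3.
#' @return Tibble of ground truth, one row per seedling: `id`, `row`, `col`,
#'   `base_x_cm`, `base_y_cm`, `length_cm`, `bend`, `azimuth_deg`,
#'   `tilt_deg`, `confidence`, `age_h`, `width_px`.
#' @export
sample_seedlings <- function(config, width_px = 3) {
  set.seed(config$seed)
  g <- config$grid
  margin <- 0.16 * config$box_cm
  pitch <- (config$box_cm - 2 * margin) / g
  cells <- expand.grid(row = seq_len(g), col = seq_len(g))
  base_x <- margin + (cells$col - 0.5) * pitch
  base_y <- margin + (cells$row - 0.5) * pitch

  ctr <- config$box_cm / 2
  pos_az <- (atan2(base_x - ctr, -(base_y - ctr)) * 180 / pi) %% 360
  nearest_prior <- vapply(pos_az, function(a) {
    pri <- config$lighting_azimuths_deg
    pri[which.min(abs(angle_diff(a, pri)))]
  }, numeric(1))

  n <- nrow(cells)
  placed <- vector("list", n)
  accepted_pts <- NULL
  for (i in seq_len(n)) {
    draw <- function(shrink) tibble(
      id = i, row = cells$row[i], col = cells$col[i],
      base_x_cm = base_x[i] + runif(1, -0.004, 0.004) * config$box_cm,
      base_y_cm = base_y[i] + runif(1, -0.004, 0.004) * config$box_cm,
      length_cm = runif(1, 0.128, 0.152) * config$box_cm * shrink,
      bend = runif(1, -0.12, 0.12),
      azimuth_deg = (nearest_prior[i] +
        runif(1, -config$lighting_tolerance_deg,
              config$lighting_tolerance_deg)) %% 360,
      tilt_deg = runif(1, 30, 60),
      confidence = runif(1, 0.45, 1),
      age_h = runif(1, config$horizon_h / 2, config$horizon_h),
      width_px = width_px)
    res <- place_clear(draw, accepted_pts, config, width_px)
    placed[[i]] <- res$seedling
    accepted_pts <- rbind(accepted_pts, res$pts)
  }
  bind_rows(placed)
}

# Redraw a seedling's pose until its (warped) midline keeps a safe distance
# from everything already placed and stays inside the frame; after repeated
# failures the length is shrunk. Deterministic under the caller's RNG state.
place_clear <- function(draw, accepted_pts, config, width_px,
                        n_try = 30L, margin_px = 4) {
  shrink <- 1
  for (attempt in seq_len(8L * n_try)) {
    if (attempt %% n_try == 0L) shrink <- shrink * 0.85
    s <- draw(shrink)
    mid <- seedling_midline_px(s$base_x_cm, s$base_y_cm, s$length_cm,
                               s$bend, s$azimuth_deg, s$tilt_deg, config)
    if (config$k1 > 0) {
      w <- apply_pincushion(data.frame(x = mid[, 1], y = mid[, 2]),
                            config$k1, rep((config$frame_px - 1) / 2, 2),
                            config$frame_px)
      mid <- cbind(w$x, w$y)
    }
    inside <- all(mid >= width_px + 1) && all(mid <= config$frame_px - width_px - 2)
    if (!inside) next
    clear <- is.null(accepted_pts) ||
      min_cross_dist2(mid, accepted_pts) > (width_px + margin_px)^2
    if (clear) {
      thin <- mid[seq(1, nrow(mid), by = 2), , drop = FALSE]
      return(list(seedling = s, pts = thin))
    }
  }
  abort("could not place a seedling without collision; box too crowded")
}

# squared minimum distance between two point sets (n x 2 matrices)
min_cross_dist2 <- function(a, b) {
  min(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
}

#' Radial-sweep layout for validating the distortion correction
#'
#' Places `n` long seedlings along rays near the frame diagonals, at base
#' radii sweeping from the centre to the frame corner, each leaning
#' phototropically towards its nearest corner light. This is the natural
#' layout for exercising a radial distortion model: instances cover the
#' full radial range (so every calibration ring is populated) while staying
#' comfortably non-overlapping, and their lengths (5.5-6.5 cm at the
#' default 25 cm box) are long enough that raster end-cap effects are small
#' against the distortion signal.
#'
#' @param config A [scene_config()]; `config$seed` drives the sampling.
#' @param n Number of seedlings. Default 16.
#' @param length_range_cm Length range, cm (scaled by `box_cm / 25`).
#' @param width_px Stroke width, px. Default 3.
#' @return Ground-truth tibble accepted by [generate_scene()].
#' @export
validation_layout <- function(config, n = 16,
                              length_range_cm = c(5.5, 6.5) * config$box_cm / 25,
                              width_px = 3) {
  set.seed(config$seed)
  half <- (config$frame_px - 1) / 2
  sc <- config$frame_px / config$box_cm
  # four diagonal rays towards the corner lights; same-ray seedlings are
  # staggered laterally, and every placement is redrawn until it keeps a
  # safe distance from the strokes already accepted
  rays <- c(45, 135, 225, 315)
  out <- vector("list", n)
  accepted_pts <- NULL
  for (i in seq_len(n)) {
    ray <- rays[(i - 1L) %% length(rays) + 1L]
    frac <- i / n
    base_r_px <- frac * 0.34 * config$frame_px
    lateral <- 0.034 * config$frame_px *
      c(1, -1, 2, -2)[((i - 1L) %/% length(rays)) %% 4L + 1L]
    u <- azimuth_dir(ray)
    v <- c(-u[2], u[1]) # perpendicular
    base_x_cm <- (half + base_r_px * u[1] + lateral * v[1] + 0.5) / sc
    base_y_cm <- (half + base_r_px * u[2] + lateral * v[2] + 0.5) / sc
    prior <- config$lighting_azimuths_deg[
      which.min(abs(angle_diff(ray, config$lighting_azimuths_deg)))]
    draw <- function(shrink) tibble(
      id = i, row = NA_integer_, col = NA_integer_,
      base_x_cm = base_x_cm + runif(1, -0.016, 0.016) * config$box_cm,
      base_y_cm = base_y_cm + runif(1, -0.016, 0.016) * config$box_cm,
      length_cm = runif(1, length_range_cm[1], length_range_cm[2]) * shrink,
      bend = runif(1, -0.1, 0.1),
      azimuth_deg = (prior + runif(1, -config$lighting_tolerance_deg,
                                   config$lighting_tolerance_deg)) %% 360,
      tilt_deg = runif(1, 30, 60),
      confidence = runif(1, 0.62, 1),
      age_h = runif(1, config$horizon_h / 2, config$horizon_h),
      width_px = width_px)
    res <- place_clear(draw, accepted_pts, config, width_px)
    out[[i]] <- res$seedling
    accepted_pts <- rbind(accepted_pts, res$pts)
  }
  bind_rows(out)
}

# Midline of one seedling in px coordinates (pincushion NOT yet applied).
# Upright local shape: quadratic Bezier from the base towards image-up with
# lateral bend, rescaled to exact arc length, foreshortened by sin(tilt)
# (top-down projection), rotated to the lean azimuth, then placed at the
# base and converted cm -> px (pixel centres at integers: px = cm*s - 0.5).
seedling_midline_px <- function(base_x_cm, base_y_cm, length_cm, bend,
                                azimuth_deg, tilt_deg, config, n = 120) {
  xy <- bezier_points(c(0, 0), c(bend * length_cm, -length_cm / 2),
                      c(0, -length_cm), n = n)
  xy <- xy * (length_cm / polyline_length(xy)) # exact arc length
  xy <- xy * sin(tilt_deg * pi / 180)          # top-down foreshortening
  rot <- rotate_align(data.frame(x = xy[, 1], y = xy[, 2]),
                      azimuth_deg, origin = c(0, 0))
  s <- config$frame_px / config$box_cm
  cbind((rot$x + base_x_cm) * s - 0.5, (rot$y + base_y_cm) * s - 0.5)
}

# Stroke radius profile: width_px/2 in the middle, tapering linearly to
# width_px/4 over the terminal 15% at both ends (seedlings thin out at the
# soil line and at the tip; narrow end caps keep the half-perimeter length
# rule nearly unbiased). The minimum radius stays above sqrt(2)/2 px for the
# default width so rasterised tips remain 8-connected at any lean angle.
taper_radius <- function(n, width_px) {
  s <- seq(0, 1, length.out = n)
  ramp <- pmin(1, pmin(s, 1 - s) / 0.15)
  (width_px / 4) + (width_px / 2 - width_px / 4) * ramp
}

#' Generate a synthetic seedling scene with exact ground truth
#'
#' Rasterises each seedling midline (foreshortened by tilt, rotated to its
#' lean azimuth, warped by the pincushion model) as a tapered stroke into a
#' per-instance soft coverage mask and a combined integer label image.
#' Instances whose binary footprints would overlap raise an error (the grid
#' layout is chosen so they never do at the defaults).
#'
#' @param config A [scene_config()]; `config$seed` drives all sampling.
#' @param seedlings Optional ground-truth tibble as produced by
#'   [sample_seedlings()]; sampled from the config when `NULL`. An empty
#'   tibble yields an empty label image.
#' @return A `seedling_scene`: list with `config`, `instances` (ground truth
#'   plus measured coverage-weighted centroids `centroid_x_px`,
#'   `centroid_y_px`), `masks` (per-instance list of `x0`, `y0`, `m`), and
#'   `label` (integer matrix, 0 background, k = instance k).
#' @examples
#' cfg <- scene_config(frame_px = 400, grid = 2, seed = 7)
#' sc <- generate_scene(cfg)
#' table(sc$label > 0)
#' @export
generate_scene <- function(config, seedlings = NULL) {
  validate_scene_config(config)
  if (is.null(seedlings)) seedlings <- sample_seedlings(config)
  label <- matrix(0L, config$frame_px, config$frame_px)
  masks <- vector("list", nrow(seedlings))
  cx <- cy <- rep(NA_real_, nrow(seedlings))
  if (nrow(seedlings) > 0) {
    center <- rep((config$frame_px - 1) / 2, 2)
    for (i in seq_len(nrow(seedlings))) {
      s <- seedlings[i, ]
      mid <- seedling_midline_px(s$base_x_cm, s$base_y_cm, s$length_cm,
                                 s$bend, s$azimuth_deg, s$tilt_deg, config)
      if (config$k1 > 0) {
        w <- apply_pincushion(data.frame(x = mid[, 1], y = mid[, 2]),
                              config$k1, center, config$frame_px)
        mid <- cbind(w$x, w$y)
      }
      r <- taper_radius(nrow(mid), s$width_px)
      msk <- rasterize_stroke(mid, r, config$frame_px)
      masks[[i]] <- msk
      fg <- which(msk$m >= 0.5, arr.ind = TRUE)
      if (nrow(fg) == 0) abort(sprintf("instance %d rasterised to nothing", s$id))
      rows <- fg[, 1] + msk$y0  # label row index = y + 1 (y0 is 0-based)
      cols <- fg[, 2] + msk$x0
      idx <- cbind(rows, cols)
      if (any(label[idx] != 0L)) {
        abort(sprintf("instance %d overlaps instance %d in the label image",
                      s$id, label[idx][label[idx] != 0L][1]))
      }
      label[idx] <- as.integer(s$id)
      wsum <- sum(msk$m)
      cx[i] <- sum(msk$m * matrix(msk$x0 + seq_len(ncol(msk$m)) - 1L,
                                  nrow(msk$m), ncol(msk$m), byrow = TRUE)) / wsum
      cy[i] <- sum(msk$m * matrix(msk$y0 + seq_len(nrow(msk$m)) - 1L,
                                  nrow(msk$m), ncol(msk$m))) / wsum
    }
  }
  instances <- mutate(seedlings, centroid_x_px = cx, centroid_y_px = cy)
  structure(list(config = config, instances = instances,
                 masks = masks, label = label),
            class = "seedling_scene")
}

#' @export
print.seedling_scene <- function(x, ...) {
  cat(sprintf("<seedling_scene> %d instances on a %d px frame (k1 = %g)\n",
              nrow(x$instances), x$config$frame_px, x$config$k1))
  invisible(x)
}

#' @describeIn generate_scene Raster plot of the label image.
#' @param object,... `seedling_scene` and ignored extra arguments.
#' @export
autoplot.seedling_scene <- function(object, ...) {
  lab <- object$label
  fg <- which(lab > 0, arr.ind = TRUE)
  df <- tibble(x = fg[, 2] - 1, y = fg[, 1] - 1,
               instance = factor(lab[fg]))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$instance)) +
    geom_raster(show.legend = FALSE) +
    scale_y_reverse() + coord_equal() +
    labs(x = "x (px)", y = "y (px)",
         title = "Synthetic seedling scene (instance labels)") +
    theme_minimal()
}

#' Simulate the ring-calibration capture protocol
#'
#' Emulates re-photographing the growth box so that the same physical
#' seedling appears at different radial distances from the optical centre:
#' each of `n_groups` calibration seedlings is rasterised once at the frame
#' centre (the calibration point) and then at increasing radial offsets, the
#' pincushion warp applied each time, and the mask perimeter measured from
#' the traced contour. Offsets are integer-pixel so that with `k1 = 0` every
#' observation of a seedling reproduces its reference perimeter exactly.
#'
#' @param config A [scene_config()].
#' @param n_groups Number of calibration seedlings (capture groups).
#'   Default 20.
#' @param images_per_group Images per group, the first at the centre.
#'   Default 7.
#' @param width_px Stroke width in px. Default 3.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return Tibble with one row per image: `group`, `image`, `seedling_id`,
#'   `radial_px` (measured centroid distance from the optical centre),
#'   `perimeter_px` (observed, distorted), `true_perimeter_px` (undistorted
#'   reference for the same seedling).
#' @examples
#' cal <- generate_calibration_set(scene_config(frame_px = 400, seed = 3),
#'                                 n_groups = 2)
#' nrow(cal) # 2 * 7
#' @export
generate_calibration_set <- function(config, n_groups = 20,
                                     images_per_group = 7, width_px = 3,
                                     seed = config$seed + 1) {
  validate_scene_config(config)
  if (n_groups < 1) abort("`n_groups` must be >= 1")
  set.seed(seed)
  center <- rep((config$frame_px - 1) / 2, 2)
  sc <- config$frame_px / config$box_cm
  rows <- vector("list", n_groups * images_per_group)
  k <- 0L
  for (g in seq_len(n_groups)) {
    length_cm <- runif(1, 0.128, 0.152) * config$box_cm
    bend <- runif(1, -0.12, 0.12)
    azimuth <- (sample(config$lighting_azimuths_deg, 1) +
                  runif(1, -config$lighting_tolerance_deg,
                        config$lighting_tolerance_deg)) %% 360
    tilt <- runif(1, 30, 60)
    # midline with its centroid at the origin, in px
    mid <- seedling_midline_px(0, 0, length_cm, bend, azimuth, tilt, config)
    mid[, 1] <- mid[, 1] - mean(mid[, 1])
    mid[, 2] <- mid[, 2] - mean(mid[, 2])
    half_ext <- max(sqrt(mid[, 1]^2 + mid[, 2]^2)) + width_px
    r_prof <- taper_radius(nrow(mid), width_px)

    # undistorted reference perimeter, measured once at the centre
    ref <- rasterize_stroke(cbind(mid[, 1] + center[1], mid[, 2] + center[2]),
                            r_prof, config$frame_px)
    true_per <- perimeter(extract_contour(ref$m, g, x0 = ref$x0, y0 = ref$y0))

    # the box is slid along the seedling's lean azimuth between captures, so
    # the stroke keeps the same pose relative to the radial direction while
    # sweeping the radii (this is also how the measured seedlings lean:
    # towards the corner lights, i.e. roughly radially)
    u <- azimuth_dir(azimuth)
    # largest centroid radius along u keeping the whole stroke in frame
    lim <- function(ci, ui) {
      if (abs(ui) < 1e-12) return(Inf)
      if (ui > 0) (config$frame_px - 3 - half_ext - ci) / ui
      else (2 + half_ext - ci) / ui
    }
    r_edge <- min(lim(center[1], u[1]), lim(center[2], u[2]))
    # the pincushion warp pushes points outward: shrink by the warp factor
    # at the outermost reach so the distorted stroke stays in frame
    r_norm <- (r_edge + half_ext) / (config$frame_px * sqrt(2) / 2)
    r_edge <- r_edge / (1 + config$k1 * r_norm^2)
    # calibrate over the radial range planted seedlings actually occupy
    # (the grid is inset from the box walls); extrapolating the ring model
    # beyond the measurement domain would be uninformative
    r_edge <- min(r_edge, 0.47 * config$frame_px)
    for (j in seq_len(images_per_group)) {
      frac <- (j - 1) / max(1, images_per_group - 1)
      offset <- round(frac * r_edge * u) # integer-px translation
      pts <- cbind(mid[, 1] + center[1] + offset[1],
                   mid[, 2] + center[2] + offset[2])
      if (config$k1 > 0) {
        wp <- apply_pincushion(data.frame(x = pts[, 1], y = pts[, 2]),
                               config$k1, center, config$frame_px)
        pts <- cbind(wp$x, wp$y)
      }
      msk <- rasterize_stroke(pts, r_prof, config$frame_px)
      per <- perimeter(extract_contour(msk$m, g, x0 = msk$x0, y0 = msk$y0))
      wsum <- sum(msk$m)
      cxx <- sum(msk$m * matrix(msk$x0 + seq_len(ncol(msk$m)) - 1L,
                                nrow(msk$m), ncol(msk$m), byrow = TRUE)) / wsum
      cyy <- sum(msk$m * matrix(msk$y0 + seq_len(nrow(msk$m)) - 1L,
                                nrow(msk$m), ncol(msk$m))) / wsum
      k <- k + 1L
      rows[[k]] <- tibble(group = g, image = j, seedling_id = g,
                          radial_px = sqrt((cxx - center[1])^2 +
                                             (cyy - center[2])^2),
                          perimeter_px = per, true_perimeter_px = true_per)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) != n_groups * images_per_group) {
    abort("calibration record count does not match n_groups * images_per_group")
  }
  out
}

#' Generate synthetic growth series for the full treatment design
#'
#' For every (salt, fe) cell the noise-free length follows the linear model
#' `L(t) = base_rate * salt_multiplier[salt] * fe_multiplier[fe, salt] * t`,
#' observed on the capture grid `t = 0, interval, ...` up to the horizon,
#' with additive Gaussian measurement noise and clipping at zero.
#'
#' @param design A [treatment_design()].
#' @param config A [scene_config()] supplying the capture interval and
#'   horizon.
#' @param seed Integer RNG seed for the noise.
#' @param replicates Series per treatment cell. Default 1.
#' @return Tibble: `salt_mmolL`, `fe_mgL`, `replicate`, `t_min`,
#'   `length_cm`, plus the ground-truth `rate_cm_per_h`.
#' @examples
#' gs <- generate_growth_series(treatment_design(), scene_config(), seed = 1)
#' length(unique(gs$t_min)) # 109 time points over 90 h at 50-min spacing
#' @export
generate_growth_series <- function(design, config, seed = 1L,
                                   replicates = 1L) {
  validate_treatment_design(design)
  validate_scene_config(config)
  t_min <- seq(0, config$horizon_h * 60, by = config$capture_interval_min)
  if (length(t_min) < 2) abort("horizon/interval must yield >= 2 time points")
  set.seed(seed)
  cells <- expand.grid(fe_mgL = design$fe_levels_mgL,
                       salt_mmolL = design$salt_levels_mmolL,
                       replicate = seq_len(replicates))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    fe <- as.character(cells$fe_mgL[i])
    salt <- as.character(cells$salt_mmolL[i])
    rate <- design$base_rate_cm_per_h * design$salt_multiplier[[salt]] *
      design$fe_multiplier[fe, salt]
    if (rate < 0) abort("negative growth rate in design")
    noise <- if (design$noise_sd_cm > 0) {
      rnorm(length(t_min), 0, design$noise_sd_cm)
    } else 0
    out[[i]] <- tibble(
      salt_mmolL = cells$salt_mmolL[i], fe_mgL = cells$fe_mgL[i],
      replicate = cells$replicate[i], t_min = t_min,
      length_cm = pmax(0, rate * t_min / 60 + noise),
      rate_cm_per_h = rate)
  }
  bind_rows(out)
}

#' Write a scene to disk as a label PNG plus ground-truth CSV
#'
#' The label image is written as an 8-bit grayscale PNG whose pixel value is
#' the instance id (0 = background; at most 255 instances). The ground truth
#' table drops list columns and is written as CSV.
#'
#' @param scene A `seedling_scene`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (max(scene$label) > 255) abort("more than 255 instances: cannot write 8-bit labels")
  png_path <- file.path(dir, "label.png")
  png::writePNG(scene$label / 255, png_path)
  csv_path <- file.path(dir, "ground_truth.csv")
  gt <- select(scene$instances, "id", "row", "col", "true_length_cm" = "length_cm",
               "azimuth_deg", "tilt_deg", "confidence", "age_h")
  readr::write_csv(gt, csv_path)
  invisible(c(png_path, csv_path))
}

#' Read a label image written by [write_scene()]
#'
#' @param path Path to an 8-bit grayscale label PNG.
#' @return Integer matrix of instance labels.
#' @export
read_label_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
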