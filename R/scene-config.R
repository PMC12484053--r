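#' Geometry, optics and timing of the virtual imaging rig
#'
#' Bundles the physical constants the synthetic scenes and the length
#' conversion assume: a square camera frame of `frame_px` pixels imaging a
#' square growth box of `box_cm` centimetres from directly above, seedlings
#' planted on a `grid` x `grid` lattice, a single-coefficient radial
#' (pincushion) distortion `k1`, the four corner lighting azimuths that drive
#' phototropic lean, and the capture cadence of the time series.
#'
#' The defaults mirror the reference rig: a 1600 px frame over a 25 cm x
#' 25 cm box (64 px/cm), a 7 x 7 planting grid, lighting at 45/135/225/315
#' degrees with a +/-15 degree tolerance band, and 90 h of observation
#' sampled every 50 minutes.
#'
#' @param frame_px Integer, pixels per frame side. Default 1600.
#' @param box_cm Physical box side in cm. Default 25.
#' @param grid Seedlings per row/column. Default 7.
#' @param k1 Radial pincushion coefficient (dimensionless, >= 0), applied as
#'   `p -> center + d * (1 + k1 * r^2)` with `r = |d| /` (half frame
#'   diagonal). Default 0.08.
#' @param lighting_azimuths_deg Prior lean azimuths in degrees clockwise from
#'   image-up. Default `c(45, 135, 225, 315)`.
#' @param lighting_tolerance_deg Half-width of the tolerance band around each
#'   prior. Default 15.
#' @param capture_interval_min Minutes between captures. Default 50.
#' @param horizon_h Observation horizon in hours. Default 90.
#' @param seed Integer RNG seed attached to the config. Default 1.
#'
#' @return An object of class `scene_config` (a validated named list).
#' @examples
#' cfg <- scene_config()
#' cfg$frame_px / cfg$box_cm # 64 px per cm
#' @export
scene_config <- function(frame_px = 1600L, box_cm = 25, grid = 7L, k1 = 0.08,
                         lighting_azimuths_deg = c(45, 135, 225, 315),
                         lighting_tolerance_deg = 15,
                         capture_interval_min = 50, horizon_h = 90,
                         seed = 1L) {
  cfg <- list(
    frame_px = as.integer(frame_px), box_cm = as.numeric(box_cm),
    grid = as.integer(grid), k1 = as.numeric(k1),
    lighting_azimuths_deg = as.numeric(lighting_azimuths_deg),
    lighting_tolerance_deg = as.numeric(lighting_tolerance_deg),
    capture_interval_min = as.numeric(capture_interval_min),
    horizon_h = as.numeric(horizon_h), seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!isTRUE(cfg$frame_px > 0)) abort("`frame_px` must be a positive integer.")
  if (!isTRUE(cfg$box_cm > 0)) abort("`box_cm` must be positive.")
  if (!isTRUE(cfg$grid >= 1)) abort("`grid` must be >= 1.")
  if (!isTRUE(cfg$k1 >= 0)) abort("`k1` must be >= 0.")
  if (!isTRUE(cfg$capture_interval_min > 0) ||
      !isTRUE(cfg$capture_interval_min <= cfg$horizon_h * 60)) {
    abort("`capture_interval_min` must lie in (0, horizon_h * 60].")
  }
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  frame: %d px | box: %g cm (%.3g px/cm) | grid: %dx%d\n",
              x$frame_px, x$box_cm, x$frame_px / x$box_cm, x$grid, x$grid))
  cat(sprintf("  pincushion k1: %g | lighting: %s deg (+/- %g)\n",
              x$k1, paste(x$lighting_azimuths_deg, collapse = "/"),
              x$lighting_tolerance_deg))
  cat(sprintf("  captures: every %g min over %g h | seed: %d\n",
              x$capture_interval_min, x$horizon_h, x$seed))
  invisible(x)
}

#' Treatment design of the salt-stress x nano-iron priming experiment
#'
#' Describes the 6 x 6 factorial (NaCl concentration x nano-iron oxide
#' priming concentration) and the linear growth model the synthetic series
#' follow: `length(t) = base_rate * salt_multiplier[salt] *
#' fe_multiplier[fe, salt] * t + noise`, clipped at zero.
#'
#' The default multipliers encode the qualitative structure of the study
#' system: growth declines monotonically with salinity; the untreated control
#' does not grow at all at 150 mmol/L; and averaged across salt levels the
#' 300 mg/L priming has the strongest effect, followed by 20, 50, 100 and
#' 200 mg/L.
#'
#' @param salt_levels_mmolL NaCl levels (mmol/L). Default
#'   `c(0, 30, 60, 90, 120, 150)`.
#' @param fe_levels_mgL Nano-iron oxide priming levels (mg/L). Default
#'   `c(0, 20, 50, 100, 200, 300)`.
#' @param base_rate_cm_per_h Baseline elongation rate (cm/h) of an unstressed,
#'   unprimed seedling. Default 0.06.
#' @param salt_multiplier Named numeric in `[0, 1]`, one entry per salt level.
#' @param fe_multiplier Numeric matrix `length(fe) x length(salt)` of positive
#'   relief factors (dimnames = fe, salt levels). The default is constant per
#'   fe level except that the (fe = 0, salt = 150) cell is 0.
#' @param noise_sd_cm Gaussian measurement noise sd in cm. Default 0.05.
#'
#' @return An object of class `treatment_design`.
#' @examples
#' des <- treatment_design()
#' des$fe_multiplier["300", ]
#' @export
treatment_design <- function(salt_levels_mmolL = c(0, 30, 60, 90, 120, 150),
                             fe_levels_mgL = c(0, 20, 50, 100, 200, 300),
                             base_rate_cm_per_h = 0.06,
                             salt_multiplier = NULL,
                             fe_multiplier = NULL,
                             noise_sd_cm = 0.05) {
  salt_chr <- as.character(salt_levels_mmolL)
  fe_chr <- as.character(fe_levels_mgL)
  if (is.null(salt_multiplier)) {
    salt_multiplier <- setNames(
      seq(1, 0.15, length.out = length(salt_levels_mmolL)), salt_chr)
    if (length(salt_levels_mmolL) == 6) {
      salt_multiplier <- setNames(c(1, 0.85, 0.65, 0.45, 0.30, 0.15), salt_chr)
    }
  }
  if (is.null(fe_multiplier)) {
    relief <- c(1, 1.30, 1.16, 1.12, 1.05, 1.38)[seq_along(fe_levels_mgL)]
    relief[is.na(relief)] <- 1
    fe_multiplier <- matrix(relief, nrow = length(fe_chr),
                            ncol = length(salt_chr),
                            dimnames = list(fe_chr, salt_chr))
    # untreated control shows no growth at the harshest salinity
    if ("0" %in% fe_chr && "150" %in% salt_chr) fe_multiplier["0", "150"] <- 0
  }
  des <- list(
    salt_levels_mmolL = as.numeric(salt_levels_mmolL),
    fe_levels_mgL = as.numeric(fe_levels_mgL),
    base_rate_cm_per_h = as.numeric(base_rate_cm_per_h),
    salt_multiplier = salt_multiplier,
    fe_multiplier = fe_multiplier,
    noise_sd_cm = as.numeric(noise_sd_cm)
  )
  validate_treatment_design(des)
  structure(des, class = "treatment_design")
}

validate_treatment_design <- function(des) {
  if (des$base_rate_cm_per_h < 0) abort("`base_rate_cm_per_h` must be >= 0.")
  if (any(des$salt_multiplier < 0 | des$salt_multiplier > 1)) {
    abort("`salt_multiplier` entries must lie in [0, 1].")
  }
  if (any(des$fe_multiplier < 0)) abort("`fe_multiplier` must be >= 0.")
  if (!identical(dim(des$fe_multiplier),
                 c(length(des$fe_levels_mgL), length(des$salt_levels_mmolL)))) {
    abort("`fe_multiplier` must be a fe-by-salt matrix.")
  }
  if (des$noise_sd_cm < 0) abort("`noise_sd_cm` must be >= 0.")
  invisible(des)
}

#' @export
print.treatment_design <- function(x, ...) {
  cat("<treatment_design>\n")
  cat(sprintf("  salt (mmol/L): %s\n  fe (mg/L): %s\n",
              paste(x$salt_levels_mmolL, collapse = ", "),
              paste(x$fe_levels_mgL, collapse = ", ")))
  cat(sprintf("  base rate: %g cm/h | noise sd: %g cm\n",
              x$base_rate_cm_per_h, x$noise_sd_cm))
  invisible(x)
}
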