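# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_config <- function() scene_config(seed = 11)

fx_calibration <- function() {
  fixture("calibration", generate_calibration_set(fx_config()))
}

fx_model <- function() {
  fixture("model", fit_ring_calibration(
    fx_calibration(), n_rings = 3,
    center_px = rep((fx_config()$frame_px - 1) / 2, 2)))
}

# Radial-sweep validation scenes (three seeds pooled): corrected and
# uncorrected measurements of long seedlings spanning the radial range.
fx_validation_pool <- function() {
  fixture("validation_pool", {
    model <- fx_model()
    dplyr::bind_rows(lapply(c(11, 12, 13), function(s) {
      cfg <- scene_config(seed = s)
      sc <- generate_scene(cfg, validation_layout(cfg))
      corrected <- measure_scene(sc, model, filter_age = FALSE)
      uncorrected <- measure_scene(sc, NULL, filter_age = FALSE)
      dplyr::tibble(seed = s, radial_px = corrected$radial_px,
                    tilt_deg = corrected$tilt_deg,
                    err_corrected = corrected$rel_error,
                    err_uncorrected = uncorrected$rel_error)
    }))
  })
}

# One default pipeline run (seed 3) shared by the pipeline-level tests.
fx_pipeline <- function() {
  fixture("pipeline", {
    dir <- file.path(tempdir(), "svig-fixture-run")
    res <- run_pipeline(run_config(seed = 3L), dir)
    list(dir = dir, res = res)
  })
}

# A small random soft blob on an n x n grid with at least one foreground
# pixel: smoothed uniform noise, rescaled.
random_blob <- function(n = 48) {
  z <- matrix(runif(n * n), n, n)
  k <- 5
  sm <- matrix(0, n, n)
  for (dx in -2:2) for (dy in -2:2) {
    sm <- sm + z[pmin(pmax(1:n + dx, 1), n), pmin(pmax(1:n + dy, 1), n)]
  }
  sm <- sm / 25
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  if (!any(sm >= 0.5)) sm[n %/% 2, n %/% 2] <- 1
  sm
}
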