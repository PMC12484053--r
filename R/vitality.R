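#' Fit a linear growth rate to a length time series
#'
#' Ordinary least squares of length (cm) on time, with the slope reported
#' per hour. This is the "dynamic vitality" of a treatment group: growth
#' increment per unit time.
#'
#' @param series Data frame with `t_min` and `length_cm` columns (one
#'   treatment group; replicates may be pooled).
#' @return Tibble: `slope_cm_per_h`, `intercept_cm`, `se_slope_cm_per_h`,
#'   `n_obs`.
#' @examples
#' s <- data.frame(t_min = 0:10 * 60, length_cm = 0.04 * (0:10) + 0.1)
#' fit_growth_rate(s) # slope 0.04, intercept 0.1
#' @export
fit_growth_rate <- function(series) {
  s <- as_tibble(series)
  if (nrow(s) < 2) abort("need at least 2 observations")
  t_h <- s$t_min / 60
  if (length(unique(t_h)) < 2) abort("all time points identical: slope undefined")
  tm <- t_h - mean(t_h)
  sxx <- sum(tm^2)
  slope <- sum(tm * s$length_cm) / sxx
  intercept <- mean(s$length_cm) - slope * mean(t_h)
  res <- s$length_cm - intercept - slope * t_h
  se <- if (nrow(s) > 2) sqrt(sum(res^2) / (nrow(s) - 2) / sxx) else NA_real_
  tibble(slope_cm_per_h = slope, intercept_cm = intercept,
         se_slope_cm_per_h = se, n_obs = nrow(s))
}

#' Mean seedling length of a series (static vitality)
#'
#' @param series Data frame with a `length_cm` column, or a numeric vector
#'   of lengths.
#' @return Arithmetic mean length in cm.
#' @examples
#' static_vitality(c(1, 2, 3)) # 2
#' @export
static_vitality <- function(series) {
  lengths <- if (is.numeric(series)) series else as_tibble(series)$length_cm
  if (length(lengths) == 0) abort("empty series: static vitality undefined")
  mean(lengths)
}

#' Comprehensive vitality scores and percentage shares
#'
#' Combines static vitality (mean length) and dynamic vitality (growth
#' slope) into one score per treatment cell and aggregates per nano-iron
#' level. Within each normalisation block ("equivalent conditions": by
#' default each salt level separately, optionally the whole table) static
#' and dynamic values are divided by their block maxima; the cell score is
#' the equal-weight mean `0.5 * norm_static + 0.5 * norm_dynamic`; each fe
#' level's score is the mean of its cell scores across salt levels; and
#' shares express the fe scores as percentages of their sum. Negative
#' slopes are floored at 0 before normalisation so scores stay in `[0, 1]`.
#'
#' @param cells Data frame with one row per (salt, fe) cell: `salt_mmolL`,
#'   `fe_mgL`, `static_cm`, `dynamic_cm_per_h`. Every combination of the
#'   levels present must appear exactly once.
#' @param strategy `"per-salt"` (default) normalises within each salt
#'   level; `"global"` uses table-wide maxima.
#' @return A `vitality_scores` object: list with `cells` (normalised values
#'   and per-cell `comprehensive` scores) and `fe_summary` (per-fe `score`,
#'   `share_pct`, `rank`).
#' @examples
#' cells <- data.frame(salt_mmolL = 0, fe_mgL = c(0, 300),
#'                     static_cm = c(2, 4), dynamic_cm_per_h = c(0.025, 0.05))
#' comprehensive_scores(cells)$fe_summary$share_pct # 33.33, 66.67
#' @export
comprehensive_scores <- function(cells, strategy = c("per-salt", "global")) {
  strategy <- match.arg(strategy)
  cells <- as_tibble(cells)
  need <- c("salt_mmolL", "fe_mgL", "static_cm", "dynamic_cm_per_h")
  if (!all(need %in% names(cells))) {
    abort(paste("cells need columns:", paste(need, collapse = ", ")))
  }
  salts <- sort(unique(cells$salt_mmolL))
  fes <- sort(unique(cells$fe_mgL))
  full <- expand.grid(salt_mmolL = salts, fe_mgL = fes)
  got <- paste(cells$salt_mmolL, cells$fe_mgL)
  want <- paste(full$salt_mmolL, full$fe_mgL)
  if (anyDuplicated(got)) abort("duplicate (salt, fe) cells")
  miss <- setdiff(want, got)
  if (length(miss) > 0) {
    abort(sprintf("missing design cell(s): (salt, fe) = %s",
                  paste(miss, collapse = "; ")))
  }

  cells <- mutate(cells, dynamic_cm_per_h = pmax(0, .data$dynamic_cm_per_h),
                  block = if (strategy == "per-salt") .data$salt_mmolL else 0)
  blocks <- cells |>
    group_by(.data$block) |>
    summarise(max_static = max(.data$static_cm),
              max_dynamic = max(.data$dynamic_cm_per_h), .groups = "drop")
  dead <- blocks$block[blocks$max_static <= 0 | blocks$max_dynamic <= 0]
  if (length(dead) > 0) {
    warn(sprintf("normalisation block(s) with zero maxima excluded: %s",
                 paste(dead, collapse = ", ")))
    cells <- filter(cells, !(.data$block %in% dead))
    if (nrow(cells) == 0) abort("no normalisation block with positive maxima")
    blocks <- filter(blocks, !(.data$block %in% dead))
  }
  cells <- cells |>
    left_join(blocks, by = "block") |>
    mutate(norm_static = .data$static_cm / .data$max_static,
           norm_dynamic = .data$dynamic_cm_per_h / .data$max_dynamic,
           comprehensive = 0.5 * .data$norm_static + 0.5 * .data$norm_dynamic) |>
    select(-"block", -"max_static", -"max_dynamic")

  fe_summary <- cells |>
    group_by(.data$fe_mgL) |>
    summarise(score = mean(.data$comprehensive), .groups = "drop") |>
    mutate(share_pct = 100 * .data$score / sum(.data$score)) |>
    arrange(desc(.data$score)) |>
    mutate(rank = row_number()) |>
    arrange(.data$fe_mgL)

  structure(list(cells = cells, fe_summary = fe_summary, strategy = strategy),
            class = "vitality_scores")
}

#' @export
print.vitality_scores <- function(x, ...) {
  cat(sprintf("<vitality_scores> strategy: %s\n", x$strategy))
  print(as.data.frame(x$fe_summary), row.names = FALSE)
  invisible(x)
}

#' @describeIn comprehensive_scores Per-cell normalised table.
#' @param x A `vitality_scores`.
#' @param ... Ignored.
#' @export
tidy.vitality_scores <- function(x, ...) as_tibble(x$cells)

#' @describeIn comprehensive_scores One-row summary (top fe level and its
#'   share).
#' @export
glance.vitality_scores <- function(x, ...) {
  top <- x$fe_summary[x$fe_summary$rank == 1, ]
  tibble(n_cells = nrow(x$cells), n_fe_levels = nrow(x$fe_summary),
         strategy = x$strategy, top_fe_mgL = top$fe_mgL,
         top_share_pct = top$share_pct)
}

#' @describeIn comprehensive_scores Bar chart of comprehensive shares per
#'   nano-iron level.
#' @param object A `vitality_scores`.
#' @export
autoplot.vitality_scores <- function(object, ...) {
  ggplot(object$fe_summary,
         aes(x = factor(.data$fe_mgL), y = .data$share_pct)) +
    geom_col() +
    labs(x = "nano-iron oxide (mg/L)", y = "comprehensive share (%)",
         title = "Dual-index vitality shares") +
    theme_minimal()
}

#' Full vitality report for a growth-series table
#'
#' Computes per-cell static vitality (mean length) and dynamic vitality
#' (fitted slope) for every (salt, fe) treatment cell of a series table,
#' then the normalised comprehensive scores and per-fe shares via
#' [comprehensive_scores()]. Deterministic and invariant to input row
#' order.
#'
#' @param series Data frame with `salt_mmolL`, `fe_mgL`, `t_min`,
#'   `length_cm` (replicates pooled per cell if present).
#' @param strategy Normalisation strategy, see [comprehensive_scores()].
#' @return A `vitality_scores` object whose `cells` table also carries
#'   `static_cm` and `dynamic_cm_per_h` per cell.
#' @examples
#' gs <- generate_growth_series(treatment_design(), scene_config(), seed = 1)
#' rep <- vitality_report(gs)
#' glance(rep)$top_fe_mgL # 300
#' @export
vitality_report <- function(series, strategy = c("per-salt", "global")) {
  strategy <- match.arg(strategy)
  s <- as_tibble(series) |> arrange(.data$salt_mmolL, .data$fe_mgL, .data$t_min)
  cells <- s |>
    group_by(.data$salt_mmolL, .data$fe_mgL) |>
    summarise(static_cm = static_vitality(length_cm),
              dynamic_cm_per_h = fit_growth_rate(
                data.frame(t_min = t_min, length_cm = length_cm)
              )$slope_cm_per_h,
              .groups = "drop")
  comprehensive_scores(cells, strategy = strategy)
}
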