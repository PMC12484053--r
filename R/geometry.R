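#' Apply a radial pincushion warp to pixel coordinates
#'
#' Single-coefficient radial distortion: each point `p` maps to
#' `center + d * (1 + k1 * r^2)` where `d = p - center` and
#' `r = |d| / (half frame diagonal)`. With `k1 > 0` edge pixels spread
#' outward (pincushion), so peripheral objects are magnified and their
#' measured perimeters over-estimated; `k1 = 0` is the identity.
#'
#' @param points A data frame (or matrix) with columns `x`, `y` in pixel
#'   coordinates (origin top-left, x right, y down, pixel centres at integer
#'   coordinates).
#' @param k1 Radial coefficient, `>= 0`.
#' @param center Length-2 numeric, the optical centre in px.
#' @param frame_px Frame side in px used to normalise radii (half the frame
#'   diagonal is the unit radius). Defaults to `2 * max(center)`.
#' @return A tibble with warped `x`, `y`.
#' @examples
#' apply_pincushion(data.frame(x = 800, y = 1600), k1 = 0.08,
#'                  center = c(800, 800)) # y -> 1632
#' @export
apply_pincushion <- function(points, k1, center, frame_px = 2 * max(center)) {
  pts <- as_xy(points)
  if (!all(is.finite(pts$x)) || !all(is.finite(pts$y))) {
    abort("`points` must contain finite coordinates.")
  }
  if (k1 < 0) abort("`k1` must be >= 0.")
  half_diag <- frame_px * sqrt(2) / 2
  dx <- pts$x - center[1]
  dy <- pts$y - center[2]
  r2 <- (dx^2 + dy^2) / half_diag^2
  s <- 1 + k1 * r2
  tibble(x = center[1] + dx * s, y = center[2] + dy * s)
}

as_xy <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points))) {
    if (ncol(points) >= 2) names(points)[1:2] <- c("x", "y")
    else abort("`points` needs `x` and `y` columns.")
  }
  tibble(x = as.numeric(points$x), y = as.numeric(points$y))
}

#' Rotate coordinates about their centroid (or a given origin)
#'
#' Applies the rotation matrix `R(theta)` so that, with `theta` equal to a
#' seedling's smoothed lean azimuth, its principal axis is brought upright.
#' A pure isometry: all pairwise distances (and hence arc lengths) are
#' preserved.
#'
#' @param points Data frame with `x`, `y` columns.
#' @param theta_deg Rotation angle in degrees (counter-clockwise in the
#'   mathematical x-right / y-up sense; in image coordinates with y down the
#'   visual rotation is clockwise).
#' @param origin Centre of rotation; defaults to the centroid of `points`.
#' @return Tibble of rotated `x`, `y`.
#' @examples
#' rotate_align(data.frame(x = 1, y = 0), 90, origin = c(0, 0)) # ~ (0, 1)
#' @export
rotate_align <- function(points, theta_deg, origin = NULL) {
  pts <- as_xy(points)
  if (!all(is.finite(pts$x)) || !all(is.finite(pts$y))) {
    abort("`points` must contain finite coordinates.")
  }
  if (is.null(origin)) origin <- c(mean(pts$x), mean(pts$y))
  th <- theta_deg * pi / 180
  dx <- pts$x - origin[1]
  dy <- pts$y - origin[2]
  tibble(x = origin[1] + cos(th) * dx - sin(th) * dy,
         y = origin[2] + sin(th) * dx + cos(th) * dy)
}

# wrap an angle difference to (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# unit direction of a compass azimuth (clockwise from image-up, y down)
azimuth_dir <- function(azimuth_deg) {
  a <- azimuth_deg * pi / 180
  c(sin(a), -cos(a))
}

# Quadratic Bezier samples through (p0, p1, p2); n points including ends.
bezier_points <- function(p0, p1, p2, n = 200) {
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(x, y)
}

polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# Densify a polyline to a maximum vertex spacing (px or cm, caller's units).
densify_polyline <- function(xy, spacing) {
  segs <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  keep <- list(xy[1, , drop = FALSE])
  for (i in seq_along(segs)) {
    if (segs[i] <= .Machine$double.eps) next
    k <- max(1L, ceiling(segs[i] / spacing))
    t <- seq_len(k) / k
    keep[[length(keep) + 1L]] <- cbind(
      xy[i, 1] + t * (xy[i + 1, 1] - xy[i, 1]),
      xy[i, 2] + t * (xy[i + 1, 2] - xy[i, 2]))
  }
  do.call(rbind, keep)
}

#' Rasterise a tapered stroke into a soft coverage mask
#'
#' Internal rasteriser used by the scene generator. The stroke is the union
#' of discs of radius `radius_px(s)` swept along the midline; each pixel gets
#' the clamped signed-distance coverage `clip(0.5 + (R - d), 0, 1)` where `d`
#' is the distance from the pixel centre to the midline and `R` the local
#' radius. The 0.5 iso-level of this field is exactly the stroke boundary,
#' so marching-squares contours recover sub-pixel perimeters.
#'
#' @param midline_px n x 2 matrix of midline vertices in px.
#' @param radius_px Scalar or length-n vector of stroke radii in px.
#' @param frame_px Frame side; pixels outside `[0, frame_px - 1]` are dropped.
#' @return A list with integer offsets `x0`, `y0` (px coordinate of the
#'   mask's first column/row) and `m`, the coverage matrix (rows = y).
#' @keywords internal
#' @noRd
rasterize_stroke <- function(midline_px, radius_px, frame_px) {
  stopifnot(nrow(midline_px) >= 2)
  if (length(radius_px) == 1L) radius_px <- rep(radius_px, nrow(midline_px))
  r_max <- max(radius_px)

  # resample midline (and its radius profile) at ~1 px spacing for segments
  cum <- c(0, cumsum(sqrt(diff(midline_px[, 1])^2 + diff(midline_px[, 2])^2)))
  total <- cum[length(cum)]
  n_seg <- max(2L, ceiling(total / 1.0))
  s_new <- seq(0, total, length.out = n_seg + 1L)
  px <- stats::approx(cum, midline_px[, 1], xout = s_new, ties = "ordered")$y
  py <- stats::approx(cum, midline_px[, 2], xout = s_new, ties = "ordered")$y
  pr <- stats::approx(cum, radius_px, xout = s_new, ties = "ordered")$y

  # candidate pixels: integer coordinates within r_max + 1.6 of any vertex
  pad <- r_max + 1.6
  x_lo <- max(0L, floor(min(px) - pad)); x_hi <- min(frame_px - 1L, ceiling(max(px) + pad))
  y_lo <- max(0L, floor(min(py) - pad)); y_hi <- min(frame_px - 1L, ceiling(max(py) + pad))
  if (x_hi < x_lo || y_hi < y_lo) abort("stroke lies entirely outside the frame")
  off <- expand.grid(dx = seq(-ceiling(pad), ceiling(pad)),
                     dy = seq(-ceiling(pad), ceiling(pad)))
  off <- off[off$dx^2 + off$dy^2 <= (pad + 0.75)^2, , drop = FALSE]
  cx <- rep(round(px), each = nrow(off)) + off$dx
  cy <- rep(round(py), each = nrow(off)) + off$dy
  ok <- cx >= x_lo & cx <= x_hi & cy >= y_lo & cy <= y_hi
  key <- unique((cy[ok] - y_lo) * (x_hi - x_lo + 1L) + (cx[ok] - x_lo))
  qx <- key %% (x_hi - x_lo + 1L) + x_lo
  qy <- key %/% (x_hi - x_lo + 1L) + y_lo

  # signed field: max over segments of (local radius - distance to segment)
  best <- rep(-Inf, length(qx))
  ax <- px[-length(px)]; ay <- py[-length(py)]
  bx <- px[-1L]; by <- py[-1L]
  ra <- pr[-length(pr)]; rb <- pr[-1L]
  for (i in seq_along(ax)) {
    vx <- bx[i] - ax[i]; vy <- by[i] - ay[i]
    L2 <- vx * vx + vy * vy
    if (L2 < .Machine$double.eps) next
    t <- ((qx - ax[i]) * vx + (qy - ay[i]) * vy) / L2
    t <- pmin(1, pmax(0, t))
    dx <- qx - (ax[i] + t * vx)
    dy <- qy - (ay[i] + t * vy)
    best <- pmax(best, (ra[i] + t * (rb[i] - ra[i])) - sqrt(dx * dx + dy * dy))
  }
  v <- pmin(1, pmax(0, 0.5 + best))

  m <- matrix(0, nrow = y_hi - y_lo + 1L, ncol = x_hi - x_lo + 1L)
  m[cbind(qy - y_lo + 1L, qx - x_lo + 1L)] <- v
  list(x0 = as.integer(x_lo), y0 = as.integer(y_lo), m = m)
}
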