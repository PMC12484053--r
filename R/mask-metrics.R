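#' Binarise and merge per-instance masks into one binary map
#'
#' Each probability mask is thresholded, the binary masks are summed, and
#' the sum is clipped back to `{0, 1}` so that overlapping instances do not
#' overflow the valid range. Idempotent on already-binary input.
#'
#' @param masks List of numeric matrices sharing one shape, values in
#'   `[0, 1]` (probabilities) or `{0, 1}` (binary).
#' @param threshold Binarisation threshold; pixels with value strictly
#'   greater are foreground. Default 0.5.
#' @param dim Frame shape `c(rows, cols)`, required only when `masks` is
#'   empty (returns an all-zero mask of that shape).
#' @return A binary matrix (values 0/1).
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[3:4, 3:4] <- 0.9
#' sum(binarize_and_merge(list(a, b))) # union: 8 pixels
#' @export
binarize_and_merge <- function(masks, threshold = 0.5, dim = NULL) {
  if (length(masks) == 0L) {
    if (is.null(dim)) abort("empty mask list: supply `dim` for the frame shape")
    return(matrix(0, dim[1], dim[2]))
  }
  shp <- base::dim(masks[[1]])
  for (m in masks) {
    if (!identical(base::dim(m), shp)) abort("all masks must share one shape")
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
      abort("mask values must be finite and within [0, 1]")
    }
  }
  merged <- Reduce(`+`, lapply(masks, function(m) (m > threshold) * 1))
  pmin(merged, 1)
}

#' Extract the outer contour of a mask at the 0.5 iso-level
#'
#' Traces the sub-pixel 0.5 iso-contour of the mask (marching-squares with
#' linear interpolation, via [grDevices::contourLines()]) and returns the
#' outer boundary of the largest connected component as an ordered, closed
#' polygon. Works on binary masks (contour passes midway between foreground
#' and background pixel centres) and on soft coverage masks (contour at the
#' true sub-pixel boundary). If the mask contains several connected
#' components only the largest is kept and the count is reported.
#'
#' @param mask Numeric matrix, values in `[0, 1]`; rows are y (down), columns
#'   x (right), pixel centres at integer coordinates starting at `(x0, y0)`.
#' @param id Instance identifier carried through to the result.
#' @param x0,y0 Pixel coordinates of `mask[1, 1]`. Default 0.
#' @return A `contour_polygon`: tibble of ordered vertices (`x`, `y`) with
#'   attributes `id` and `closed = TRUE` (first vertex implicitly follows the
#'   last).
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 1
#' extract_contour(m) # 4-vertex diamond around the single pixel
#' @export
extract_contour <- function(mask, id = 1L, x0 = 0, y0 = 0) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  bin <- mask >= 0.5
  if (!any(bin)) abort("no foreground: mask has no pixel >= 0.5")

  n_comp <- 1L
  lab <- EBImage::bwlabel(bin * 1)
  n_comp <- max(lab)
  if (n_comp > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
    keep <- which.max(sizes)
    inform(sprintf("mask has %d connected components; keeping the largest", n_comp))
    mask[lab != keep & bin] <- 0
  }

  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  ys <- (y0 - 1):(y0 + nrow(mask))
  xs <- (x0 - 1):(x0 + ncol(mask))
  # trace a hair below 0.5 so grid values exactly at the level (common in
  # synthetic coverage fields) cannot split the loop at degenerate vertices
  cl <- grDevices::contourLines(x = ys, y = xs, z = padded, levels = 0.5 - 1e-6)
  if (length(cl) == 0L) abort("no contour found at the 0.5 level")

  areas <- vapply(cl, function(p) abs(shoelace_area(p$y, p$x)), numeric(1))
  best <- cl[[which.max(areas)]]
  # contourLines: $x follows the matrix rows (our y), $y the columns (our x)
  vx <- best$y
  vy <- best$x
  if (length(vx) > 1 && vx[1] == vx[length(vx)] && vy[1] == vy[length(vy)]) {
    vx <- vx[-length(vx)]
    vy <- vy[-length(vy)]
  }
  if (length(vx) < 3) abort("degenerate contour with fewer than 3 vertices")
  structure(tibble(x = vx, y = vy),
            id = id, closed = TRUE, n_components = n_comp,
            class = c("contour_polygon", "tbl_df", "tbl", "data.frame"))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Perimeter of a closed contour polygon
#'
#' Sum of Euclidean segment lengths around the closed vertex cycle (the
#' closing segment from last back to first vertex is included).
#'
#' @param polygon A `contour_polygon` or any data frame with `x`, `y`
#'   columns describing a closed polygon.
#' @return Perimeter in px (strictly positive).
#' @examples
#' sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' perimeter(sq) # 4
#' @export
perimeter <- function(polygon) {
  pts <- as_xy(polygon)
  n <- nrow(pts)
  if (n > 1 && pts$x[1] == pts$x[n] && pts$y[1] == pts$y[n]) {
    pts <- pts[-n, ]
    n <- n - 1L
  }
  if (n < 3) abort("a polygon needs at least 3 distinct vertices")
  j <- c(2:n, 1)
  sum(sqrt((pts$x[j] - pts$x)^2 + (pts$y[j] - pts$y)^2))
}

#' @export
print.contour_polygon <- function(x, ...) {
  cat(sprintf("<contour_polygon> id=%s, %d vertices, perimeter %.3f px\n",
              format(attr(x, "id")), nrow(x), perimeter(x)))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Binary (or probability, thresholded at 0.5) matrices of the
#'   same shape.
#' @return `|a & b| / |a | b|` in `[0, 1]`. Two empty masks are an error.
#' @examples
#' a <- matrix(0, 4, 8); a[1:2, 1:4] <- 1
#' b <- matrix(0, 4, 8); b[1:2, 3:6] <- 1
#' mask_iou(a, b) # 4 / 12
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("masks must share one shape")
  fa <- a >= 0.5
  fb <- b >= 0.5
  uni <- sum(fa | fb)
  if (uni == 0) abort("both masks are empty: IoU undefined")
  sum(fa & fb) / uni
}

#' Average precision of instance detections against ground truth
#'
#' Greedy confidence-ordered matching per IoU threshold: predictions are
#' visited in decreasing confidence; each claims the unmatched ground-truth
#' instance of highest IoU if that IoU reaches the threshold (true positive),
#' otherwise it is a false positive. AP is the area under the
#' precision-recall curve with all-point interpolation (precision envelope),
#' and mAP averages AP over thresholds 0.5, 0.55, ..., 0.95.
#'
#' @param pred_masks List of predicted binary masks.
#' @param confidence Numeric vector in `[0, 1]`, one value per prediction.
#' @param truth_masks List of ground-truth binary masks (at least one).
#' @param iou_thresholds IoU thresholds. Default `seq(0.5, 0.95, by = 0.05)`.
#' @param iou_matrix Optional precomputed `length(pred) x length(truth)` IoU
#'   matrix; when given the masks may be omitted.
#' @return A tibble with one row per threshold (`iou_threshold`, `ap`) and
#'   attributes `map50` (AP at 0.5) and `map` (mean over all thresholds).
#' @examples
#' a <- matrix(0, 8, 8); a[1:4, 1:4] <- 1
#' average_precision(list(a), 0.9, list(a))$ap # 1 at every threshold
#' @export
average_precision <- function(pred_masks = NULL, confidence = NULL,
                              truth_masks = NULL,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05),
                              iou_matrix = NULL) {
  if (is.null(iou_matrix)) {
    if (is.null(truth_masks) || length(truth_masks) < 1L) {
      abort("at least one ground-truth instance is required")
    }
    n_pred <- length(pred_masks)
    iou_matrix <- matrix(0, n_pred, length(truth_masks))
    if (n_pred > 0) {
      for (i in seq_len(n_pred)) {
        for (j in seq_along(truth_masks)) {
          iou_matrix[i, j] <- tryCatch(
            mask_iou(pred_masks[[i]], truth_masks[[j]]),
            error = function(e) 0)
        }
      }
    }
  }
  n_pred <- nrow(iou_matrix)
  n_truth <- ncol(iou_matrix)
  if (n_truth < 1L) abort("at least one ground-truth instance is required")
  if (any(iou_thresholds <= 0 | iou_thresholds >= 1)) {
    abort("IoU thresholds must lie in (0, 1)")
  }
  if (n_pred == 0L) {
    warn("no predictions: AP is 0 at every threshold")
    out <- tibble(iou_threshold = iou_thresholds, ap = 0)
    return(structure(out, map50 = 0, map = 0))
  }
  if (is.null(confidence)) confidence <- rep(1, n_pred)
  if (any(confidence < 0 | confidence > 1)) abort("confidences must be in [0, 1]")
  ord <- order(confidence, decreasing = TRUE)

  ap_at <- function(thr) {
    matched <- logical(n_truth)
    tp <- numeric(n_pred)
    for (k in seq_along(ord)) {
      ious <- iou_matrix[ord[k], ]
      ious[matched] <- -1
      j <- which.max(ious)
      if (ious[j] >= thr) {
        matched[j] <- TRUE
        tp[k] <- 1
      }
    }
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_len(n_pred)
    rec <- cum_tp / n_truth
    # all-point interpolation: integrate the precision envelope over recall
    env <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * env)
  }

  ap <- vapply(iou_thresholds, ap_at, numeric(1))
  out <- tibble(iou_threshold = iou_thresholds, ap = ap)
  structure(out,
            map50 = if (any(abs(iou_thresholds - 0.5) < 1e-9))
              ap[which.min(abs(iou_thresholds - 0.5))] else NA_real_,
            map = mean(ap))
}
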