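test_that("binarise-and-merge unions, clips and stays idempotent", {
  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1
  b <- matrix(0, 6, 6); b[4:5, 4:5] <- 0.9
  merged <- binarize_and_merge(list(a, b))
  expect_equal(sum(merged), 8)
  expect_true(all(merged %in% c(0, 1)))
  # overlapping identical masks: clipping absorbs the double count
  expect_equal(binarize_and_merge(list(a, a)), (a > 0.5) * 1)
  # idempotent on already-binary input
  expect_equal(binarize_and_merge(list(merged)), merged)
  # a constant sub-threshold probability mask vanishes
  expect_equal(sum(binarize_and_merge(list(matrix(0.4, 5, 5)))), 0)
  expect_error(binarize_and_merge(list(a, matrix(0, 3, 3))), "shape")
  expect_equal(sum(binarize_and_merge(list(), dim = c(4, 4))), 0)
  expect_error(binarize_and_merge(list()), "dim")
})

test_that("contour of a single pixel is the 4-vertex midpoint diamond", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  p <- extract_contour(m)
  expect_equal(nrow(p), 4)
  # vertices at half-integer offsets around pixel (2, 2) (0-based x, y)
  got <- p[order(p$x, p$y), ]
  expect_equal(got$x, c(1.5, 2, 2, 2.5), tolerance = 1e-5)
  expect_equal(got$y, c(2, 1.5, 2.5, 2), tolerance = 1e-5)
})

test_that("contour of a filled rectangle stays rectangle-like", {
  m <- matrix(0, 30, 40); m[10:20, 5:35] <- 1
  p <- extract_contour(m)
  # perimeter of the traced 0.5 iso-line: 2*(11 + 31) with corner cuts
  expect_equal(perimeter(p), 2 * (11 + 31), tolerance = 0.05)
  expect_gte(min(p$y), 8); expect_lte(max(p$y), 20)
})

test_that("ring masks yield the outer boundary only", {
  n <- 41
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, `+`))
  ring <- (d <= 15 & d >= 8) * 1
  p <- expect_message(extract_contour(ring), NA)
  r_vert <- sqrt((p$x - 20)^2 + (p$y - 20)^2)
  expect_true(all(r_vert > 13)) # all vertices near the outer radius
  expect_equal(perimeter(p), 2 * pi * 15.5, tolerance = 0.05)
})

test_that("multi-component masks keep the largest component", {
  m <- matrix(0, 20, 20)
  m[2:10, 2:4] <- 1   # 27 px
  m[15:16, 15] <- 1   # 2 px speck
  expect_message(p <- extract_contour(m), "2 connected components")
  expect_true(all(p$x < 10)) # contour belongs to the big component
  expect_error(extract_contour(matrix(0, 4, 4)), "no foreground")
})

test_that("perimeter matches closed forms on exact polygons", {
  expect_equal(perimeter(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))), 4)
  expect_equal(perimeter(data.frame(x = c(0, 3, 0), y = c(0, 0, 4))), 12)
  expect_error(perimeter(data.frame(x = c(0, 1), y = c(0, 1))), "3")
})

test_that("perimeter is translation- and rotation-invariant on rasters", {
  m <- matrix(0, 40, 40); m[10:25, 15:22] <- 1
  base <- perimeter(extract_contour(m))
  shifted <- matrix(0, 40, 40); shifted[14:29, 8:15] <- 1
  expect_equal(perimeter(extract_contour(shifted)), base, tolerance = 1e-9)
  rotated <- t(m) # 90 degree rotation of a binary raster
  expect_equal(perimeter(extract_contour(rotated)), base, tolerance = 1e-9)
  # doubling the raster scale doubles the perimeter within the raster bound
  up <- m[rep(1:40, each = 2), rep(1:40, each = 2)]
  expect_equal(perimeter(extract_contour(up)) / base, 2, tolerance = 0.02)
})

test_that("mask IoU matches pixel counting and its invariants", {
  a <- matrix(0, 4, 8); a[1:2, 1:4] <- 1
  b <- matrix(0, 4, 8); b[1:2, 3:6] <- 1
  expect_equal(mask_iou(a, b), 4 / 12)
  expect_equal(mask_iou(a, a), 1)
  disj <- matrix(0, 4, 8); disj[3:4, 1:4] <- 1
  expect_equal(mask_iou(a, disj), 0)
  expect_error(mask_iou(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_error(mask_iou(a, matrix(0, 2, 2)), "shape")
  set.seed(7)
  for (i in 1:20) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(x | y) == 0) next
    expect_equal(mask_iou(x, y), mask_iou(y, x))
    expect_lte(mask_iou(x, y),
               min(sum(x), sum(y)) / max(1, max(sum(x), sum(y))) + 1e-12)
    expect_equal(mask_iou(x, y) == 1, identical(x == 1, y == 1))
  }
})

test_that("average precision is exact on forced matchings", {
  a <- matrix(0, 8, 8); a[1:4, 1:4] <- 1
  b <- matrix(0, 8, 8); b[5:8, 5:8] <- 1
  # perfect predictions: AP 1 at every threshold
  res <- average_precision(list(a, b), c(0.9, 0.8), list(a, b))
  expect_true(all(res$ap == 1))
  expect_equal(attr(res, "map"), 1)
  # nothing overlaps: AP 0
  c1 <- matrix(0, 8, 8); c1[1:2, 5:8] <- 1
  res0 <- average_precision(list(c1), 0.9, list(b))
  expect_true(all(res0$ap == 0))
  expect_warning(average_precision(list(), numeric(0), list(a)), "no predictions")
  expect_error(average_precision(list(a), 0.9, list()), "ground-truth")
})

test_that("average precision agrees with a brute-force PR construction", {
  # 3 truths, 3 predictions with IoUs {1.0, 0.6, 0.2} in descending
  # confidence; oracle: walk detections, build the PR curve, integrate the
  # precision envelope over recall
  iou <- diag(c(1.0, 0.6, 0.2))
  conf <- c(0.9, 0.8, 0.7)
  oracle_ap <- function(iou, conf, thr) {
    ord <- order(conf, decreasing = TRUE)
    matched <- logical(ncol(iou)); tp <- integer(0)
    for (k in ord) {
      cand <- which(!matched & iou[k, ] >= thr)
      if (length(cand) > 0) {
        j <- cand[which.max(iou[k, cand])]
        matched[j] <- TRUE; tp <- c(tp, 1L)
      } else tp <- c(tp, 0L)
    }
    prec <- cumsum(tp) / seq_along(tp)
    rec <- cumsum(tp) / ncol(iou)
    ap <- 0; prev_r <- 0
    for (i in seq_along(rec)) {
      env <- max(prec[i:length(prec)])
      ap <- ap + (rec[i] - prev_r) * env
      prev_r <- rec[i]
    }
    ap
  }
  res <- average_precision(confidence = conf, iou_matrix = iou,
                           iou_thresholds = 0.5)
  expect_equal(res$ap, oracle_ap(iou, conf, 0.5))
  expect_equal(res$ap, 2 / 3, tolerance = 1e-12)
  # against the oracle across thresholds and a random IoU matrix
  set.seed(3)
  riou <- matrix(runif(20), 5, 4)
  rconf <- runif(5)
  thr <- seq(0.5, 0.95, 0.05)
  res2 <- average_precision(confidence = rconf, iou_matrix = riou,
                            iou_thresholds = thr)
  expect_equal(res2$ap, vapply(thr, function(t) oracle_ap(riou, rconf, t),
                               numeric(1)))
  # AP is non-increasing in the IoU threshold
  expect_true(all(diff(res2$ap) <= 1e-12))
})
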