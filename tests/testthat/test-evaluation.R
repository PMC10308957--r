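# Brute-force AP oracle: explicit envelope over the interpolation grid.
ap_oracle <- function(flags, n_gt, grid = seq(0, 1, 0.01)) {
  if (n_gt == 0) return(NA_real_)
  if (!length(flags) || !any(flags)) return(0)
  tp <- cumsum(flags); fp <- cumsum(!flags)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  vals <- vapply(grid, function(r) {
    ok <- which(rec >= r)
    if (length(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(vals)
}

det_df <- function(boxes, conf, cls = 1L) {
  data.frame(cx = boxes[, 1], cy = boxes[, 2], w = boxes[, 3], h = boxes[, 4],
             confidence = conf, class_id = cls)
}

test_that("match_detections applies greedy one-to-one matching", {
  gt <- data.frame(class_id = 1L, cx = 10, cy = 10, w = 8, h = 8)
  d1 <- det_df(bbox(10, 10, 8, 8), 0.9)
  expect_true(match_detections(d1, gt, 0.5)[1])
  # two detections over one gt: only the more confident is TP
  d2 <- det_df(rbind(bbox(10, 10, 8, 8), bbox(10.5, 10, 8, 8)), c(0.7, 0.9))
  m <- match_detections(d2, gt, 0.5)
  expect_equal(sum(m), 1L)
  expect_equal(attr(m, "order")[which(m)[1]], 2L) # the 0.9 one
  # IoU exactly at the threshold counts as correct
  g2 <- data.frame(class_id = 1L, cx = 5, cy = 5, w = 10, h = 10)
  shifted <- bbox(10, 5, 10, 10) # IoU = 5*10 / (150) = 1/3
  expect_true(match_detections(det_df(shifted, 0.8), g2, 1 / 3)[1])
  expect_false(match_detections(det_df(shifted, 0.8), g2, 1 / 3 + 1e-9)[1])
})

test_that("average_precision equals the brute-force envelope oracle", {
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1.0)
  expect_equal(average_precision(logical(0), 3), 0)
  expect_true(is.na(average_precision(logical(0), 0)))
  # 3 dets (TP, FP, TP) over 2 GTs
  fl <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(fl, 2), ap_oracle(fl, 2), tolerance = 1e-9)
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    fl <- runif(n) < 0.4
    ngt <- sum(fl) + sample(0:5, 1)
    if (ngt == 0) next
    expect_equal(average_precision(fl, ngt), ap_oracle(fl, ngt),
                 tolerance = 1e-9)
    expect_equal(average_precision(fl, ngt, "11"),
                 ap_oracle(fl, ngt, seq(0, 1, 0.1)), tolerance = 1e-9)
  }
})

test_that("mean_ap averages evaluated classes only", {
  expect_equal(mean_ap(c(0.5, 0.7)), 0.6)
  expect_equal(mean_ap(0.42), 0.42)
  expect_equal(mean_ap(c(0.2, NA, 0.6)), 0.4)
  expect_error(mean_ap(NA_real_), "no evaluated classes")
  set.seed(22)
  ap <- runif(17)
  expect_equal(mean_ap(ap), sum(ap) / 17, tolerance = 1e-12)
})

test_that("evaluate_detections reproduces closed-form threshold sweeps", {
  # perfect detector: exact boxes -> 1.0 at every threshold
  gt <- data.frame(class_id = c(1L, 2L), cx = c(10, 30), cy = c(10, 30),
                   w = c(8, 10), h = c(8, 12))
  dets <- det_df(as.matrix(gt[, c("cx", "cy", "w", "h")]), c(0.9, 0.8),
                 gt$class_id)
  ev <- evaluate_detections(list(dets), list(gt), 2)
  expect_equal(ev$map50, 1.0)
  expect_equal(ev$map5095, 1.0)
  # detections at IoU ~0.72 to their gts: AP 1 for thr <= 0.70, 0 above
  g <- data.frame(class_id = 1L, cx = 50, cy = 50, w = 20, h = 20)
  d <- det_df(bbox(50, 50 + 20 * (1 - 0.72) / (1 + 0.72), 20, 20), 0.9)
  stopifnot(abs(iou(as.matrix(d[, 1:4]), as.matrix(g[, 2:5])) - 0.72) < 1e-9)
  ev2 <- evaluate_detections(list(d), list(g), 1)
  expect_equal(unname(ev2$per_class[1, ]),
               as.numeric(seq(0.5, 0.95, 0.05) <= 0.72))
  expect_equal(ev2$map5095, 0.5)
  # a detector with constant per-threshold mAP keeps that mean
  expect_equal(map_range(list(d), list(g), 1), 0.5)
})

test_that("AP is invariant under duplication across images", {
  set.seed(23)
  gt <- data.frame(class_id = 1L, cx = c(20, 50), cy = c(20, 52),
                   w = c(10, 14), h = c(12, 10))
  d <- det_df(rbind(bbox(20, 21, 10, 12), bbox(49, 52, 14, 10),
                    bbox(70, 70, 8, 8)), c(0.9, 0.7, 0.8))
  e1 <- evaluate_detections(list(d), list(gt), 1)
  e2 <- evaluate_detections(list(d, d), list(gt, gt), 1)
  expect_equal(e1$map50, e2$map50, tolerance = 1e-9)
  expect_equal(e1$map5095, e2$map5095, tolerance = 1e-9)
})

test_that("map5095 never exceeds map50 on random scenes", {
  set.seed(24)
  for (i in 1:25) {
    n_img <- sample(1:3, 1)
    gts <- lapply(seq_len(n_img), function(j) {
      k <- sample(1:4, 1)
      data.frame(class_id = sample(1:3, k, TRUE),
                 cx = runif(k, 10, 90), cy = runif(k, 10, 90),
                 w = runif(k, 5, 20), h = runif(k, 5, 20))
    })
    dets <- lapply(gts, function(g) {
      jit <- as.matrix(g[, c("cx", "cy", "w", "h")]) +
        matrix(rnorm(4 * nrow(g), sd = 2), ncol = 4)
      jit[, 3:4] <- abs(jit[, 3:4]) + 1
      det_df(jit, runif(nrow(g)), g$class_id)
    })
    ev <- evaluate_detections(dets, gts, 3)
    expect_lte(ev$map5095, ev$map50 + 1e-12)
  }
})

test_that("measure_fps is definitional under an injected clock", {
  pair <- build_tiny_pair(0.05, 6L, test_anchor_set())
  m <- materialize_params(pair$student, 2)
  imgs <- lapply(1:10, function(i) array(0.5, c(64, 64, 3)))
# fake clock advancing 1 s between the two reads: 10 images in 1 s
  clk <- local({ i <- 0; function() { v <- i; i <<- i + 1; v } })
  expect_equal(as.numeric(measure_fps(m, imgs, clock = clk)), 10)
  # doubling the image count with the same fake elapsed time scales FPS
  clk2 <- local({ i <- 0; function() { v <- i; i <<- i + 1; v } })
  expect_equal(as.numeric(measure_fps(m, lapply(1:20, function(i) imgs[[1]]),
                                      clock = clk2)), 20)
  expect_error(measure_fps(m, list()), "zero images")
  # wall-clock smoke
  fps <- measure_fps(m, imgs[1:2])
  expect_gt(fps, 0)
  expect_true(!is.null(attr(fps, "meta")$platform))
})
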