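test_that("iou handles identity, disjoint and partial overlap", {
  a <- bbox_from_corners(0, 0, 2, 2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(bbox_from_corners(0, 0, 1, 1), bbox_from_corners(5, 5, 6, 6)), 0)
  # overlap 1x1 over union 7: verified against a rasterization oracle
  b <- bbox_from_corners(1, 1, 3, 3)
  expect_equal(iou(a, b), 1 / 7, tolerance = 1e-12)
  expect_equal(iou_raster_oracle(a, b), 1 / 7, tolerance = 2e-2)
  # degenerate pair
  z <- bbox(1, 1, 0, 0)
  expect_equal(iou(z, z), 0)
})

test_that("iou is symmetric and bounded on random pairs", {
  set.seed(7)
  a <- random_boxes(1e4); b <- random_boxes(1e4)
  v1 <- iou(a, b); v2 <- iou(b, a)
  expect_equal(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 1))
})

test_that("ciou_loss matches the closed form and a literal transcription", {
  t1 <- bbox(1, 1, 2, 2)
  expect_equal(ciou_loss(t1, t1), 0)
  # concentric, same aspect: L = 1 - IoU = 1 - 4/16
  expect_equal(ciou_loss(bbox(0, 0, 2, 2), bbox(0, 0, 4, 4)), 0.75,
               tolerance = 1e-9)
  p <- bbox(0, 0, 1, 2); t2 <- bbox(3, 0, 2, 1)
  expect_equal(ciou_loss(p, t2), ciou_literal(c(0, 0, 1, 2), c(3, 0, 2, 1)),
               tolerance = 1e-9)
  set.seed(1)
  a <- random_boxes(200); b <- random_boxes(200)
  lit <- vapply(seq_len(200), function(i) ciou_literal(a[i, ], b[i, ]),
                numeric(1))
  expect_equal(unname(ciou_loss(a, b)), lit, tolerance = 1e-9)
  # lower bound and degenerate-pred guard
  expect_true(all(ciou_loss(a, b) >= 1 - iou(a, b) - 1e-12))
  expect_true(all(ciou_loss(a, b) <= 3))
  expect_true(is.finite(ciou_loss(bbox(1, 1, 0, 0), bbox(2, 2, 3, 3))))
  expect_error(ciou_loss(a[1, , drop = FALSE], bbox(0, 0, 0, 1)), "positive")
})

test_that("ciou_grad matches numeric differentiation", {
  set.seed(2)
  a <- random_boxes(100); b <- random_boxes(100)
  g <- ciou_grad(a, b)
  for (i in c(1, 7, 23, 55, 90)) {
    gn <- num_grad(function(x) ciou_loss(rbind(x), b[i, , drop = FALSE]), a[i, ])
    expect_equal(unname(g[i, ]), gn, tolerance = 1e-5)
  }
})

test_that("nms suppresses duplicates per class and is idempotent", {
  d1 <- data.frame(cx = 5, cy = 5, w = 4, h = 4, confidence = 0.9, class_id = 1L)
  expect_equal(nrow(nms(d1, 0.5, 0.1)), 1L)
  # identical boxes, same class: higher confidence survives
  d2 <- rbind(d1, transform(d1, confidence = 0.8))
  out <- nms(d2, 0.5, 0.001)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, 0.9)
  # disjoint boxes both survive; different classes never suppress
  d3 <- rbind(d1, data.frame(cx = 50, cy = 50, w = 4, h = 4,
                             confidence = 0.8, class_id = 1L))
  expect_equal(nrow(nms(d3, 0.5, 0.001)), 2L)
  d4 <- rbind(d1, transform(d1, confidence = 0.8, class_id = 2L))
  expect_equal(nrow(nms(d4, 0.5, 0.001)), 2L)
  expect_equal(nrow(nms(d1[0, ], 0.5, 0.1)), 0L)
  # random scenes against the brute-force oracle + idempotence
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    d <- cbind(as.data.frame(random_boxes(n, lim = 40, wmax = 15)),
               confidence = runif(n), class_id = sample(1:3, n, TRUE))
    names(d)[1:4] <- c("cx", "cy", "w", "h")
    got <- nms(d, 0.5, 0.05)
    want <- nms_oracle(d, 0.5, 0.05)
    expect_equal(got, want)
    expect_equal(nms(got, 0.5, 0.05), got)
  }
})

test_that("kmeans_anchors recovers planted clusters and orders by area", {
  b <- rbind(matrix(rep(c(58, 64), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(597, 440), 10), ncol = 2, byrow = TRUE))
  a <- kmeans_anchors(b, 2, seed = 1, levels = 1L)
  expect_equal(unname(a$anchors), rbind(c(58, 64), c(597, 440)))
  # k = number of distinct boxes returns the boxes themselves
  distinct <- cbind(c(10, 40, 90), c(12, 44, 80))
  a3 <- kmeans_anchors(distinct, 3, seed = 2, levels = 1L)
  expect_equal(unname(a3$anchors), distinct[order(distinct[, 1] * distinct[, 2]), ])
  expect_error(kmeans_anchors(distinct, 5, seed = 1), "insufficient boxes")
  # 12 well-separated planted clusters recovered within 2 px
  set.seed(9)
  means <- cbind(w = seq(20, 460, by = 40), h = seq(30, 470, by = 40))
  pts <- means[rep(1:12, each = 40), ] + matrix(rnorm(2 * 480, sd = 1), ncol = 2)
  ak <- kmeans_anchors(pts, 12, seed = 4)
  ord <- order(means[, 1] * means[, 2])
  expect_lt(max(abs(ak$anchors - means[ord, ])), 2)
  # reproducibility and non-increasing Lloyd objective
  ak2 <- kmeans_anchors(pts, 12, seed = 4)
  expect_identical(ak$anchors, ak2$anchors)
  obj <- attr(ak, "objective")
  expect_true(all(diff(obj) <= 1e-9))
})

test_that("kmeans_anchors agrees with a reference implementation", {
  set.seed(11)
  pts <- cbind(runif(300, 5, 200), runif(300, 5, 200))
  ours <- kmeans_anchors(pts, 4, seed = 3, levels = 1L)
  ref <- stats::kmeans(pts, centers = ours$anchors, iter.max = 50,
                       algorithm = "Lloyd")
  # our solution is a fixed point: one more Lloyd pass does not move it
  expect_equal(unname(ref$centers[order(ref$centers[, 1] * ref$centers[, 2]), ]),
               unname(ours$anchors), tolerance = 1e-6)
})

test_that("anchor files round-trip and the packaged priors load area-sorted", {
  aset <- default_anchor_set()
  expect_equal(aset$levels, 4L)
  expect_equal(aset$per_level, 3L)
  areas <- aset$anchors[, 1] * aset$anchors[, 2]
  expect_true(all(diff(areas) >= 0))
  expect_equal(unname(aset$anchors[1, ]), c(58, 64))
  expect_equal(unname(aset$anchors[12, ]), c(597, 440))
  f <- tempfile(fileext = ".txt")
  write_anchors(aset, f)
  back <- read_anchors(f)
  expect_equal(back$anchors, aset$anchors)
})

test_that("decode_head follows the power decode convention", {
  aset <- test_anchor_set()
  g <- grid_spec(8, 4, 4, 1)
  C <- 3L
  raw <- array(0, c(3, 4, 4, 5 + C))
  dec <- decode_head(raw, level_anchors(aset, 1), g)
  # zero logits: center = cell center, wh = anchor exactly
  i <- which(abs(dec$cx - (0 + 0.5) * 8) < 1e-9 & abs(dec$cy - 0.5 * 8) < 1e-9)
  expect_true(length(i) >= 3)
  la <- level_anchors(aset, 1)
  expect_equal(sort(unique(dec$w)), sort(unique(unname(la[, 1]))))
  expect_equal(sort(unique(dec$h)), sort(unique(unname(la[, 2]))))
  expect_true(all(dec$confidence == 0.5))
  # random logits against an independent transcription of the decode
  set.seed(5)
  raw <- array(rnorm(length(raw)), dim(raw))
  dec <- decode_head(raw, la, g)
  k <- 0
  for (cc in 1:4) for (rr in 1:4) for (a in 1:3) {
    s <- function(j) plogis(raw[a, rr, cc, j])
    k <- k + 1
  }
  # explicit check at a handful of positions
  for (pos in list(c(1, 1, 1), c(2, 3, 4), c(3, 4, 2))) {
    a <- pos[1]; rr <- pos[2]; cc <- pos[3]
    idx <- which(abs(dec$cx - (2 * plogis(raw[a, rr, cc, 1]) - 0.5 + cc - 1) * 8) < 1e-9 &
                 abs(dec$cy - (2 * plogis(raw[a, rr, cc, 2]) - 0.5 + rr - 1) * 8) < 1e-9)
    expect_true(length(idx) >= 1)
    expect_true(any(abs(dec$w[idx] - (2 * plogis(raw[a, rr, cc, 3]))^2 * la[a, 1]) < 1e-9))
  }
  expect_true(all(dec$confidence > 0 & dec$confidence < 1))
  expect_error(decode_head(array(0, c(3, 4, 4, 2)), la, g), "5")
  expect_error(decode_head(array(0, c(2, 4, 4, 8)), la, g), "mismatch")
})

test_that("box conversions round-trip losslessly", {
  set.seed(13)
  b <- random_boxes(500)
  co <- box_corners(b)
  b2 <- bbox_from_corners(co[, 1], co[, 2], co[, 3], co[, 4])
  expect_equal(unname(b2), unname(b), tolerance = 1e-9)
  expect_error(bbox(0, 0, -1, 2), ">= 0")
  expect_error(bbox_from_corners(2, 0, 1, 3), "x2 >= x1")
})
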