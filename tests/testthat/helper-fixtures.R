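# Shared fixtures built in code at test time.

random_boxes <- function(n, lim = 100, wmax = 30) {
  bbox(runif(n, 0, lim), runif(n, 0, lim),
       runif(n, 0.5, wmax), runif(n, 0.5, wmax))
}

# Rasterization oracle for IoU: count cells of a fine integer grid lying in
# both boxes / in either box.
iou_raster_oracle <- function(a, b, res = 400) {
  ca <- box_corners(a); cb <- box_corners(b)
  lo <- pmin(ca[1, 1:2], cb[1, 1:2]) - 1
  hi <- pmax(ca[1, 3:4], cb[1, 3:4]) + 1
  xs <- seq(lo[1], hi[1], length.out = res)
  ys <- seq(lo[2], hi[2], length.out = res)
  gx <- rep(xs, times = res); gy <- rep(ys, each = res)
  ina <- gx >= ca[1, 1] & gx <= ca[1, 3] & gy >= ca[1, 2] & gy <= ca[1, 4]
  inb <- gx >= cb[1, 1] & gx <= cb[1, 3] & gy >= cb[1, 2] & gy <= cb[1, 4]
  sum(ina & inb) / sum(ina | inb)
}

# Literal second transcription of the CIoU formula (kept deliberately
# element-by-element and independent of the vectorized implementation).
ciou_literal <- function(p, t) {
  px1 <- p[1] - p[3] / 2; px2 <- p[1] + p[3] / 2
  py1 <- p[2] - p[4] / 2; py2 <- p[2] + p[4] / 2
  tx1 <- t[1] - t[3] / 2; tx2 <- t[1] + t[3] / 2
  ty1 <- t[2] - t[4] / 2; ty2 <- t[2] + t[4] / 2
  iw <- max(0, min(px2, tx2) - max(px1, tx1))
  ih <- max(0, min(py2, ty2) - max(py1, ty1))
  inter <- iw * ih
  uni <- p[3] * p[4] + t[3] * t[4] - inter
  iou <- inter / uni
  cw <- max(px2, tx2) - min(px1, tx1)
  ch <- max(py2, ty2) - min(py1, ty1)
  rho2 <- (p[1] - t[1])^2 + (p[2] - t[2])^2
  v <- 4 / pi^2 * (atan(t[3] / t[4]) - atan(p[3] / p[4]))^2
  alpha <- v / ((1 - iou) + v)
  1 - iou + rho2 / (cw^2 + ch^2 + 1e-9) + alpha * v
}

# Brute-force greedy per-class NMS oracle.
nms_oracle <- function(dets, iou_thr, score_thr) {
  dets <- dets[dets$confidence >= score_thr, , drop = FALSE]
  if (!nrow(dets)) return(dets)
  ord <- order(-dets$confidence, dets$class_id, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || dets$class_id[j] != dets$class_id[i]) next
      o <- iou(as.matrix(dets[j, c("cx", "cy", "w", "h")]),
               as.matrix(dets[i, c("cx", "cy", "w", "h")]))
      if (o > iou_thr) { keep[i] <- FALSE; break }
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Small labelled scene records for trainer tests (deterministic pixels).
tiny_records <- function(n = 6, seed = 42, n_train = NULL, n_test = 0) {
  cfg <- synth_config(n_train = n_train %||% n, n_test = n_test, seed = seed)
  generate_synthetic_dataset(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_anchor_set <- function() {
  anchor_set(cbind(w = c(6, 10, 14, 12, 20, 26, 24, 40, 52, 48, 80, 104),
                   h = c(8, 10, 10, 18, 22, 24, 40, 42, 50, 90, 96, 100)))
}
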