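# ---------------------------------------------------------------------------
# Detector geometry primitives. Boxes use continuous pixel coordinates with
# the origin at the top-left; a box is a row (cx, cy, w, h) and its corner
# form (x1, y1, x2, y2) is a closed real interval, so area = (x2-x1)*(y2-y1).
# ---------------------------------------------------------------------------

#' Construct boxes in center form
#'
#' @param cx,cy Box center, pixels.
#' @param w,h Box width and height, pixels (non-negative).
#' @return A numeric matrix with columns `cx, cy, w, h`, one row per box.
#' @export
bbox <- function(cx, cy, w, h) {
  b <- cbind(cx = cx, cy = cy, w = w, h = h)
  if (any(b[, c("w", "h")] < 0)) stop("box width/height must be >= 0")
  b
}

#' Construct boxes from corner form
#'
#' @param x1,y1,x2,y2 Corner coordinates with `x2 >= x1`, `y2 >= y1`.
#' @return Center-form box matrix (see [bbox()]).
#' @export
bbox_from_corners <- function(x1, y1, x2, y2) {
  if (any(x2 < x1) || any(y2 < y1)) stop("corners must satisfy x2 >= x1, y2 >= y1")
  bbox((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

#' Convert boxes to corner form
#' @param b Center-form box matrix.
#' @return Matrix with columns `x1, y1, x2, y2`.
#' @export
box_corners <- function(b) {
  b <- rbind(b)
  cbind(x1 = b[, 1] - b[, 3] / 2, y1 = b[, 2] - b[, 4] / 2,
        x2 = b[, 1] + b[, 3] / 2, y2 = b[, 2] + b[, 4] / 2)
}

#' Intersection over union
#'
#' Vectorized over rows; `a` and `b` must have the same number of rows (or
#' one of them a single row). Two degenerate (zero-area) boxes have IoU 0.
#'
#' @param a,b Center-form box matrices.
#' @return IoU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ca <- box_corners(a); cb <- box_corners(b)
  n <- max(nrow(ca), nrow(cb))
  if (nrow(ca) == 1L) ca <- ca[rep(1L, n), , drop = FALSE]
  if (nrow(cb) == 1L) cb <- cb[rep(1L, n), , drop = FALSE]
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  union <- (ca[, 3] - ca[, 1]) * (ca[, 4] - ca[, 2]) +
           (cb[, 3] - cb[, 1]) * (cb[, 4] - cb[, 2]) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Complete-IoU (CIoU) loss
#'
#' `L = 1 - IoU + rho^2/c^2 + alpha*v`, where `rho` is the center distance,
#' `c` the diagonal of the smallest enclosing box,
#' `v = (4/pi^2) * (atan(wt/ht) - atan(w/h))^2` the aspect-ratio penalty and
#' `alpha = v / ((1 - IoU) + v)`. Zero iff `pred == target`. Degenerate
#' predictions (zero width/height) are epsilon-guarded to a finite loss.
#'
#' @param pred,target Center-form box matrices (same number of rows, or one
#'   row recycled). Targets must have positive width and height.
#' @param eps Numerical guard for degenerate boxes.
#' @return Loss values, one per row pair.
#' @export
ciou_loss <- function(pred, target, eps = 1e-9) {
  pred <- rbind(pred); target <- rbind(target)
  n <- max(nrow(pred), nrow(target))
  if (nrow(pred) == 1L) pred <- pred[rep(1L, n), , drop = FALSE]
  if (nrow(target) == 1L) target <- target[rep(1L, n), , drop = FALSE]
  if (any(target[, 3] <= 0) || any(target[, 4] <= 0))
    stop("target boxes must have positive width and height")
  ciou_terms(pred, target, eps)$loss
}

# Shared computation for ciou_loss and ciou_grad.
ciou_terms <- function(p, t, eps = 1e-9) {
  cp <- box_corners(p); ct <- box_corners(t)
  iw <- pmin(cp[, 3], ct[, 3]) - pmax(cp[, 1], ct[, 1])
  ih <- pmin(cp[, 4], ct[, 4]) - pmax(cp[, 2], ct[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  ap <- p[, 3] * p[, 4]; at <- t[, 3] * t[, 4]
  u <- ap + at - inter
  iou <- inter / pmax(u, eps)
  cw <- pmax(cp[, 3], ct[, 3]) - pmin(cp[, 1], ct[, 1])
  ch <- pmax(cp[, 4], ct[, 4]) - pmin(cp[, 2], ct[, 2])
  c2 <- cw^2 + ch^2 + eps
  rho2 <- (p[, 1] - t[, 1])^2 + (p[, 2] - t[, 2])^2
  k <- 4 / pi^2
  q <- atan(t[, 3] / t[, 4]) - atan(p[, 3] / pmax(p[, 4], eps))
  v <- k * q^2
  denom <- (1 - iou) + v
  alpha <- ifelse(denom > eps, v / denom, 0)
  loss <- unname(1 - iou + rho2 / c2 + alpha * v)
  list(loss = loss, iou = iou, inter = inter, u = u, iw = iw, ih = ih,
       cw = cw, ch = ch, c2 = c2, rho2 = rho2, q = q, v = v,
       cp = cp, ct = ct)
}

#' Gradient of the CIoU loss w.r.t. the predicted box
#'
#' Analytic gradient of [ciou_loss()] in `(cx, cy, w, h)` of `pred`,
#' including the dependence of `alpha` on the prediction. Defined almost
#' everywhere; at corner ties a subgradient is returned.
#'
#' @inheritParams ciou_loss
#' @return Matrix `n x 4` with columns `d_cx, d_cy, d_w, d_h`.
#' @export
ciou_grad <- function(pred, target, eps = 1e-9) {
  p <- rbind(pred); t <- rbind(target)
  n <- max(nrow(p), nrow(t))
  if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(t) == 1L) t <- t[rep(1L, n), , drop = FALSE]
  tm <- ciou_terms(p, t, eps)
  cp <- tm$cp; ct <- tm$ct
  pos <- tm$inter > 0

  # dI in (x, y, w, h); zero when boxes are disjoint
  min_x2 <- as.numeric(cp[, 3] <= ct[, 3]) # pred provides min(x2)
  max_x1 <- as.numeric(cp[, 1] >= ct[, 1]) # pred provides max(x1)
  min_y2 <- as.numeric(cp[, 4] <= ct[, 4])
  max_y1 <- as.numeric(cp[, 2] >= ct[, 2])
  diw_dx <- min_x2 - max_x1
  diw_dw <- (min_x2 + max_x1) / 2
  dih_dy <- min_y2 - max_y1
  dih_dh <- (min_y2 + max_y1) / 2
  dI <- cbind(tm$ih * diw_dx, tm$iw * dih_dy, tm$ih * diw_dw, tm$iw * dih_dh)
  dI[!pos, ] <- 0
  dA <- cbind(0, 0, p[, 4], p[, 3])
  dU <- dA - dI
  u2 <- pmax(tm$u, eps)^2
  dIoU <- (dI * tm$u - tm$inter * dU) / u2

  # enclosing-box diagonal
  max_x2 <- as.numeric(cp[, 3] >= ct[, 3])
  min_x1 <- as.numeric(cp[, 1] <= ct[, 1])
  max_y2 <- as.numeric(cp[, 4] >= ct[, 4])
  min_y1 <- as.numeric(cp[, 2] <= ct[, 2])
  dcw <- cbind(max_x2 - min_x1, 0, (max_x2 + min_x1) / 2, 0)
  dch <- cbind(0, max_y2 - min_y1, 0, (max_y2 + min_y1) / 2)
  dc2 <- 2 * tm$cw * dcw + 2 * tm$ch * dch
  drho2 <- cbind(2 * (p[, 1] - t[, 1]), 2 * (p[, 2] - t[, 2]), 0, 0)
  dpen <- (drho2 * tm$c2 - tm$rho2 * dc2) / tm$c2^2

  # aspect-ratio term with alpha's full dependence:
  # alpha*v = v^2 / D, D = (1 - IoU) + v
  k <- 4 / pi^2
  wh2 <- p[, 3]^2 + pmax(p[, 4], eps)^2
  dv <- cbind(0, 0, -2 * k * tm$q * p[, 4] / wh2, 2 * k * tm$q * p[, 3] / wh2)
  D <- pmax((1 - tm$iou) + tm$v, eps)
  dav <- (2 * tm$v * dv * D - tm$v^2 * (dv - dIoU)) / D^2

  g <- -dIoU + dpen + dav
  colnames(g) <- c("d_cx", "d_cy", "d_w", "d_h")
  g
}

#' Non-maximum suppression
#'
#' Greedy, per-class, hard suppression: detections are visited in order of
#' descending confidence (ties broken by smaller class id, then input order);
#' a detection is dropped if it overlaps an already-kept detection of the
#' same class with IoU above `iou_threshold`.
#'
#' @param dets Data frame with columns `cx, cy, w, h, confidence, class_id`.
#' @param iou_threshold Overlap above which a same-class box is suppressed.
#' @param score_threshold Detections below this confidence are discarded.
#' @return The surviving rows, sorted by confidence descending.
#' @export
nms <- function(dets, iou_threshold = 0.65, score_threshold = 0.001) {
  if (is.null(dets) || nrow(dets) == 0L) return(dets[0L, , drop = FALSE])
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1)
  dets <- dets[dets$confidence >= score_threshold, , drop = FALSE]
  if (nrow(dets) == 0L) return(dets)
  ord <- order(-dets$confidence, dets$class_id, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  boxes <- as.matrix(dets[, c("cx", "cy", "w", "h")])
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    prev <- which(keep & dets$class_id == dets$class_id[i])
    if (!length(prev) ||
        all(iou(boxes[prev, , drop = FALSE], boxes[i, , drop = FALSE]) <= iou_threshold))
      keep[i] <- TRUE
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Anchor estimation and anchor sets
# ---------------------------------------------------------------------------

#' Anchor set
#'
#' An ordered list of (w, h) prior pairs, area-sorted ascending and split
#' evenly across the head levels (finest level gets the smallest anchors).
#'
#' @param anchors Matrix with columns `w, h` (positive).
#' @param levels Number of head levels.
#' @return An `anchor_set` object.
#' @export
anchor_set <- function(anchors, levels = 4L) {
  anchors <- rbind(anchors)
  colnames(anchors) <- c("w", "h")
  if (any(anchors <= 0)) stop("anchor dimensions must be positive")
  if (nrow(anchors) %% levels != 0L)
    stop("anchor count must be a multiple of the number of levels")
  anchors <- anchors[order(anchors[, 1] * anchors[, 2]), , drop = FALSE]
  structure(list(anchors = anchors, levels = as.integer(levels),
                 per_level = nrow(anchors) %/% levels),
            class = "anchor_set")
}

#' Anchors of one head level
#' @param aset An [anchor_set()].
#' @param level Head level, 1 = finest stride.
#' @return Matrix `per_level x 2`.
#' @export
level_anchors <- function(aset, level) {
  i <- (level - 1L) * aset$per_level + seq_len(aset$per_level)
  aset$anchors[i, , drop = FALSE]
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set: %d anchors, %d levels x %d>\n",
              nrow(x$anchors), x$levels, x$per_level))
  print(x$anchors)
  invisible(x)
}

#' Estimate anchor priors by k-means
#'
#' Lloyd's algorithm with k-means++ seeding on box (w, h) pairs. The default
#' distance is Euclidean; `metric = "iou"` assigns each box to the centroid
#' with the largest IoU when both are anchored at a common center (the
#' 1 - IoU distance commonly used for anchor estimation).
#'
#' @param boxes Matrix with columns `w, h` (one row per ground-truth box).
#' @param k Number of anchors.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param metric `"euclidean"` or `"iou"`.
#' @param levels Head levels for the returned [anchor_set()].
#' @param max_iter Lloyd iteration cap.
#' @return An [anchor_set()]; attribute `objective` holds the per-iteration
#'   mean within-cluster distance (non-increasing).
#' @export
kmeans_anchors <- function(boxes, k, seed = 1L, metric = c("euclidean", "iou"),
                           levels = 4L, max_iter = 100L) {
  metric <- match.arg(metric)
  boxes <- rbind(boxes)[, 1:2, drop = FALSE]
  if (k < 1L) stop("k must be >= 1")
  if (nrow(boxes) < k) stop("insufficient boxes: need at least k = ", k)
  dist_fn <- function(b, cent) {
    # n x k distance matrix
    if (metric == "euclidean") {
      outer(b[, 1], cent[, 1], "-")^2 + outer(b[, 2], cent[, 2], "-")^2
    } else {
      iw <- outer(b[, 1], cent[, 1], pmin); ih <- outer(b[, 2], cent[, 2], pmin)
      inter <- iw * ih
      1 - inter / (outer(b[, 1] * b[, 2], cent[, 1] * cent[, 2], "+") - inter)
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  # k-means++ seeding
  cent <- boxes[sample.int(nrow(boxes), 1L), , drop = FALSE]
  while (nrow(cent) < k) {
    d2 <- do.call(pmin, as.data.frame(dist_fn(boxes, cent)))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / length(d2), length(d2))
    cent <- rbind(cent, boxes[sample.int(nrow(boxes), 1L, prob = p), ])
  }
  obj <- numeric(0)
  assign_prev <- NULL
  for (it in seq_len(max_iter)) {
    d <- dist_fn(boxes, cent)
    a <- max.col(-d, ties.method = "first")
    obj <- c(obj, mean(d[cbind(seq_len(nrow(boxes)), a)]))
    if (identical(a, assign_prev)) break
    assign_prev <- a
    for (j in seq_len(k)) {
      sel <- a == j
      if (any(sel)) cent[j, ] <- colMeans(boxes[sel, , drop = FALSE])
    }
  }
  out <- anchor_set(cent, levels = if (k %% levels == 0L) levels else 1L)
  attr(out, "objective") <- obj
  out
}

#' Read / write anchor files
#'
#' Plain text, one `w,h` pair per line, area-ascending.
#' @param path File path.
#' @param levels Head levels for the returned [anchor_set()].
#' @export
read_anchors <- function(path, levels = 4L) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
  anchor_set(parts, levels = levels)
}

#' @rdname read_anchors
#' @param aset An [anchor_set()].
#' @export
write_anchors <- function(aset, path) {
  writeLines(sprintf("%g,%g", aset$anchors[, 1], aset$anchors[, 2]), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Head decoding
# ---------------------------------------------------------------------------

#' Grid specification of one head level
#' @param stride Pixels per cell.
#' @param grid_h,grid_w Cell counts.
#' @param level Head level index.
#' @export
grid_spec <- function(stride, grid_h, grid_w, level = 1L) {
  stopifnot(stride > 0, grid_h >= 1, grid_w >= 1)
  structure(list(stride = stride, grid_h = as.integer(grid_h),
                 grid_w = as.integer(grid_w), level = as.integer(level)),
            class = "grid_spec")
}

#' Decode raw head predictions into detections
#'
#' Power decode of the YOLOv4/YOLOR family: for cell `(r, c)` (0-based) and
#' anchor `(aw, ah)`,
#' `cx = (2*sigma(tx) - 0.5 + c) * stride`, `cy = (2*sigma(ty) - 0.5 + r) * stride`,
#' `w = (2*sigma(tw))^2 * aw`, `h = (2*sigma(th))^2 * ah`; objectness and
#' class scores are sigmoids of their logits.
#'
#' @param raw Array `[per_level, grid_h, grid_w, 5 + C]` of logits
#'   `(tx, ty, tw, th, obj, cls...)` for one image and one level.
#' @param anchors Matrix `per_level x 2` of (w, h) anchors for this level.
#' @param grid A [grid_spec()].
#' @return Data frame with columns `cx, cy, w, h, confidence, class_id` and
#'   attribute `class_scores` (matrix `n x C`). `confidence` is the
#'   objectness score; `class_id` is the argmax class (1-based).
#' @export
decode_head <- function(raw, anchors, grid) {
  d <- dim(raw)
  anchors <- rbind(anchors)
  if (length(d) != 4L)
    stop("expected raw dims [per_level, grid_h, grid_w, 5+C], got rank ", length(d))
  if (d[1] != nrow(anchors) || d[2] != grid$grid_h || d[3] != grid$grid_w)
    stop(sprintf("shape mismatch: expected [%d, %d, %d, 5+C], got [%s]",
                 nrow(anchors), grid$grid_h, grid$grid_w,
                 paste(d, collapse = ", ")))
  C <- d[4] - 5L
  if (C < 1L) stop("raw last dim must be 5 + C with C >= 1")
  a <- slice.index(raw[, , , 1, drop = FALSE], 1)
  r <- slice.index(raw[, , , 1, drop = FALSE], 2) - 1L
  cc <- slice.index(raw[, , , 1, drop = FALSE], 3) - 1L
  s <- function(i) stats::plogis(as.vector(raw[, , , i]))
  cx <- (2 * s(1) - 0.5 + as.vector(cc)) * grid$stride
  cy <- (2 * s(2) - 0.5 + as.vector(r)) * grid$stride
  w <- (2 * s(3))^2 * anchors[as.vector(a), 1]
  h <- (2 * s(4))^2 * anchors[as.vector(a), 2]
  obj <- s(5)
  cls <- vapply(seq_len(C), function(j) s(5L + j), numeric(length(obj)))
  cls <- matrix(cls, ncol = C)
  out <- data.frame(cx = cx, cy = cy, w = w, h = h, confidence = obj,
                    class_id = max.col(cls, ties.method = "first"))
  attr(out, "class_scores") <- cls
  out
}
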