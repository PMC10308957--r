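# ---------------------------------------------------------------------------
# Detection metrics: greedy TP/FP matching, per-class average precision,
# mAP@.5 and mAP@.5:.95, and an FPS harness with an injectable clock.
# ---------------------------------------------------------------------------

#' Match detections of one image and class to ground truths
#'
#' Greedy one-to-one matching in descending confidence order: each detection
#' takes the unmatched ground truth with the highest IoU, provided that IoU
#' is at least `iou_thr` (a boundary tie counts as a match). Each ground
#' truth is consumed at most once; leftover detections are false positives,
#' leftover ground truths false negatives.
#'
#' @param dets Detection data frame (columns `cx, cy, w, h, confidence`),
#'   same image and class.
#' @param gts Ground-truth box matrix or data frame (columns `cx, cy, w, h`).
#' @param iou_thr IoU threshold.
#' @return Logical TP flag per detection, in descending-confidence order;
#'   attribute `order` gives the permutation applied.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  n <- if (is.null(dets)) 0L else nrow(dets)
  if (n == 0L) {
    out <- logical(0); attr(out, "order") <- integer(0); return(out)
  }
  ord <- order(-dets$confidence)
  gm <- if (is.null(gts)) matrix(numeric(0), 0, 4) else
    as.matrix(rbind(gts)[, c("cx", "cy", "w", "h"), drop = FALSE])
  used <- logical(nrow(gm))
  tp <- logical(n)
  db <- as.matrix(dets[, c("cx", "cy", "w", "h")])
  for (i in ord) {
    if (!nrow(gm)) break
    ious <- iou(gm, db[i, , drop = FALSE])
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      tp[i] <- TRUE; used[j] <- TRUE
    }
  }
  out <- tp[ord]
  attr(out, "order") <- ord
  out
}

#' Average precision from ordered TP flags
#'
#' Area under the precision-recall sweep. The default is COCO-style 101-point
#' interpolation: `AP = mean over r in {0, 0.01, ..., 1} of max precision at
#' recall >= r`; `interpolation = "11"` gives the older 11-point variant.
#'
#' @param flags Logical TP flags ordered by descending confidence (across
#'   all images).
#' @param n_gt Number of ground truths of the class.
#' @param interpolation `"101"` or `"11"`.
#' @return AP in `[0, 1]`; 0 when `n_gt > 0` with no TP; `NA` when
#'   `n_gt == 0` (class excluded from the mean).
#' @export
average_precision <- function(flags, n_gt, interpolation = c("101", "11")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0L) return(NA_real_)
  if (!length(flags) || !any(flags)) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  rgrid <- if (interpolation == "101") seq(0, 1, by = 0.01) else seq(0, 1, by = 0.1)
  # precision envelope: max precision at any recall >= r
  ap <- 0
  for (r in rgrid) {
    sel <- recall >= r
    ap <- ap + if (any(sel)) max(precision[sel]) else 0
  }
  ap / length(rgrid)
}

#' Mean average precision over evaluated classes
#' @param per_class_ap AP values (NA entries — classes absent from the
#'   ground truth — are excluded).
#' @export
mean_ap <- function(per_class_ap) {
  ap <- per_class_ap[!is.na(per_class_ap)]
  if (!length(ap)) stop("no evaluated classes")
  mean(ap)
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP at each IoU threshold in `thresholds`, `map50`
#' (mean AP at IoU 0.5) and `map5095` (mean over thresholds 0.5 to 0.95 in
#' steps of 0.05). Classes with no ground-truth instance are excluded from
#' the means.
#'
#' @param dets_by_image List over images of detection data frames
#'   (`cx, cy, w, h, confidence, class_id`).
#' @param gts_by_image List over images of ground-truth data frames
#'   (`class_id, cx, cy, w, h`).
#' @param num_classes Number of classes.
#' @param thresholds IoU thresholds.
#' @param interpolation AP interpolation scheme.
#' @return An `eval_result`: list with `per_class` (classes x thresholds AP
#'   matrix), `map50`, `map5095`, and per-class TP/FP/FN counts at IoU 0.5.
#' @export
evaluate_detections <- function(dets_by_image, gts_by_image, num_classes,
                                thresholds = seq(0.5, 0.95, by = 0.05),
                                interpolation = "101") {
  stopifnot(length(dets_by_image) == length(gts_by_image))
  ap <- matrix(NA_real_, num_classes, length(thresholds),
               dimnames = list(NULL, sprintf("iou%.2f", thresholds)))
  counts <- data.frame(class_id = seq_len(num_classes), tp = 0L, fp = 0L,
                       fn = 0L, n_gt = 0L)
  for (cl in seq_len(num_classes)) {
    n_gt <- sum(vapply(gts_by_image, function(g)
      if (is.null(g) || !nrow(g)) 0L else sum(g$class_id == cl), integer(1)))
    counts$n_gt[cl] <- n_gt
    # gather class detections across images with image index
    recs <- NULL
    for (im in seq_along(dets_by_image)) {
      d <- dets_by_image[[im]]
      if (is.null(d) || !nrow(d)) next
      d <- d[d$class_id == cl, , drop = FALSE]
      if (!nrow(d)) next
      d$image <- im
      recs <- rbind(recs, d)
    }
    if (n_gt == 0L) next
    for (ti in seq_along(thresholds)) {
      if (is.null(recs) || !nrow(recs)) { ap[cl, ti] <- 0; next }
      flags <- logical(nrow(recs))
      for (im in unique(recs$image)) {
        sel <- which(recs$image == im)
        g <- gts_by_image[[im]]
        g <- if (is.null(g) || !nrow(g)) NULL else
          g[g$class_id == cl, , drop = FALSE]
        m <- match_detections(recs[sel, , drop = FALSE], g, thresholds[ti])
        flags[sel[attr(m, "order")]] <- m
      }
      ordg <- order(-recs$confidence)
      ap[cl, ti] <- average_precision(flags[ordg], n_gt, interpolation)
      if (abs(thresholds[ti] - 0.5) < 1e-9) {
        counts$tp[cl] <- sum(flags)
        counts$fp[cl] <- sum(!flags)
        counts$fn[cl] <- n_gt - sum(flags)
      }
    }
  }
  i50 <- which(abs(thresholds - 0.5) < 1e-9)
  maps <- apply(ap, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v)) mean(v) else NA_real_
  })
  structure(list(per_class = ap, thresholds = thresholds,
                 map50 = if (length(i50)) unname(maps[i50]) else NA_real_,
                 map5095 = mean(maps, na.rm = TRUE), counts = counts),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: mAP@.5 = %.4f | mAP@.5:.95 = %.4f | %d classes evaluated\n",
              x$map50, x$map5095, sum(!is.na(x$per_class[, 1]))))
  invisible(x)
}

#' mAP averaged over the 0.5:0.95 threshold range
#'
#' Convenience wrapper: `(1/10) * sum over thresholds {0.50, ..., 0.95}` of
#' mAP at that threshold.
#' @inheritParams evaluate_detections
#' @export
map_range <- function(dets_by_image, gts_by_image, num_classes,
                      interpolation = "101") {
  evaluate_detections(dets_by_image, gts_by_image, num_classes,
                      interpolation = interpolation)$map5095
}

#' Measure frames per second of the full pipeline
#'
#' Runs forward pass, decode and NMS per image and reports
#' `N / elapsed seconds`. The clock is injectable for testing; wall-clock
#' results are hardware-dependent and reported with environment metadata.
#'
#' @param model Materialized `ld_model`.
#' @param images List of `[H, W, 3]` arrays.
#' @param clock Zero-argument function returning seconds.
#' @return FPS (numeric) with attribute `meta` (R version, platform, n).
#' @export
measure_fps <- function(model, images,
                        clock = function() proc.time()[["elapsed"]]) {
  if (!length(images)) stop("zero images")
  t0 <- clock()
  for (img in images) ld_detect(model, img)
  dt <- clock() - t0
  fps <- length(images) / max(dt, .Machine$double.eps)
  attr(fps, "meta") <- list(n = length(images), elapsed = dt,
                            platform = R.version$platform,
                            r_version = R.version.string)
  fps
}
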