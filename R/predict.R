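# ---------------------------------------------------------------------------
# Inference helpers: forward pass, head reshaping, detection pipeline.
# ---------------------------------------------------------------------------

# [g, g, 3*(5+C)] -> [3, g, g, 5+C] (anchor-major head layout)
head_raw_split <- function(raw_n, per_level, C) {
  d <- dim(raw_n)
  aperm(array(raw_n, c(d[1], d[2], 5L + C, per_level)), c(4, 1, 2, 3))
}

check_input_size <- function(model, X) {
  ms <- max(model$meta$strides)
  d <- dim(X)
  if (any(d[1:2] %% ms != 0))
    stop("input spatial dims must be multiples of ", ms,
         " (got ", d[1], "x", d[2], ")")
}

# Forward a batch, returning the 4 per-level raw arrays [g, g, 3*(5+C), N]
# (and the full activation cache when keep_acts = TRUE).
ld_forward <- function(model, X, keep_acts = FALSE) {
  check_input_size(model, X)
  fw <- nn_forward(model, X)
  out <- list(levels = fw$acts[model$head_ids])
  if (keep_acts) out$fw <- fw
  out
}

#' Run the full detection pipeline on images
#'
#' Forward pass, YOLO-style decode at each head level, score composition
#' (objectness times class score) and per-class NMS.
#'
#' @param model A materialized `ld_model`.
#' @param X Image array `[H, W, 3, N]` or a single image `[H, W, 3]`.
#' @param iou_threshold,score_threshold NMS parameters.
#' @param max_det Keep at most this many detections per image.
#' @return A list (one element per image) of detection data frames with
#'   columns `cx, cy, w, h, confidence, class_id`.
#' @export
ld_detect <- function(model, X, iou_threshold = 0.65, score_threshold = 0.001,
                      max_det = 300L) {
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  pr <- ld_forward(model, X)
  N <- dim(X)[4]
  C <- model$meta$num_classes
  pl <- model$meta$per_level
  lapply(seq_len(N), function(n) {
    dets <- NULL
    for (l in seq_along(pr$levels)) {
      raw_n <- pr$levels[[l]][, , , n, drop = FALSE]
      dim(raw_n) <- dim(raw_n)[1:3]
      arr <- head_raw_split(raw_n, pl, C)
      dec <- decode_head(arr, level_anchors(model$meta$anchors, l),
                         grid_spec(model$meta$strides[l], dim(arr)[2],
                                   dim(arr)[3], l))
      cls <- attr(dec, "class_scores")
      best <- max.col(cls, ties.method = "first")
      dec$class_id <- best
      dec$confidence <- dec$confidence * cls[cbind(seq_len(nrow(cls)), best)]
      dets <- rbind(dets, dec)
    }
    out <- nms(dets, iou_threshold, score_threshold)
    utils::head(out, max_det)
  })
}
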