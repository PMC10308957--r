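# ---------------------------------------------------------------------------
# Target assignment and the two training loops: the plain (detection-module
# only) baseline and the multistage-distilled trainer with a frozen teacher.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Optimizer defaults follow the reference recipe: SGD with momentum 0.937
#' and weight decay 0.0005; the learning-rate schedule (linear warmup then
#' cosine decay from `lr0`) is this package's choice. `epochs` and
#' `batch_size` default to desk-scale values; the full-scale reference values
#' (300 epochs, batch 12) live in the config file defaults.
#'
#' @param epochs Training epochs.
#' @param batch_size Images per step.
#' @param lr0 Peak learning rate.
#' @param lr_final_frac Final LR as a fraction of `lr0` (cosine floor).
#' @param warmup_epochs Linear warmup length (may be fractional).
#' @param momentum,weight_decay SGD parameters.
#' @param seed RNG seed; recorded in the history.
#' @param dm_weights,head_weights [distill_weights()] for the supervised and
#'   head-distillation losses.
#' @param stage_weights [stage_loss_weights()] (alpha, beta, theta, gamma).
#' @param distiller [distiller_config()] for the backbone/neck distillers.
#' @param ratio_threshold Anchor-matching width/height ratio bound.
#' @param head_positions `"all"` (dense head distillation) or `"positive"`.
#' @export
train_config <- function(epochs = 16L, batch_size = 12L, lr0 = 0.01,
                         lr_final_frac = 0.05, warmup_epochs = 2,
                         momentum = 0.937, weight_decay = 5e-4, seed = 1L,
                         dm_weights = distill_weights(),
                         head_weights = distill_weights(),
                         stage_weights = stage_loss_weights(),
                         distiller = distiller_config(),
                         ratio_threshold = 4.0, clip_norm = 5,
                         head_positions = c("all", "positive")) {
  stopifnot(epochs >= 0, batch_size >= 1, momentum >= 0, momentum < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, lr_final_frac = lr_final_frac,
                 warmup_epochs = warmup_epochs, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 dm_weights = dm_weights, head_weights = head_weights,
                 stage_weights = stage_weights, distiller = distiller,
                 ratio_threshold = ratio_threshold, clip_norm = clip_norm,
                 head_positions = match.arg(head_positions)),
            class = "train_config")
}

#' Assign ground truths to (anchor, cell, level) positions
#'
#' Ratio-based multi-anchor matching: a ground truth matches an anchor when
#' `max(w/aw, aw/w, h/ah, ah/h) < ratio_threshold`; it is placed in the cell
#' containing its center plus the nearest horizontal and vertical neighbor
#' cells. Conflicting claims on a position keep the first ground truth
#' (deterministic in input order).
#'
#' @param gts Data frame with columns `class_id, cx, cy, w, h`.
#' @param anchors An [anchor_set()].
#' @param grids List of [grid_spec()]s, one per level.
#' @param ratio_threshold Matching bound (exclusive).
#' @return Data frame with columns `level, anchor, row, col, gt, class_id`
#'   (cells 1-based) — zero rows when nothing matches.
#' @export
assign_targets <- function(gts, anchors, grids, ratio_threshold = 4.0) {
  empty <- data.frame(level = integer(0), anchor = integer(0),
                      row = integer(0), col = integer(0), gt = integer(0),
                      class_id = integer(0))
  if (is.null(gts) || nrow(gts) == 0L) return(empty)
  if (any(gts$w <= 0 | gts$h <= 0)) {
    warning("dropping zero-area ground-truth box (run label cleaning)")
    gts <- gts[gts$w > 0 & gts$h > 0, , drop = FALSE]
    if (nrow(gts) == 0L) return(empty)
  }
  out <- vector("list", 64L); nout <- 0L
  taken <- new.env(parent = emptyenv())
  for (gi in seq_len(nrow(gts))) {
    for (l in seq_along(grids)) {
      g <- grids[[l]]
      la <- level_anchors(anchors, l)
      gx <- gts$cx[gi] / g$stride; gy <- gts$cy[gi] / g$stride
      col0 <- floor(gx); row0 <- floor(gy)
      cols <- c(col0, if (gx - col0 < 0.5) col0 - 1 else col0 + 1)
      rows <- c(row0, if (gy - row0 < 0.5) row0 - 1 else row0 + 1)
      cells <- rbind(c(row0, col0), c(row0, cols[2]), c(rows[2], col0))
      cells <- cells[cells[, 1] >= 0 & cells[, 1] < g$grid_h &
                     cells[, 2] >= 0 & cells[, 2] < g$grid_w, , drop = FALSE]
      for (a in seq_len(nrow(la))) {
        r <- max(gts$w[gi] / la[a, 1], la[a, 1] / gts$w[gi],
                 gts$h[gi] / la[a, 2], la[a, 2] / gts$h[gi])
        if (r >= ratio_threshold) next
        for (ci in seq_len(nrow(cells))) {
          key <- paste(l, a, cells[ci, 1], cells[ci, 2], sep = "_")
          if (!is.null(taken[[key]])) next
          taken[[key]] <- TRUE
          nout <- nout + 1L
          if (nout > length(out)) out <- c(out, vector("list", length(out)))
          out[[nout]] <- c(l, a, cells[ci, 1] + 1L, cells[ci, 2] + 1L, gi,
                           gts$class_id[gi])
        }
      }
    }
  }
  if (nout == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(nout)])
  data.frame(level = m[, 1], anchor = m[, 2], row = m[, 3], col = m[, 4],
             gt = m[, 5], class_id = m[, 6])
}

#' Encode a ground-truth box into head logits
#'
#' Inverse of the [decode_head()] transform at a given (anchor, cell, level):
#' returns `(tx, ty, tw, th)` such that decoding reproduces the box exactly.
#'
#' @param box Center-form box (single row).
#' @param anchor `(w, h)` anchor pair.
#' @param row,col 1-based cell indices.
#' @param stride Level stride.
#' @export
encode_box <- function(box, anchor, row, col, stride) {
  box <- rbind(box)
  gx <- box[, 1] / stride; gy <- box[, 2] / stride
  sx <- (gx - (col - 1L) + 0.5) / 2; sy <- (gy - (row - 1L) + 0.5) / 2
  sw <- sqrt(box[, 3] / anchor[1]) / 2; sh <- sqrt(box[, 4] / anchor[2]) / 2
  if (any(c(sx, sy, sw, sh) <= 0 | c(sx, sy, sw, sh) >= 1))
    stop("box not encodable at this (anchor, cell): logits would be infinite")
  cbind(tx = stats::qlogis(sx), ty = stats::qlogis(sy),
        tw = stats::qlogis(sw), th = stats::qlogis(sh))
}

model_grids <- function(model, input_size) {
  lapply(seq_along(model$meta$strides), function(l) {
    s <- model$meta$strides[l]
    grid_spec(s, input_size[1] %/% s, input_size[2] %/% s, l)
  })
}

sigmoid <- stats::plogis

# --- supervised (detection-module) loss and gradient -----------------------
# raws: list over levels of [g, g, 3*(5+C), B]; assigns: list over images of
# assignment data frames; gts: list over images of instance data frames.
# Returns the detection-module loss (cls and box terms over positive
# positions, objectness over every position) and per-level logit gradients.
dm_loss_grad <- function(raws, assigns, gts, model, w, want_grad = TRUE) {
  C <- model$meta$num_classes; pl <- model$meta$per_level
  B <- dim(raws[[1]])[4]
  obj_ch <- (seq_len(pl) - 1L) * (5L + C) + 5L
  grads <- if (want_grad) lapply(raws, function(r) array(0, dim(r)))
  # YOLO-family normalization: per-level means, objectness balanced toward
  # the fine levels, and gradients scaled by the batch size so the step
  # magnitude is batch-invariant.
  balance <- c(4.0, 1.0, 0.4, 0.1)
  loss_obj <- 0; loss_cls <- 0; loss_box <- 0
  for (l in seq_along(raws)) {
    la <- level_anchors(model$meta$anchors, l)
    stride <- model$meta$strides[l]
    # objectness: dense BCE over every position of this level
    z <- raws[[l]][, , obj_ch, , drop = FALSE]
    p <- sigmoid(z)
    y <- array(0, dim(z))
    for (b in seq_len(B)) {
      A <- assigns[[b]]; A <- A[A$level == l, , drop = FALSE]
      if (nrow(A)) y[cbind(A$row, A$col, A$anchor, b)] <- 1
    }
    n_l <- length(z)
    loss_obj <- loss_obj +
      w$w2 * balance[l] * sum(-(y * log(pmax(p, 1e-12)) +
                                (1 - y) * log(pmax(1 - p, 1e-12)))) / n_l
    if (want_grad)
      grads[[l]][, , obj_ch, ] <- w$w2 * balance[l] * B * (p - y) / n_l
    # class scores and boxes at this level's positive positions
    npos_l <- sum(vapply(assigns, function(A)
      sum(A$level == l), integer(1)))
    if (npos_l == 0L) next
    for (b in seq_len(B)) {
      A <- assigns[[b]]; A <- A[A$level == l, , drop = FALSE]
      if (!nrow(A)) next
      base <- (A$anchor - 1L) * (5L + C)
      for (j in seq_len(C)) {
        idx <- cbind(A$row, A$col, base + 5L + j, b)
        z <- raws[[l]][idx]; p <- sigmoid(z)
        yj <- as.numeric(A$class_id == j)
        loss_cls <- loss_cls + w$w1 * sum(-(yj * log(pmax(p, 1e-12)) +
                    (1 - yj) * log(pmax(1 - p, 1e-12)))) / (npos_l * C)
        if (want_grad)
          grads[[l]][idx] <- grads[[l]][idx] +
            w$w1 * B * (p - yj) / (npos_l * C)
      }
      zs <- matrix(vapply(1:4, function(j)
        raws[[l]][cbind(A$row, A$col, base + j, b)], numeric(nrow(A))),
        ncol = 4)
      ss <- sigmoid(zs)
      aw <- la[A$anchor, 1]; ah <- la[A$anchor, 2]
      bx <- cbind((2 * ss[, 1] - 0.5 + (A$col - 1L)) * stride,
                  (2 * ss[, 2] - 0.5 + (A$row - 1L)) * stride,
                  (2 * ss[, 3])^2 * aw, (2 * ss[, 4])^2 * ah)
      tb <- as.matrix(gts[[b]][A$gt, c("cx", "cy", "w", "h")])
      loss_box <- loss_box + w$w3 * sum(ciou_loss(bx, tb)) / npos_l
      if (want_grad) {
        cg <- ciou_grad(bx, tb) * (w$w3 * B / npos_l)
        dsig <- ss * (1 - ss)
        dt <- cbind(cg[, 1] * 2 * dsig[, 1] * stride,
                    cg[, 2] * 2 * dsig[, 2] * stride,
                    cg[, 3] * 8 * ss[, 3] * dsig[, 3] * aw,
                    cg[, 4] * 8 * ss[, 4] * dsig[, 4] * ah)
        for (j in 1:4) {
          idx <- cbind(A$row, A$col, base + j, b)
          grads[[l]][idx] <- grads[[l]][idx] + dt[, j]
        }
      }
    }
  }
  list(loss = loss_obj + loss_cls + loss_box, grads = grads)
}

# --- head-stage distillation loss and gradient ------------------------------
# Dense over all aligned positions (or restricted to label positives):
# DKT on class scores, soft cross-entropy on objectness, CIoU between the
# decoded student and teacher boxes.
head_loss_grad <- function(s_raws, t_raws, assigns, model, w,
                           positions = "all", want_grad = TRUE) {
  C <- model$meta$num_classes; pl <- model$meta$per_level
  B <- dim(s_raws[[1]])[4]
  grads <- if (want_grad) lapply(s_raws, function(r) array(0, dim(r)))
  cls_ch <- as.vector(vapply(seq_len(pl), function(a)
    (a - 1L) * (5L + C) + 5L + seq_len(C), integer(C)))
  obj_ch <- (seq_len(pl) - 1L) * (5L + C) + 5L
  n_cls <- 0; n_obj <- 0; sum_cls <- 0; sum_obj <- 0
  box_loss <- 0; n_box <- 0
  eps <- 1e-12
  for (l in seq_along(s_raws)) {
    dimr <- dim(s_raws[[l]])
    keep <- NULL
    if (positions == "positive") {
      keep <- array(FALSE, c(dimr[1], dimr[2], pl, B))
      for (b in seq_len(B)) {
        A <- assigns[[b]]; A <- A[A$level == l, , drop = FALSE]
        if (nrow(A)) keep[cbind(A$row, A$col, A$anchor, b)] <- TRUE
      }
      if (!any(keep)) next
    }
    sel_arr <- function(x, chs) x[, , chs, , drop = FALSE]
    mask_for <- function(chs) {
      if (is.null(keep)) return(NULL)
      k <- length(chs) / pl
      keep[, , rep(seq_len(pl), each = k), , drop = FALSE]
    }
    # class scores
    ps <- sigmoid(sel_arr(s_raws[[l]], cls_ch))
    pt <- sigmoid(sel_arr(t_raws[[l]], cls_ch))
    mk <- mask_for(cls_ch)
    ce <- -(pt * log(pmax(ps, eps)) + (1 - pt) * log(pmax(1 - ps, eps)))
    if (!is.null(mk)) ce <- ce * mk
    sum_cls <- sum_cls + sum(ce)
    n_cls <- n_cls + if (is.null(mk)) length(ce) else sum(mk)
    if (want_grad) {
      g <- ps - pt
      if (!is.null(mk)) g <- g * mk
      grads[[l]][, , cls_ch, ] <- g # scaled later
    }
    # objectness
    ps <- sigmoid(sel_arr(s_raws[[l]], obj_ch))
    pt <- sigmoid(sel_arr(t_raws[[l]], obj_ch))
    mk <- mask_for(obj_ch)
    ce <- -(pt * log(pmax(ps, eps)) + (1 - pt) * log(pmax(1 - ps, eps)))
    if (!is.null(mk)) ce <- ce * mk
    sum_obj <- sum_obj + sum(ce)
    n_obj <- n_obj + if (is.null(mk)) length(ce) else sum(mk)
    if (want_grad) {
      g <- ps - pt
      if (!is.null(mk)) g <- g * mk
      grads[[l]][, , obj_ch, ] <- g
    }
  }
  # boxes (dense decode, per level/anchor, vectorized over cells and batch)
  box_parts <- vector("list", length(s_raws))
  for (l in seq_along(s_raws)) {
    dimr <- dim(s_raws[[l]])
    la <- level_anchors(model$meta$anchors, l)
    stride <- model$meta$strides[l]
    rows <- slice.index(array(0, c(dimr[1], dimr[2], B)), 1) - 1L
    cols <- slice.index(array(0, c(dimr[1], dimr[2], B)), 2) - 1L
    for (a in seq_len(pl)) {
      base <- (a - 1L) * (5L + C)
      keepv <- NULL
      if (positions == "positive") {
        kv <- array(FALSE, c(dimr[1], dimr[2], B))
        for (b in seq_len(B)) {
          A <- assigns[[b]]
          A <- A[A$level == l & A$anchor == a, , drop = FALSE]
          if (nrow(A)) kv[cbind(A$row, A$col, b)] <- TRUE
        }
        keepv <- as.vector(kv)
        if (!any(keepv)) next
      }
      dec1 <- function(raws) {
        zs <- vapply(1:4, function(j) as.vector(raws[[l]][, , base + j, ]),
                     numeric(dimr[1] * dimr[2] * B))
        zs <- matrix(zs, ncol = 4)
        ss <- sigmoid(zs)
        list(z = zs, s = ss,
             box = cbind((2 * ss[, 1] - 0.5 + as.vector(cols)) * stride,
                         (2 * ss[, 2] - 0.5 + as.vector(rows)) * stride,
                         (2 * ss[, 3])^2 * la[a, 1], (2 * ss[, 4])^2 * la[a, 2]))
      }
      sd <- dec1(s_raws); td <- dec1(t_raws)
      sel <- if (is.null(keepv)) seq_len(nrow(sd$box)) else which(keepv)
      lv <- ciou_loss(sd$box[sel, , drop = FALSE], td$box[sel, , drop = FALSE])
      box_loss <- box_loss + sum(lv)
      n_box <- n_box + length(sel)
      if (want_grad)
        box_parts[[l]] <- c(box_parts[[l]], list(list(
          a = a, sel = sel, sd = sd, td = td)))
    }
  }
  loss <- w$w1 * (if (n_cls > 0) sum_cls / n_cls else 0) +
          w$w2 * (if (n_obj > 0) sum_obj / n_obj else 0) +
          w$w3 * (if (n_box > 0) box_loss / n_box else 0)
  if (want_grad) {
    for (l in seq_along(s_raws)) {
      if (n_cls > 0) grads[[l]][, , cls_ch, ] <- grads[[l]][, , cls_ch, ] * (w$w1 * B / n_cls)
      if (n_obj > 0) grads[[l]][, , obj_ch, ] <- grads[[l]][, , obj_ch, ] * (w$w2 * B / n_obj)
      la <- level_anchors(model$meta$anchors, l)
      stride <- model$meta$strides[l]
      dimr <- dim(s_raws[[l]])
      for (part in box_parts[[l]]) {
        a <- part$a; base <- (a - 1L) * (5L + C)
        sel <- part$sel
        cg <- ciou_grad(part$sd$box[sel, , drop = FALSE],
                        part$td$box[sel, , drop = FALSE]) * (w$w3 * B / n_box)
        ss <- part$sd$s[sel, , drop = FALSE]
        dsig <- ss * (1 - ss)
        dt <- cbind(cg[, 1] * 2 * dsig[, 1] * stride,
                    cg[, 2] * 2 * dsig[, 2] * stride,
                    cg[, 3] * 8 * ss[, 3] * dsig[, 3] * la[a, 1],
                    cg[, 4] * 8 * ss[, 4] * dsig[, 4] * la[a, 2])
        plane <- dimr[1] * dimr[2]
        for (j in 1:4) {
          full <- numeric(plane * dim(s_raws[[l]])[4])
          full[sel] <- dt[, j]
          grads[[l]][, , base + j, ] <- grads[[l]][, , base + j, ] + full
        }
      }
    }
  }
  list(loss = loss, grads = grads)
}

# --- feature (backbone/neck) distillation over a batch ----------------------

make_adapter <- function(c_in, c_out, seed) {
  p <- new.env(parent = emptyenv())
  p$shapes <- list(W = c(1L, 1L, c_in, c_out), b = c_out)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  p$W <- array(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)),
               c(1L, 1L, c_in, c_out))
  p$b <- numeric(c_out)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  p
}

# Loss and gradients for one stage family ("backbone" or "neck") over a
# batch. Returns loss, per-tap student-activation gradients, and updates
# adapter parameter gradients in place.
stage_loss_grad <- function(stage, t_acts, s_acts, session, gts_batch,
                            image_size, want_grad = TRUE, weight = 1) {
  cfg <- session$cfg$distiller
  taps <- paste0(stage, "-", 1:4)
  total <- 0
  tap_grads <- list()
  for (tp in taps) {
    t_feat_b <- t_acts[[session$teacher$taps[[tp]]]]
    s_feat_b <- s_acts[[session$student$taps[[tp]]]]
    ad <- session$adapters[[tp]]
    s_al_b <- if (is.null(ad)) s_feat_b else
      .conv2d_fw(s_feat_b, ad$W, ad$b, 1L, 0L, 1L)
    B <- dim(s_al_b)[4]
    rop <- session$relops[[tp]]
    if (is.null(rop)) {
      rop <- tap_relation_op(cfg, dim(t_feat_b)[3])
      session$relops[[tp]] <- rop
    }
    g_al <- if (want_grad) array(0, dim(s_al_b))
    for (b in seq_len(B)) {
      tap <- feature_tap(tp, array(t_feat_b[, , , b], dim(t_feat_b)[1:3]),
                         array(s_al_b[, , , b], dim(s_al_b)[1:3]),
                         gt_boxes = gts_batch[[b]], image_size = image_size)
      total <- total + (focal_feature_loss(tap, cfg) +
                        cfg$w_global * global_relation_loss(tap, rop)) / B
      if (want_grad)
        g_al[, , , b] <- tap_distill_grad(tap, cfg, rop) * (weight / B)
    }
    if (want_grad) {
      if (is.null(ad)) {
        tap_grads[[as.character(session$student$taps[[tp]])]] <- g_al
      } else {
        bwd <- .conv2d_bw(s_feat_b, ad$W, g_al, 1L, 0L, 1L, TRUE)
        ad$dW <- if (is.null(ad$dW)) bwd$dw else ad$dW + bwd$dw
        ad$db <- if (is.null(ad$db)) bwd$db else ad$db + bwd$db
        tap_grads[[as.character(session$student$taps[[tp]])]] <- bwd$dx
      }
    }
  }
  list(loss = total, tap_grads = tap_grads)
}

adapter_step <- function(session, lr) {
  for (ad in session$adapters) {
    if (is.null(ad$dW)) next
    for (nm in c("W", "b")) {
      g <- ad[[paste0("d", nm)]]
      mnm <- paste0("m_", nm)
      v <- if (is.null(ad[[mnm]])) g else session$cfg$momentum * ad[[mnm]] + g
      ad[[mnm]] <- v
      ad[[nm]] <- ad[[nm]] - lr * v
      ad[[paste0("d", nm)]] <- NULL
    }
  }
}

#' Create a distillation session
#'
#' Pairs a frozen, pretrained teacher with a student, builds the pointwise
#' channel adapters for the feature distillers, and caches the shared
#' relation operators. The teacher receives no parameter updates.
#'
#' @param teacher,student Materialized `ld_model`s with matching tap names.
#' @param cfg A [train_config()].
#' @param input_size Image size `c(H, W)` the session will train on.
#' @export
distill_session <- function(teacher, student, cfg = train_config(),
                            input_size = c(64L, 64L)) {
  missing <- setdiff(names(teacher$taps), names(student$taps))
  if (length(missing))
    stop("student is missing taps: ", paste(missing, collapse = ", "))
  ses <- new.env(parent = emptyenv())
  ses$teacher <- teacher; ses$student <- student; ses$cfg <- cfg
  ses$input_size <- input_size
  ses$adapters <- list(); ses$relops <- list()
  sw <- cfg$stage_weights
  if (sw$alpha > 0 || sw$beta > 0) {
    tshapes <- shape_pass(teacher, input_size)
    sshapes <- shape_pass(student, input_size)
    for (tp in paste0(rep(c("backbone", "neck"), each = 4), "-", 1:4)) {
      ct <- tshapes[[teacher$taps[[tp]]]][3]
      cs <- sshapes[[student$taps[[tp]]]][3]
      if (cs != ct && !cfg$distiller$adapter)
        stop("tap ", tp, ": channel mismatch and adapter disabled")
      if (cs != ct || cfg$distiller$adapter)
        ses$adapters[[tp]] <- make_adapter(cs, ct, cfg$seed + 10000L)
    }
  }
  class(ses) <- "distill_session"
  ses
}

lr_at <- function(cfg, step, steps_total, steps_per_epoch) {
  wsteps <- max(1, round(cfg$warmup_epochs * steps_per_epoch))
  if (step <= wsteps) return(cfg$lr0 * step / wsteps)
  t <- (step - wsteps) / max(1, steps_total - wsteps)
  lrf <- cfg$lr0 * cfg$lr_final_frac
  lrf + 0.5 * (cfg$lr0 - lrf) * (1 + cos(pi * t))
}

batch_tensor <- function(records, idx) {
  d <- dim(records[[idx[1]]]$image)
  X <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (i in seq_along(idx)) X[, , , i] <- records[[idx[i]]]$image
  X
}

# Core loop shared by train_plain and train_distilled. `teacher = NULL`
# trains with the detection-module loss only (still scaled by gamma so the
# plain and gamma-only-distilled runs are step-for-step identical).
train_core <- function(teacher, student, data, cfg) {
  sw <- cfg$stage_weights
  n <- length(data)
  if (n == 0L) stop("empty training set")
  input_size <- dim(data[[1]]$image)[1:2]
  grids <- model_grids(student, input_size)
  assigns <- lapply(data, function(rec)
    assign_targets(rec$instances, student$meta$anchors, grids,
                   cfg$ratio_threshold))
  gts <- lapply(data, function(rec) rec$instances)
  session <- NULL
  use_feat <- !is.null(teacher) && (sw$alpha > 0 || sw$beta > 0)
  use_head <- !is.null(teacher) && sw$theta > 0
  if (!is.null(teacher))
    session <- distill_session(teacher, student, cfg, input_size)
  steps_per_epoch <- max(1L, n %/% cfg$batch_size)
  steps_total <- cfg$epochs * steps_per_epoch
  hist <- vector("list", steps_total)
  set.seed(cfg$seed)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(steps_per_epoch)) {
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      X <- batch_tensor(data, idx)
      s_out <- ld_forward(student, X, keep_acts = TRUE)
      grads <- list()
      add_head_grads <- function(glist, scale = 1) {
        for (l in seq_along(glist)) {
          key <- as.character(student$head_ids[l])
          g <- glist[[l]] * scale
          grads[[key]] <<- if (is.null(grads[[key]])) g else grads[[key]] + g
        }
      }
      dm <- dm_loss_grad(s_out$levels, assigns[idx], gts[idx], student,
                         cfg$dm_weights)
      if (!is.finite(dm$loss))
        stop("non-finite loss_dm at step ", step + 1L)
      if (sw$gamma > 0) add_head_grads(dm$grads, sw$gamma)
      lb <- 0; ln <- 0; lh <- 0
      if (!is.null(teacher) && (use_feat || use_head)) {
        t_fw <- nn_forward(teacher, X)
        if (use_head) {
          hd <- head_loss_grad(s_out$levels, t_fw$acts[teacher$head_ids],
                               assigns[idx], student, cfg$head_weights,
                               cfg$head_positions)
          lh <- hd$loss
          if (!is.finite(lh)) stop("non-finite loss_head at step ", step + 1L)
          add_head_grads(hd$grads, sw$theta)
        }
        if (use_feat) {
          gts_boxes <- lapply(idx, function(i)
            if (nrow(gts[[i]])) as.matrix(gts[[i]][, c("cx", "cy", "w", "h")]))
          if (sw$alpha > 0) {
            sb <- stage_loss_grad("backbone", t_fw$acts, s_out$fw$acts,
                                  session, gts_boxes, input_size,
                                  weight = sw$alpha)
            lb <- sb$loss
            if (!is.finite(lb)) stop("non-finite loss_backbone at step ", step + 1L)
            for (k in names(sb$tap_grads))
              grads[[k]] <- if (is.null(grads[[k]])) sb$tap_grads[[k]]
                            else grads[[k]] + sb$tap_grads[[k]]
          }
          if (sw$beta > 0) {
            sn <- stage_loss_grad("neck", t_fw$acts, s_out$fw$acts,
                                  session, gts_boxes, input_size,
                                  weight = sw$beta)
            ln <- sn$loss
            if (!is.finite(ln)) stop("non-finite loss_neck at step ", step + 1L)
            for (k in names(sn$tap_grads))
              grads[[k]] <- if (is.null(grads[[k]])) sn$tap_grads[[k]]
                            else grads[[k]] + sn$tap_grads[[k]]
          }
        }
      }
      bundle <- total_distill_loss(lb, ln, lh, dm$loss, sw)
      step <- step + 1L
      lr <- lr_at(cfg, step, steps_total, steps_per_epoch)
      if (length(grads)) {
        nn_backward(student, s_out$fw, grads)
        if (is.finite(cfg$clip_norm))
          clip_grads(student, cfg$clip_norm,
                     extra = if (!is.null(session)) session$adapters else list())
        sgd_step(student, lr, cfg$momentum, cfg$weight_decay)
        zero_grads(student)
      }
      if (!is.null(session)) adapter_step(session, lr)
      hist[[step]] <- data.frame(step = step, epoch = ep,
                                 loss_backbone = lb, loss_neck = ln,
                                 loss_head = lh, loss_dm = dm$loss,
                                 total = bundle$total, lr = lr)
    }
  }
  history <- if (step > 0) do.call(rbind, hist[seq_len(step)]) else
    data.frame(step = integer(0), epoch = integer(0), loss_backbone = numeric(0),
               loss_neck = numeric(0), loss_head = numeric(0),
               loss_dm = numeric(0), total = numeric(0), lr = numeric(0))
  list(model = student, history = history, session = session)
}

#' Train a student with the supervised detection loss only
#'
#' The undistilled baseline: optimizes the detection-module loss
#' (class/objectness binary cross-entropy + CIoU box regression), scaled by
#' `gamma` from the stage weights.
#'
#' @param student Materialized `ld_model`.
#' @param data List of records, each `list(image = [H, W, 3] array,
#'   instances = data.frame(class_id, cx, cy, w, h))`.
#' @param cfg A [train_config()].
#' @return List with the trained `model` and the per-step loss `history`.
#' @export
train_plain <- function(student, data, cfg = train_config()) {
  sw <- cfg$stage_weights
  cfg$stage_weights <- stage_loss_weights(0, 0, 0, sw$gamma)
  train_core(NULL, student, data, cfg)
}

#' Train a student under multistage knowledge distillation
#'
#' Freezes the teacher, attaches the backbone/neck feature distillers and
#' the head-stage distiller, and optimizes the combined objective
#' `alpha*backbone + beta*neck + theta*head + gamma*dm`.
#'
#' @param teacher Materialized, pretrained `ld_model` (never updated).
#' @param student Materialized `ld_model` with matching tap names.
#' @inheritParams train_plain
#' @return List with the trained `model`, the per-step `history` of all loss
#'   components, and the `session`.
#' @export
train_distilled <- function(teacher, student, data, cfg = train_config()) {
  h0 <- param_hash(teacher)
  out <- train_core(teacher, student, data, cfg)
  if (!identical(param_hash(teacher), h0))
    stop("teacher freeze contract violated")
  out
}

#' Report which parameter groups receive gradients from one stage
#'
#' Runs a single forward/backward pass with only the named stage's loss
#' enabled and reports the student scopes holding nonzero gradients.
#' Expected scopes: backbone stage -> backbone; neck stage -> backbone +
#' neck; head stage -> backbone + neck + head.
#'
#' @param session A [distill_session()].
#' @param stage `"backbone"`, `"neck"` or `"head"`.
#' @param data Fixture records (a small batch is taken from the front).
#' @param n_images Batch size for the probe.
#' @return List with `stage`, `scopes` (character vector), `expected`, and
#'   `violation` (TRUE when an out-of-scope group holds gradient).
#' @export
gradient_scope_report <- function(session, stage = c("backbone", "neck", "head"),
                                  data, n_images = 2L) {
  stage <- match.arg(stage)
  student <- session$student; teacher <- session$teacher
  cfg <- session$cfg
  idx <- seq_len(min(n_images, length(data)))
  X <- batch_tensor(data, idx)
  input_size <- dim(X)[1:2]
  grids <- model_grids(student, input_size)
  assigns <- lapply(idx, function(i)
    assign_targets(data[[i]]$instances, student$meta$anchors, grids,
                   cfg$ratio_threshold))
  gts <- lapply(idx, function(i) data[[i]]$instances)
  zero_grads(student)
  s_out <- ld_forward(student, X, keep_acts = TRUE)
  t_fw <- nn_forward(teacher, X)
  grads <- list()
  if (stage == "head") {
    hd <- head_loss_grad(s_out$levels, t_fw$acts[teacher$head_ids], assigns,
                         student, cfg$head_weights, cfg$head_positions)
    for (l in seq_along(hd$grads))
      grads[[as.character(student$head_ids[l])]] <- hd$grads[[l]]
  } else {
    gts_boxes <- lapply(gts, function(g)
      if (nrow(g)) as.matrix(g[, c("cx", "cy", "w", "h")]))
    sg <- stage_loss_grad(stage, t_fw$acts, s_out$fw$acts, session,
                          gts_boxes, input_size)
    grads <- sg$tap_grads
  }
  if (length(grads)) nn_backward(student, s_out$fw, grads)
  scopes <- scopes_with_grads(student)
  zero_grads(student)
  expected <- switch(stage, backbone = "backbone",
                     neck = c("backbone", "neck"),
                     head = c("backbone", "head", "neck"))
  list(stage = stage, scopes = scopes, expected = sort(expected),
       violation = length(setdiff(scopes, expected)) > 0)
}
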