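# ---------------------------------------------------------------------------
# Backbone/neck feature distillers: attention-guided focal feature imitation
# (foreground/background separated by ground-truth boxes, teacher-attention
# weighted) plus a global relation loss through a shared context operator.
# Feature maps here are single-image arrays [H, W, C].
# ---------------------------------------------------------------------------

#' Paired teacher/student feature tap
#'
#' @param stage Stage name, e.g. `"backbone-2"` or `"neck-1"`.
#' @param t_feat,s_feat Teacher / student feature maps `[H, W, C]` with equal
#'   spatial dims (same stride).
#' @param gt_boxes Center-form box matrix in image coordinates (may be empty).
#' @param image_size `c(H_img, W_img)` in pixels.
#' @export
feature_tap <- function(stage, t_feat, s_feat, gt_boxes = NULL,
                        image_size) {
  if (!all(dim(t_feat)[1:2] == dim(s_feat)[1:2]))
    stop("teacher and student features must share spatial dims at a tap")
  structure(list(stage = stage, t_feat = t_feat, s_feat = s_feat,
                 gt_boxes = gt_boxes, image_size = image_size),
            class = "feature_tap")
}

#' Distiller configuration
#'
#' @param temperature Softmax temperature of the attention maps.
#' @param w_fg,w_bg,w_attention,w_global Sub-loss weights (foreground
#'   imitation, background imitation, attention imitation, global relation).
#' @param relation `"context"` (global pooling + two pointwise transforms,
#'   shared parameters) or `"gap"` (plain global average pooling).
#' @param relation_seed Seed for the shared context-block parameters.
#' @param adapter Whether a pointwise adapter bridges student channels.
#' @export
distiller_config <- function(temperature = 0.5, w_fg = 1e-3, w_bg = 5e-4,
                             w_attention = 5e-4, w_global = 5e-6,
                             relation = c("context", "gap"),
                             relation_seed = 7L, adapter = TRUE) {
  relation <- match.arg(relation)
  if (any(c(temperature) <= 0)) stop("temperature must be > 0")
  if (any(c(w_fg, w_bg, w_attention, w_global) < 0))
    stop("distiller weights must be >= 0")
  structure(list(temperature = temperature, w_fg = w_fg, w_bg = w_bg,
                 w_attention = w_attention, w_global = w_global,
                 relation = relation, relation_seed = as.integer(relation_seed),
                 adapter = adapter),
            class = "distiller_config")
}

#' Spatial attention map
#'
#' `H*W * softmax_positions(mean_channels(|feat|) / temperature)`; sums to
#' `H*W`.
#' @param feat Feature map `[H, W, C]`.
#' @param temperature Softmax temperature (> 0).
#' @return Matrix `[H, W]`, non-negative.
#' @export
spatial_attention <- function(feat, temperature = 0.5) {
  stopifnot(temperature > 0)
  d <- dim(feat)
  m <- rowMeans(matrix(abs(feat), d[1] * d[2], d[3]))
  z <- m / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  matrix(length(m) * p, d[1], d[2])
}

#' Channel attention vector
#'
#' `C * softmax_channels(mean_positions(|feat|) / temperature)`; sums to `C`.
#' @inheritParams spatial_attention
#' @return Vector length `C`, non-negative.
#' @export
channel_attention <- function(feat, temperature = 0.5) {
  stopifnot(temperature > 0)
  d <- dim(feat)
  m <- colMeans(matrix(abs(feat), d[1] * d[2], d[3]))
  z <- m / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  d[3] * p
}

#' Foreground mask and scale weights on a feature grid
#'
#' A cell is foreground iff its center falls inside any ground-truth box
#' scaled to the grid. Foreground cells are weighted by the reciprocal of
#' the cell-area of their smallest covering box (small objects weigh more);
#' background cells share weight `1 / n_background`.
#'
#' @param gt_boxes Center-form boxes in image coordinates (may be `NULL`).
#' @param grid `c(H, W)` cell counts.
#' @param image_size `c(H_img, W_img)`.
#' @return List with `mask` (binary `[H, W]`), `fg_weight` and `bg_weight`
#'   maps `[H, W]`.
#' @export
foreground_mask <- function(gt_boxes, grid, image_size) {
  H <- grid[1]; W <- grid[2]
  sy <- image_size[1] / H; sx <- image_size[2] / W
  mask <- matrix(0, H, W)
  wmin <- matrix(Inf, H, W)
  if (!is.null(gt_boxes) && nrow(rbind(gt_boxes)) > 0) {
    corners <- box_corners(gt_boxes)
    cxs <- (seq_len(W) - 0.5) * sx
    cys <- (seq_len(H) - 0.5) * sy
    for (bi in seq_len(nrow(corners))) {
      co <- corners[bi, ]
      cols <- which(cxs >= co[1] & cxs <= co[3])
      rows <- which(cys >= co[2] & cys <= co[4])
      if (!length(cols) || !length(rows)) next
      area_cells <- ((co[3] - co[1]) / sx) * ((co[4] - co[2]) / sy)
      mask[rows, cols] <- 1
      wmin[rows, cols] <- pmin(wmin[rows, cols], area_cells)
    }
  }
  fg_weight <- ifelse(is.finite(wmin), 1 / pmax(wmin, 1e-12), 0)
  n_bg <- sum(mask == 0)
  bg_weight <- matrix(if (n_bg > 0) 1 / n_bg else 0, H, W) * (mask == 0)
  list(mask = mask, fg_weight = fg_weight * mask, bg_weight = bg_weight)
}

# Internal: focal loss pieces (and optionally the gradient w.r.t. s_feat).
focal_feature_terms <- function(tap, cfg, want_grad = FALSE) {
  t_f <- tap$t_feat; s_f <- tap$s_feat
  if (!all(dim(t_f) == dim(s_f)))
    stop("focal distillation needs channel-aligned features (use an adapter)")
  d <- dim(t_f)
  fm <- foreground_mask(tap$gt_boxes, d[1:2], tap$image_size)
  a_sp_t <- spatial_attention(t_f, cfg$temperature)
  a_ch_t <- channel_attention(t_f, cfg$temperature)
  wmap <- cfg$w_fg * fm$fg_weight + cfg$w_bg * fm$bg_weight
  diff <- t_f - s_f
  # position-and-channel weight: wmap * a_sp_t (spatial) x a_ch_t (channel)
  wfull <- array(as.vector(wmap * a_sp_t), d) *
    rep(a_ch_t, each = d[1] * d[2])
  imitation <- sum(wfull * diff^2)

  a_sp_s <- spatial_attention(s_f, cfg$temperature)
  a_ch_s <- channel_attention(s_f, cfg$temperature)
  att <- cfg$w_attention *
    (mean(abs(a_sp_t - a_sp_s)) + mean(abs(a_ch_t - a_ch_s)))
  out <- list(imitation = imitation, attention = att,
              loss = imitation + att)
  if (want_grad) {
    g <- -2 * wfull * diff
    # attention-imitation gradient through the student softmaxes
    hw <- d[1] * d[2]
    # spatial: a = HW * softmax(m/T), m = mean_c |s|
    ga <- cfg$w_attention * sign(a_sp_s - a_sp_t) / hw # dL/da_s
    p <- as.vector(a_sp_s) / hw
    gp <- hw * as.vector(ga)
    gm <- (p * (gp - sum(gp * p))) / cfg$temperature
    g <- g + array(gm, d) * sign(s_f) / d[3]
    # channel: a = C * softmax(m/T), m = mean_pos |s|
    gc <- cfg$w_attention * sign(a_ch_s - a_ch_t) / d[3]
    pc <- a_ch_s / d[3]
    gpc <- d[3] * gc
    gmc <- (pc * (gpc - sum(gpc * pc))) / cfg$temperature
    g <- g + rep(gmc, each = hw) * sign(s_f) / hw
    out$grad <- g
  }
  out
}

#' Focal (attention-guided) feature imitation loss
#'
#' Teacher-attention- and mask-weighted squared feature difference, with
#' foreground and background weighted separately, plus an L1 imitation term
#' between teacher and student attention maps. Zero when the features are
#' identical.
#'
#' @param tap A [feature_tap()] with channel-aligned features.
#' @param cfg A [distiller_config()].
#' @export
focal_feature_loss <- function(tap, cfg = distiller_config()) {
  focal_feature_terms(tap, cfg, want_grad = FALSE)$loss
}

#' Global average pooling relation operator
#' @export
relation_gap <- function() {
  structure(list(
    fn = function(f) colMeans(matrix(f, prod(dim(f)[1:2]), dim(f)[3])),
    grad = function(f, dr) {
      d <- dim(f)
      array(rep(dr / (d[1] * d[2]), each = d[1] * d[2]), d)
    }),
    class = "relation_op")
}

#' Context-block relation operator
#'
#' Global average pooling followed by two pointwise linear transforms with a
#' ReLU in between. Parameters are drawn once from `seed` and shared between
#' the teacher and student branches.
#'
#' @param channels Feature channels the operator acts on.
#' @param hidden Hidden width.
#' @param seed Parameter seed.
#' @export
make_context_block <- function(channels, hidden = max(4L, channels %/% 2L),
                               seed = 7L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  W1 <- matrix(stats::rnorm(hidden * channels, sd = sqrt(2 / channels)),
               hidden, channels)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(channels * hidden, sd = sqrt(2 / hidden)),
               channels, hidden)
  b2 <- numeric(channels)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(
    fn = function(f) {
      g <- colMeans(matrix(f, prod(dim(f)[1:2]), dim(f)[3]))
      h <- pmax(W1 %*% g + b1, 0)
      as.vector(W2 %*% h + b2)
    },
    grad = function(f, dr) {
      d <- dim(f)
      g <- colMeans(matrix(f, d[1] * d[2], d[3]))
      pre <- as.vector(W1 %*% g + b1)
      dh <- as.vector(t(W2) %*% dr) * (pre > 0)
      dg <- as.vector(t(W1) %*% dh)
      array(rep(dg / (d[1] * d[2]), each = d[1] * d[2]), d)
    }),
    class = "relation_op")
}

#' Global relation loss
#'
#' Squared difference between a shared deterministic relation operator
#' applied to the teacher and to the student features.
#'
#' @param tap A [feature_tap()] with channel-aligned features.
#' @param relation_op A relation operator ([relation_gap()] or
#'   [make_context_block()]).
#' @export
global_relation_loss <- function(tap, relation_op = relation_gap()) {
  rt <- relation_op$fn(tap$t_feat)
  rs <- relation_op$fn(tap$s_feat)
  sum((rt - rs)^2)
}

global_relation_grad <- function(tap, relation_op = relation_gap()) {
  rt <- relation_op$fn(tap$t_feat)
  rs <- relation_op$fn(tap$s_feat)
  relation_op$grad(tap$s_feat, -2 * (rt - rs))
}

# Relation operator for a tap under a config (cached by channel count).
tap_relation_op <- function(cfg, channels, cache = NULL) {
  if (cfg$relation == "gap") return(relation_gap())
  key <- as.character(channels)
  if (!is.null(cache)) {
    if (is.null(cache[[key]]))
      cache[[key]] <- make_context_block(channels, seed = cfg$relation_seed)
    return(cache[[key]])
  }
  make_context_block(channels, seed = cfg$relation_seed)
}

#' Stage distillation loss over a set of taps
#'
#' Sum over taps of the focal imitation loss plus the weighted global
#' relation loss. Zero iff student features equal teacher features at every
#' tap.
#'
#' @param taps List of [feature_tap()]s from one stage family.
#' @param cfg A [distiller_config()].
#' @export
stage_distill_loss <- function(taps, cfg = distiller_config()) {
  if (!length(taps)) stop("empty tap list")
  cache <- new.env(parent = emptyenv())
  total <- 0
  for (tap in taps) {
    rop <- tap_relation_op(cfg, dim(tap$t_feat)[3], cache)
    total <- total + focal_feature_loss(tap, cfg) +
      cfg$w_global * global_relation_loss(tap, rop)
  }
  total
}

# Gradient of one tap's (focal + w_global * global) loss w.r.t. s_feat.
tap_distill_grad <- function(tap, cfg, rop) {
  focal_feature_terms(tap, cfg, want_grad = TRUE)$grad +
    cfg$w_global * global_relation_grad(tap, rop)
}
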