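# ---------------------------------------------------------------------------
# Loss algebra: supervised binary cross-entropy, soft-target cross-entropy,
# diversity knowledge transfer, the head-stage distillation loss, the
# detection-module loss, and the combined objective.
#
# All cross-entropies are per-element binary (sigmoid-score) losses averaged
# over every element, matching multi-label detector heads. Log arguments are
# clamped to [eps, 1 - eps].
# ---------------------------------------------------------------------------

.ld_eps <- 1e-7

clamp01 <- function(p, eps = .ld_eps) pmin(pmax(p, eps), 1 - eps)

#' Head signal bundle
#'
#' Position-aligned per-anchor-position signals: class scores, objectness and
#' box parameters, tagged with their source (`student`, `teacher`, `label`).
#' Label-source class rows must be one-hot and label objectness in {0, 1}.
#'
#' @param cls Matrix `N x C` of class scores in `[0, 1]`.
#' @param obj Vector length `N` of objectness scores in `[0, 1]`.
#' @param box Matrix `N x 4` of center-form box parameters.
#' @param source One of `"student"`, `"teacher"`, `"label"`.
#' @export
head_signals <- function(cls, obj, box, source = c("student", "teacher", "label")) {
  source <- match.arg(source)
  cls <- rbind(cls); box <- rbind(box)
  if (nrow(cls) != length(obj) || nrow(box) != length(obj))
    stop("cls, obj and box must agree on the number of positions")
  if (any(cls < 0 | cls > 1) || any(obj < 0 | obj > 1))
    stop("scores must lie in [0, 1]")
  if (source == "label") {
    if (nrow(cls) && !all(cls %in% c(0, 1) & rowSums(cls) == 1))
      stop("label class scores must be one-hot")
    if (!all(obj %in% c(0, 1))) stop("label objectness must be 0/1")
  }
  structure(list(cls = cls, obj = obj, box = box, source = source),
            class = "head_signals")
}

#' Distillation term weights (omega1, omega2, omega3)
#'
#' Weights of the class-score, objectness and box terms in the head-stage
#' and detection-module losses. Defaults mirror the usual YOLO loss balance.
#' @param w1,w2,w3 Non-negative scalars.
#' @export
distill_weights <- function(w1 = 0.5, w2 = 1.0, w3 = 0.05) {
  if (any(c(w1, w2, w3) < 0)) stop("distillation weights must be >= 0")
  structure(list(w1 = w1, w2 = w2, w3 = w3), class = "distill_weights")
}

#' Stage loss weights (alpha, beta, theta, gamma)
#'
#' Balance of the backbone, neck, head and detection-module losses in the
#' combined objective. Defaults are the reference values
#' `alpha = 1e-5, beta = 1e-8, theta = 1, gamma = 0.5`.
#' @param alpha,beta,theta,gamma Non-negative scalars.
#' @export
stage_loss_weights <- function(alpha = 1e-5, beta = 1e-8, theta = 1.0, gamma = 0.5) {
  if (any(c(alpha, beta, theta, gamma) < 0)) stop("stage weights must be >= 0")
  structure(list(alpha = alpha, beta = beta, theta = theta, gamma = gamma),
            class = "stage_loss_weights")
}

#' Binary cross-entropy (mean)
#'
#' `mean(-(t*log(p) + (1-t)*log(1-p)))` with predictions clamped to
#' `[eps, 1-eps]`. With one-hot targets this is the supervised detection
#' form; [soft_ce()] is the same formula with soft (teacher) targets.
#'
#' @param pred Predicted scores in `[0, 1]`.
#' @param target Targets in `[0, 1]` (one-hot or soft).
#' @param eps Clamp for log arguments.
#' @return Scalar mean loss.
#' @export
bce <- function(pred, target, eps = .ld_eps) {
  if (length(pred) != length(target))
    stop("shape mismatch: pred has ", length(pred), " elements, target ",
         length(target))
  p <- clamp01(pred, eps)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Soft-target cross-entropy (mean)
#'
#' Identical formula to [bce()] but intended for soft targets; its minimum in
#' `pred` is at `pred = target` where it equals the mean binary entropy of
#' the target, not zero.
#' @inheritParams bce
#' @export
soft_ce <- function(pred, target, eps = .ld_eps) bce(pred, target, eps)

#' Mean binary entropy of a score array
#' @param t Scores in `[0, 1]`.
#' @export
mean_binary_entropy <- function(t, eps = .ld_eps) {
  t <- clamp01(t, eps)
  mean(-(t * log(t) + (1 - t) * log(1 - t)))
}

#' Diversity knowledge transfer loss
#'
#' Soft-target cross-entropy of student class scores against teacher class
#' scores, averaged over all positions and classes. Because every teacher
#' class score is nonzero, the loss carries gradient for every class --
#' negative classes included -- which is what transfers the teacher's
#' between-class diversity structure to the student.
#'
#' @param s_cls,t_cls Matrices `N x C` of student / teacher class scores.
#' @export
dkt_loss <- function(s_cls, t_cls, eps = .ld_eps) {
  if (!all(dim(rbind(s_cls)) == dim(rbind(t_cls))))
    stop("shape mismatch between student and teacher class scores")
  soft_ce(rbind(s_cls), rbind(t_cls), eps)
}

# d(mean BCE)/d(pred), elementwise; zero where the clamp is active.
bce_grad <- function(pred, target, eps = .ld_eps) {
  inside <- pred > eps & pred < 1 - eps
  p <- clamp01(pred, eps)
  g <- (-target / p + (1 - target) / (1 - p)) / length(pred)
  g * inside
}

check_sources <- function(a, b, expect_a, expect_b) {
  if (!inherits(a, "head_signals") || !inherits(b, "head_signals"))
    stop("operands must be head_signals objects")
  if (a$source != expect_a || b$source != expect_b)
    stop(sprintf("expected sources (%s, %s), got (%s, %s)",
                 expect_a, expect_b, a$source, b$source))
  if (nrow(a$cls) != nrow(b$cls))
    stop("operands must be position-aligned")
}

#' Head-stage distillation loss
#'
#' `w1 * L_DKT(S_cls, T_cls) + w2 * L_CE(S_obj, T_obj) +
#'  w3 * mean(L_CIoU(S_box, T_box))`.
#'
#' @param S Student [head_signals()].
#' @param T_ Teacher [head_signals()].
#' @param w [distill_weights()].
#' @export
head_distill_loss <- function(S, T_, w = distill_weights()) {
  check_sources(S, T_, "student", "teacher")
  n <- nrow(S$cls)
  if (n == 0L) return(0)
  w$w1 * dkt_loss(S$cls, T_$cls) +
    w$w2 * soft_ce(S$obj, T_$obj) +
    w$w3 * mean(ciou_loss(S$box, T_$box))
}

#' Detection-module (supervised) loss
#'
#' `w1 * L_BCE(S_cls, L_cls) + w2 * L_BCE(S_obj, L_obj) +
#'  w3 * mean(L_CIoU(S_box, L_box))` against one-hot labels.
#'
#' @param S Student [head_signals()].
#' @param L Label [head_signals()].
#' @param w [distill_weights()].
#' @export
dm_loss <- function(S, L, w = distill_weights()) {
  check_sources(S, L, "student", "label")
  n <- nrow(S$cls)
  if (n == 0L) return(0)
  w$w1 * bce(S$cls, L$cls) +
    w$w2 * bce(S$obj, L$obj) +
    w$w3 * mean(ciou_loss(S$box, L$box))
}

#' Combined distillation objective
#'
#' `total = alpha*loss_backbone + beta*loss_neck + theta*loss_head +
#'  gamma*loss_dm`.
#'
#' @param loss_backbone,loss_neck,loss_head,loss_dm Non-negative component
#'   losses.
#' @param sw [stage_loss_weights()].
#' @return A `loss_bundle` with the four components and the weighted total.
#' @export
total_distill_loss <- function(loss_backbone, loss_neck, loss_head, loss_dm,
                               sw = stage_loss_weights()) {
  comp <- c(loss_backbone = loss_backbone, loss_neck = loss_neck,
            loss_head = loss_head, loss_dm = loss_dm)
  if (any(!is.finite(comp))) stop("loss components must be finite")
  if (any(comp < 0))
    stop("negative loss component: ",
         paste(names(comp)[comp < 0], collapse = ", "))
  total <- sw$alpha * loss_backbone + sw$beta * loss_neck +
    sw$theta * loss_head + sw$gamma * loss_dm
  structure(list(loss_backbone = loss_backbone, loss_neck = loss_neck,
                 loss_head = loss_head, loss_dm = loss_dm, total = total,
                 weights = sw),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(paste0("loss_bundle: backbone %.4g | neck %.4g | head %.4g | ",
                     "dm %.4g | total %.6g\n"),
              x$loss_backbone, x$loss_neck, x$loss_head, x$loss_dm, x$total))
  invisible(x)
}
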