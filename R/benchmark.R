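# ---------------------------------------------------------------------------
# The standard desk-scale distillation benchmark: one synthetic dataset, one
# tiny teacher, then per-seed plain vs distilled students, all on one CPU.
# ---------------------------------------------------------------------------

# Desk-scale training recipe. The reference stage weights (alpha, beta,
# theta, gamma) are kept; the detection-term balance (w1, w2, w3) and the
# learning rate are re-tuned for short schedules on 64-px synthetic scenes
# (see the methods vignette for the rationale).
desk_train_config <- function(epochs, seed,
                              stage_weights = stage_loss_weights()) {
  train_config(epochs = epochs, seed = seed, lr0 = 0.01, warmup_epochs = 1,
               clip_norm = 20,
               dm_weights = distill_weights(2, 1, 1),
               head_weights = distill_weights(2, 1, 1),
               stage_weights = stage_weights)
}

#' Run the standard distillation benchmark
#'
#' Generates the standard synthetic benchmark (600 train / 150 test images,
#' 64 px, 6 classes), estimates anchors from the training boxes, trains a
#' tiny teacher on the training split, then for each seed trains a tiny
#' student twice from identical initialisation -- once with the supervised
#' detection loss only, once under full multistage distillation with the
#' reference stage weights -- and evaluates mAP@.5 on the held-out split.
#'
#' @param seed Global seed; dataset, anchor and training seeds derive from it.
#' @param seeds Per-student training/initialisation seeds.
#' @param scale Width multiplier of the tiny pair.
#' @param teacher_epochs,student_epochs Training lengths.
#' @param n_train,n_test Dataset split sizes.
#' @param verbose Print progress.
#' @return List with `teacher_map50`, `results` (one row per seed: plain and
#'   distilled mAP@.5 and their difference), and `median_gain`.
#' @export
run_benchmark <- function(seed = 1L, seeds = c(1L, 2L, 3L), scale = 0.1,
                          teacher_epochs = 30L, student_epochs = 8L,
                          n_train = 600L, n_test = 150L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  scfg <- synth_config(n_train = n_train, n_test = n_test,
                       seed = derive_seed(seed, "synth"))
  recs <- generate_synthetic_dataset(scfg)
  train <- Filter(function(r) identical(r$split, "train"), recs)
  test <- Filter(function(r) identical(r$split, "test"), recs)
  nc <- length(class_names(scfg))
  wh <- do.call(rbind, lapply(train, function(r)
    as.matrix(r$instances[, c("w", "h"), drop = FALSE])))
  aset <- kmeans_anchors(wh, 12L, seed = derive_seed(seed, "anchors"))
  Xte <- batch_tensor(test, seq_along(test))
  gts <- lapply(test, function(r) r$instances)
  eval_map <- function(model) {
    evaluate_detections(ld_detect(model, Xte), gts, nc)$map50
  }
  pair <- build_tiny_pair(scale, nc, aset)
  teacher <- materialize_params(pair$teacher, derive_seed(seed, "train"))
  say("training tiny teacher (%d epochs)...", teacher_epochs)
  train_plain(teacher, train, desk_train_config(teacher_epochs,
                                                derive_seed(seed, "train")))
  teacher_map <- eval_map(teacher)
  say("teacher mAP@.5 = %.3f", teacher_map)
  teacher_params <- get_params(teacher)
  rows <- lapply(seeds, function(sd) {
    pair_s <- build_tiny_pair(scale, nc, aset)
    plain <- materialize_params(pair_s$student, 1000L + sd)
    init <- get_params(plain)
    say("seed %d: plain student...", sd)
    train_plain(plain, train, desk_train_config(student_epochs, sd))
    m_plain <- eval_map(plain)
    pair_d <- build_tiny_pair(scale, nc, aset)
    dist <- materialize_params(pair_d$student, 1000L + sd)
    set_params(dist, init)
    say("seed %d: distilled student...", sd)
    train_distilled(teacher, dist, train, desk_train_config(student_epochs, sd))
    m_dist <- eval_map(dist)
    say("seed %d: plain %.3f vs distilled %.3f", sd, m_plain, m_dist)
    data.frame(seed = sd, map50_plain = m_plain, map50_distilled = m_dist,
               gain = m_dist - m_plain)
  })
  set_params(teacher, teacher_params)
  results <- do.call(rbind, rows)
  list(teacher_map50 = teacher_map, results = results,
       median_gain = stats::median(results$gain))
}
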