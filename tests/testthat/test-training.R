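# Trainer tests run on the tiny pair at 64 px with small record sets.

small_set <- function(n, seed, lesions = c(1L, 3L)) {
  generate_synthetic_dataset(synth_config(n_train = n, n_test = 0, seed = seed,
                                          lesions_min = lesions[1],
                                          lesions_max = lesions[2]))
}

test_that("assign_targets matches a brute-force scan of the matching rule", {
  aset <- test_anchor_set()
  grids <- lapply(1:4, function(l) {
    s <- c(8L, 16L, 32L, 64L)[l]
    grid_spec(s, 64L %/% s, 64L %/% s, l)
  })
  expect_equal(nrow(assign_targets(NULL, aset, grids)), 0L)
  # a box equal to an anchor, centered in a cell, is positive there
  la <- level_anchors(aset, 1)
  g1 <- data.frame(class_id = 1L, cx = 20, cy = 20, w = la[2, 1], h = la[2, 2])
  A <- assign_targets(g1, aset, grids)
  expect_true(any(A$level == 1 & A$anchor == 2 & A$row == 3 & A$col == 3))
  # brute-force oracle over all (level, anchor, cell) triples
  brute <- function(gts, thr = 4) {
    out <- NULL
    taken <- character(0)
    for (gi in seq_len(nrow(gts))) for (l in 1:4) {
      g <- grids[[l]]; la <- level_anchors(aset, l)
      gx <- gts$cx[gi] / g$stride; gy <- gts$cy[gi] / g$stride
      col0 <- floor(gx); row0 <- floor(gy)
      cand <- rbind(c(row0, col0),
                    c(row0, if (gx - col0 < 0.5) col0 - 1 else col0 + 1),
                    c(if (gy - row0 < 0.5) row0 - 1 else row0 + 1, col0))
      for (a in seq_len(nrow(la))) {
        r <- max(gts$w[gi] / la[a, 1], la[a, 1] / gts$w[gi],
                 gts$h[gi] / la[a, 2], la[a, 2] / gts$h[gi])
        if (r >= thr) next
        for (ci in seq_len(nrow(cand))) {
          rr <- cand[ci, 1]; cc <- cand[ci, 2]
          if (rr < 0 || cc < 0 || rr >= g$grid_h || cc >= g$grid_w) next
          key <- paste(l, a, rr, cc)
          if (key %in% taken) next
          taken <- c(taken, key)
          out <- rbind(out, data.frame(level = l, anchor = a, row = rr + 1,
                                       col = cc + 1, gt = gi,
                                       class_id = gts$class_id[gi]))
        }
      }
    }
    out
  }
  set.seed(41)
  for (i in 1:10) {
    k <- sample(1:4, 1)
    gts <- data.frame(class_id = sample(1:6, k, TRUE),
                      cx = runif(k, 6, 58), cy = runif(k, 6, 58),
                      w = runif(k, 5, 40), h = runif(k, 5, 40))
    got <- assign_targets(gts, aset, grids)
    want <- brute(gts)
    expect_equal(got[order(got$level, got$anchor, got$row, got$col), ],
                 want[order(want$level, want$anchor, want$row, want$col), ],
                 ignore_attr = TRUE)
  }
  # zero-area boxes are rejected with a warning
  expect_warning(assign_targets(
    data.frame(class_id = 1L, cx = 10, cy = 10, w = 0, h = 5), aset, grids),
    "cleaning")
})

test_that("encode_box inverts the head decode exactly", {
  aset <- test_anchor_set()
  grids <- lapply(1:4, function(l) {
    s <- c(8L, 16L, 32L, 64L)[l]
    grid_spec(s, 64L %/% s, 64L %/% s, l)
  })
  set.seed(42)
  for (i in 1:50) {
    gts <- data.frame(class_id = 1L, cx = runif(1, 6, 58), cy = runif(1, 6, 58),
                      w = runif(1, 5, 40), h = runif(1, 5, 40))
    A <- assign_targets(gts, aset, grids)
    if (!nrow(A)) next
    a <- A[1, ]
    la <- level_anchors(aset, a$level)
    t <- encode_box(as.matrix(gts[, c("cx", "cy", "w", "h")]),
                    la[a$anchor, ], a$row, a$col, grids[[a$level]]$stride)
    s <- plogis(t)
    dec <- c((2 * s[1] - 0.5 + a$col - 1) * grids[[a$level]]$stride,
             (2 * s[2] - 0.5 + a$row - 1) * grids[[a$level]]$stride,
             (2 * s[3])^2 * la[a$anchor, 1], (2 * s[4])^2 * la[a$anchor, 2])
    expect_equal(unname(dec),
                 unlist(gts[, c("cx", "cy", "w", "h")], use.names = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("supervised loss gradients match numeric differentiation", {
  aset <- test_anchor_set()
  model <- list(meta = list(num_classes = 3L, per_level = 3L, anchors = aset,
                            strides = c(8L, 16L, 32L, 64L)))
  gdims <- c(8, 4, 2, 1)
  set.seed(43)
  raws <- lapply(gdims, function(g) array(rnorm(g * g * 24 * 2) * 0.5,
                                          c(g, g, 24, 2)))
  gts <- list(data.frame(class_id = c(1L, 2L), cx = c(20, 40), cy = c(18, 44),
                         w = c(10, 18), h = c(12, 16)),
              data.frame(class_id = 3L, cx = 30, cy = 30, w = 24, h = 20))
  grids <- lapply(1:4, function(l)
    grid_spec(c(8, 16, 32, 64)[l], gdims[l], gdims[l], l))
  assigns <- lapply(gts, function(g) assign_targets(g, aset, grids))
  w <- distill_weights(2, 1, 1)
  r <- leafdistill:::dm_loss_grad(raws, assigns, gts, model, w)
  B <- 2 # gradients are defined as B x the derivative of the mean loss
  for (l in 1:4) for (i in sample(length(raws[[l]]), 8)) {
    num <- (function(eps = 1e-6) {
      rp <- raws; rp[[l]][i] <- rp[[l]][i] + eps
      rm <- raws; rm[[l]][i] <- rm[[l]][i] - eps
      (leafdistill:::dm_loss_grad(rp, assigns, gts, model, w, FALSE)$loss -
       leafdistill:::dm_loss_grad(rm, assigns, gts, model, w, FALSE)$loss) / (2 * eps)
    })()
    expect_equal(r$grads[[l]][i], B * num, tolerance = 1e-4 * max(1, abs(num)))
  }
})

test_that("head distillation gradients match numeric differentiation", {
  aset <- test_anchor_set()
  model <- list(meta = list(num_classes = 3L, per_level = 3L, anchors = aset,
                            strides = c(8L, 16L, 32L, 64L)))
  gdims <- c(8, 4, 2, 1)
  set.seed(44)
  s_raws <- lapply(gdims, function(g) array(rnorm(g * g * 24), c(g, g, 24, 1)))
  t_raws <- lapply(gdims, function(g) array(rnorm(g * g * 24), c(g, g, 24, 1)))
  w <- distill_weights(1, 1, 0.5)
  r <- leafdistill:::head_loss_grad(s_raws, t_raws, list(NULL), model, w, "all")
  for (l in c(1, 3)) for (i in sample(length(s_raws[[l]]), 6)) {
    num <- (function(eps = 1e-6) {
      rp <- s_raws; rp[[l]][i] <- rp[[l]][i] + eps
      rm <- s_raws; rm[[l]][i] <- rm[[l]][i] - eps
      (leafdistill:::head_loss_grad(rp, t_raws, list(NULL), model, w, "all", FALSE)$loss -
       leafdistill:::head_loss_grad(rm, t_raws, list(NULL), model, w, "all", FALSE)$loss) / (2 * eps)
    })()
    expect_equal(r$grads[[l]][i], num, tolerance = 1e-4 * max(1, abs(num)))
  }
})

test_that("whole-model backprop agrees with numeric gradients", {
  # end-to-end autodiff check through conv/act/concat/upsample/implicit ops
  recs <- small_set(2, 45)
  pair <- build_tiny_pair(0.05, 6L, test_anchor_set())
  stu <- materialize_params(pair$student, 5)
  X <- leafdistill:::batch_tensor(recs, 1:2)
  loss_of <- function() {
    out <- leafdistill:::ld_forward(stu, X)
    sum(vapply(out$levels, function(r) sum(plogis(r)^2), numeric(1)))
  }
  out <- leafdistill:::ld_forward(stu, X, keep_acts = TRUE)
  grads <- stats::setNames(lapply(out$levels, function(r) {
    p <- plogis(r); 2 * p * p * (1 - p)
  }), as.character(stu$head_ids))
  leafdistill:::zero_grads(stu)
  leafdistill:::nn_backward(stu, out$fw, grads)
  set.seed(46)
  checked <- 0
  for (nd in sample(leafdistill:::param_nodes(stu), 6)) {
    nm <- names(nd$p$shapes)[1]
    i <- sample(length(nd$p[[nm]]), 1)
    eps <- 1e-5
    orig <- nd$p[[nm]][i]
    nd$p[[nm]][i] <- orig + eps; up <- loss_of()
    nd$p[[nm]][i] <- orig - eps; dn <- loss_of()
    nd$p[[nm]][i] <- orig
    num <- (up - dn) / (2 * eps)
    got <- nd$p[[paste0("d", nm)]][i]
    expect_equal(got, num, tolerance = 2e-3 * max(1, abs(num)))
    checked <- checked + 1
  }
  expect_equal(checked, 6)
  leafdistill:::zero_grads(stu)
})

test_that("train_plain honours the zero-epoch and determinism contracts", {
  recs <- small_set(8, 47)
  pair <- build_tiny_pair(0.05, 6L, test_anchor_set())
  stu <- materialize_params(pair$student, 6)
  h0 <- leafdistill:::param_hash(stu)
  res0 <- train_plain(stu, recs, train_config(epochs = 0, seed = 1))
  expect_equal(nrow(res0$history), 0L)
  expect_identical(leafdistill:::param_hash(stu), h0)
  # bit-identical histories for a fixed seed
  run <- function() {
    p <- build_tiny_pair(0.05, 6L, test_anchor_set())
    s <- materialize_params(p$student, 6)
    train_plain(s, recs, train_config(epochs = 2, seed = 9))$history
  }
  expect_identical(run(), run())
})

test_that("one-image overfit reduces the loss at least tenfold in 200 steps", {
  recs <- generate_synthetic_dataset(synth_config(n_train = 1, n_test = 0,
                                                  lesions_min = 1,
                                                  lesions_max = 1, seed = 7))
  pair <- build_tiny_pair(0.08, 6L, test_anchor_set())
  stu <- materialize_params(pair$student, 1)
  cfg <- train_config(epochs = 200, batch_size = 1, seed = 1, lr0 = 0.1,
                      lr_final_frac = 1, warmup_epochs = 10, weight_decay = 0)
  res <- train_plain(stu, recs, cfg)
  h <- res$history$loss_dm
  expect_lt(tail(h, 1), 0.1 * h[1])
})

test_that("distillation freezes the teacher and satisfies the loss identity", {
  recs <- small_set(12, 48)
  pair <- build_tiny_pair(0.05, 6L, test_anchor_set())
  teacher <- materialize_params(pair$teacher, 7)
  stu <- materialize_params(pair$student, 8)
  th0 <- leafdistill:::param_hash(teacher)
  cfg <- train_config(epochs = 3, seed = 3)
  res <- train_distilled(teacher, stu, recs, cfg)
  expect_identical(leafdistill:::param_hash(teacher), th0)
  # combined-objective identity at every logged step
  sw <- cfg$stage_weights
  expect_equal(res$history$total,
               sw$alpha * res$history$loss_backbone +
                 sw$beta * res$history$loss_neck +
                 sw$theta * res$history$loss_head +
                 sw$gamma * res$history$loss_dm,
               tolerance = 1e-9)
  expect_true(all(is.finite(res$history$total)))
  # tap mismatch errors
  bad <- pair$student; bad$taps <- bad$taps[1:4]
  expect_error(distill_session(teacher, bad, cfg), "missing taps")
})

test_that("gamma-only distillation reproduces plain training step for step", {
  recs <- small_set(10, 49)
  mk <- function() materialize_params(
    build_tiny_pair(0.05, 6L, test_anchor_set())$student, 11)
  cfg <- train_config(epochs = 2, seed = 13,
                      stage_weights = stage_loss_weights(0, 0, 0, 0.5))
  plain <- mk()
  h1 <- train_plain(plain, recs, cfg)$history
  teacher <- materialize_params(build_tiny_pair(0.05, 6L, test_anchor_set())$teacher, 12)
  dist <- mk()
  h2 <- train_distilled(teacher, dist, recs, cfg)$history
  expect_identical(h1$loss_dm, h2$loss_dm)
  expect_identical(h1$total, h2$total)
  expect_identical(leafdistill:::param_hash(plain), leafdistill:::param_hash(dist))
})

test_that("gradient scopes follow the stage-wise contracts", {
  recs <- small_set(4, 50)
  pair <- build_tiny_pair(0.05, 6L, test_anchor_set())
  teacher <- materialize_params(pair$teacher, 21)
  stu <- materialize_params(pair$student, 22)
  cfg <- train_config(epochs = 1, seed = 1)
  ses <- distill_session(teacher, stu, cfg, c(64L, 64L))
  rb <- gradient_scope_report(ses, "backbone", recs)
  expect_identical(rb$scopes, "backbone")
  expect_false(rb$violation)
  rn <- gradient_scope_report(ses, "neck", recs)
  expect_identical(rn$scopes, c("backbone", "neck"))
  expect_false(rn$violation)
  rh <- gradient_scope_report(ses, "head", recs)
  expect_identical(rh$scopes, c("backbone", "head", "neck"))
  expect_false(rh$violation)
  # head parameter gradients are identically zero under the backbone stage
  leafdistill:::zero_grads(stu)
  sb <- gradient_scope_report(ses, "backbone", recs)
  head_nodes <- Filter(function(nd) nd$scope == "head" &&
                         length(nd$p$shapes), stu$nodes)
  for (nd in head_nodes)
    for (nm in names(nd$p$shapes))
      expect_true(is.null(nd$p[[paste0("d", nm)]]) ||
                    all(nd$p[[paste0("d", nm)]] == 0))
})

test_that("all-zero stage weights leave every parameter gradient zero", {
  recs <- small_set(4, 51)
  pair <- build_tiny_pair(0.05, 6L, test_anchor_set())
  stu <- materialize_params(pair$student, 23)
  h0 <- leafdistill:::param_hash(stu)
  cfg <- train_config(epochs = 1, seed = 1,
                      stage_weights = stage_loss_weights(0, 0, 0, 0))
  res <- train_plain(stu, recs, cfg)
  expect_identical(leafdistill:::param_hash(stu), h0)
})
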