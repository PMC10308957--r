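test_that("bce matches analytic values and clamps safely", {
  expect_equal(bce(0.5, 0.5), log(2), tolerance = 1e-12)
  expect_lt(bce(1 - 1e-7, 1), 2e-7)
  expect_equal(bce(c(0.9, 0.2), c(1, 0)), mean(c(-log(0.9), -log(0.8))),
               tolerance = 1e-12)
  expect_error(bce(c(0.5, 0.5), 0.5), "shape mismatch")
  # clamp keeps extreme inputs finite
  expect_true(is.finite(bce(c(0, 1), c(1, 0))))
})

test_that("soft_ce is minimized at pred = target with entropy floor", {
  expect_equal(soft_ce(0.9, 0.9), -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  # one-hot target reduces to bce
  p <- c(0.7, 0.2, 0.4); t <- c(1, 0, 0)
  expect_equal(soft_ce(p, t), bce(p, t))
  # numeric gradient vanishes at pred = target
  g <- num_grad(function(x) soft_ce(x, 0.37), 0.37)
  expect_lt(abs(g), 1e-6)
})

test_that("dkt_loss transfers negative-class structure", {
  # s = t: entropy floor; at t = 0.5 everywhere this is ln 2
  t_half <- matrix(0.5, 4, 3)
  expect_equal(dkt_loss(t_half, t_half), log(2), tolerance = 1e-12)
  # clamped one-hot teacher reduces to supervised bce
  t1 <- matrix(c(1, 0, 0), 1)
  s <- matrix(c(0.8, 0.1, 0.3), 1)
  expect_equal(dkt_loss(s, t1), bce(s, t1))
  # element-wise arithmetic oracle
  s <- matrix(c(0.7, 0.2, 0.1), 1); tt <- matrix(c(0.8, 0.3, 0.05), 1)
  oracle <- mean(-(tt * log(s) + (1 - tt) * log(1 - s)))
  expect_equal(dkt_loss(s, tt), oracle, tolerance = 1e-12)
  expect_error(dkt_loss(matrix(0.5, 2, 3), matrix(0.5, 2, 2)), "shape")
  # Gibbs: dkt(s, t) >= mean entropy of t, equality iff s = t
  set.seed(4)
  for (i in 1:50) {
    tt <- matrix(runif(12, 0.05, 0.95), 3)
    s <- matrix(runif(12, 0.05, 0.95), 3)
    expect_gte(dkt_loss(s, tt) - mean_binary_entropy(tt), -1e-12)
  }
  tt <- matrix(runif(12, 0.05, 0.95), 3)
  expect_equal(dkt_loss(tt, tt), mean_binary_entropy(tt), tolerance = 1e-12)
})

make_signals <- function(n, C, source, seed) {
  set.seed(seed)
  cls <- matrix(runif(n * C, 0.02, 0.98), n, C)
  if (source == "label") {
    cls <- matrix(0, n, C)
    cls[cbind(seq_len(n), sample.int(C, n, TRUE))] <- 1
  }
  obj <- if (source == "label") rep(1, n) else runif(n, 0.02, 0.98)
  head_signals(cls, obj, random_boxes(n, lim = 60, wmax = 20), source)
}

test_that("head_distill_loss composes its three terms", {
  S <- make_signals(8, 4, "student", 1)
  T_ <- make_signals(8, 4, "teacher", 2)
  expect_equal(head_distill_loss(S, T_, distill_weights(0, 0, 0)), 0)
  # S = T: entropy floors for the two CE terms, zero box term
  S2 <- head_signals(T_$cls, T_$obj, T_$box, "student")
  w1 <- distill_weights(1, 1, 1)
  expect_equal(head_distill_loss(S2, T_, w1),
               mean_binary_entropy(T_$cls) + mean_binary_entropy(T_$obj),
               tolerance = 1e-9)
  # generic: sum of independently computed terms
  expect_equal(head_distill_loss(S, T_, w1),
               dkt_loss(S$cls, T_$cls) + soft_ce(S$obj, T_$obj) +
                 mean(ciou_loss(S$box, T_$box)),
               tolerance = 1e-12)
  expect_error(head_distill_loss(S, S, w1), "sources")
})

test_that("dm_loss matches arithmetic oracles and reduces to ciou", {
  L <- make_signals(3, 3, "label", 3)
  # perfect prediction (clamped labels)
  Sp <- head_signals(pmin(pmax(L$cls, 1e-7), 1 - 1e-7), L$obj, L$box, "student")
  expect_lt(dm_loss(Sp, L, distill_weights(1, 1, 1)), 3e-7)
  # cls-only oracle
  L1 <- head_signals(matrix(c(1, 0, 0), 1), 1, bbox(5, 5, 4, 4), "label")
  S1 <- head_signals(matrix(c(0.9, 0.2, 0.1), 1), 0.5, bbox(5, 5, 4, 4), "student")
  expect_equal(dm_loss(S1, L1, distill_weights(1, 0, 0)),
               mean(c(-log(0.9), -log(0.8), -log(0.9))), tolerance = 1e-9)
  # box-only reduction
  S <- make_signals(5, 3, "student", 6)
  L5 <- make_signals(5, 3, "label", 7)
  expect_equal(dm_loss(S, L5, distill_weights(0, 0, 1)),
               mean(ciou_loss(S$box, L5$box)), tolerance = 1e-12)
})

test_that("total_distill_loss is the exact weighted sum", {
  sw <- stage_loss_weights()
  expect_identical(unname(c(sw$alpha, sw$beta, sw$theta, sw$gamma)),
                   c(1e-5, 1e-8, 1.0, 0.5))
  b0 <- total_distill_loss(0, 0, 0, 0, sw)
  expect_equal(b0$total, 0)
  b1 <- total_distill_loss(1, 1, 1, 1, sw)
  expect_equal(b1$total, 1.50001001, tolerance = 1e-12)
  # linearity in each component
  b2 <- total_distill_loss(1, 1, 2, 1, sw)
  expect_equal(b2$total - b1$total, sw$theta * 1, tolerance = 1e-12)
  expect_error(total_distill_loss(-1, 0, 0, 0, sw), "negative")
  expect_error(total_distill_loss(Inf, 0, 0, 0, sw), "finite")
  # identity invariant on random components
  set.seed(8)
  for (i in 1:100) {
    comp <- runif(4, 0, 10)
    b <- total_distill_loss(comp[1], comp[2], comp[3], comp[4], sw)
    expect_equal(b$total, sum(comp * c(1e-5, 1e-8, 1, 0.5)),
                 tolerance = 1e-9 * max(1, b$total))
  }
})

test_that("losses are non-negative and finite on random clamped inputs", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(1:6, 1); C <- sample(2:5, 1)
    p <- matrix(runif(n * C, 1e-6, 1 - 1e-6), n)
    t <- matrix(runif(n * C, 1e-6, 1 - 1e-6), n)
    v <- c(bce(p, round(t)), soft_ce(p, t), dkt_loss(p, t))
    expect_true(all(is.finite(v) & v >= 0))
  }
})

test_that("head and dm losses are invariant under joint position permutation", {
  set.seed(11)
  S <- make_signals(10, 4, "student", 21)
  T_ <- make_signals(10, 4, "teacher", 22)
  L <- make_signals(10, 4, "label", 23)
  w <- distill_weights(0.7, 1.3, 0.2)
  perm <- sample.int(10)
  permute <- function(H) head_signals(H$cls[perm, ], H$obj[perm],
                                      H$box[perm, ], H$source)
  expect_equal(head_distill_loss(permute(S), permute(T_), w),
               head_distill_loss(S, T_, w), tolerance = 1e-12)
  expect_equal(dm_loss(permute(S), permute(L), w), dm_loss(S, L, w),
               tolerance = 1e-12)
})

test_that("loss gradients match numeric differentiation", {
  set.seed(12)
  for (i in 1:20) {
    n <- 8
    p <- runif(n, 0.05, 0.95); t <- runif(n, 0.05, 0.95)
    g <- leafdistill:::bce_grad(p, t)
    gn <- num_grad(function(x) bce(x, t), p)
    expect_equal(g, gn, tolerance = 1e-4)
  }
})

test_that("head_signals validates its invariants", {
  expect_error(head_signals(matrix(0.5, 2, 3), c(0.5), matrix(1, 2, 4),
                            "student"), "positions")
  expect_error(head_signals(matrix(0.4, 1, 2), 0.5, bbox(1, 1, 2, 2), "label"),
               "one-hot")
  expect_error(head_signals(matrix(c(1, 0), 1), 0.4, bbox(1, 1, 2, 2), "label"),
               "0/1")
  expect_error(head_signals(matrix(1.2, 1, 2), 0.5, bbox(1, 1, 2, 2),
                            "student"), "\\[0, 1\\]")
})
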