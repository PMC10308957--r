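#' @useDynLib leafdistill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A small reverse-mode-differentiated computation graph for convolutional
# detectors. Tensors are plain R arrays with dim c(H, W, C, N). Nodes are
# created in topological order by the architecture builders; parameters live
# in per-node environments so a model can be updated in place.
# ---------------------------------------------------------------------------

nn_builder <- function(name) {
  b <- new.env(parent = emptyenv())
  b$name <- name
  b$nodes <- list()
  b
}

nn_node <- function(b, op, inputs = integer(0), cfg = list(),
                    scope = "backbone", role = NA_character_) {
  id <- length(b$nodes) + 1L
  p <- new.env(parent = emptyenv())
  p$shapes <- list()
  node <- list(id = id, op = op, inputs = as.integer(inputs), cfg = cfg,
               scope = scope, role = role, p = p)
  b$nodes[[id]] <- node
  id
}

# conv node; role is the census class: "1x1", "3x3", "depthwise", "pointwise",
# or NA for convs outside the census scope (heads, adapters).
nn_conv <- function(b, input, in_ch, out_ch, k = 1L, stride = 1L,
                    pad = NULL, groups = 1L, bias = TRUE,
                    scope = "backbone", role = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  if (is.null(role)) {
    role <- if (groups > 1L && groups == in_ch) "depthwise"
            else if (k == 1L) "1x1" else sprintf("%dx%d", k, k)
  }
  id <- nn_node(b, "conv", input,
                cfg = list(k = as.integer(k), stride = as.integer(stride),
                           pad = as.integer(pad), groups = as.integer(groups),
                           in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                           bias = bias),
                scope = scope, role = role)
  b$nodes[[id]]$p$shapes <- c(
    list(W = c(k, k, in_ch %/% groups, out_ch)),
    if (bias) list(b = out_ch))
  id
}

nn_act <- function(b, input, kind, scope) {
  nn_node(b, "act", input, cfg = list(kind = kind), scope = scope)
}

nn_conv_act <- function(b, input, in_ch, out_ch, k = 1L, stride = 1L,
                        act = "silu", scope = "backbone", role = NULL,
                        groups = 1L) {
  id <- nn_conv(b, input, in_ch, out_ch, k, stride, groups = groups,
                scope = scope, role = role)
  if (!identical(act, "linear")) id <- nn_act(b, id, act, scope)
  id
}

nn_implicit <- function(b, input, ch, kind = c("add", "mul"), scope = "head") {
  kind <- match.arg(kind)
  id <- nn_node(b, paste0("implicit_", kind), input,
                cfg = list(ch = as.integer(ch)), scope = scope)
  b$nodes[[id]]$p$shapes <- list(v = ch)
  id
}

nn_finish <- function(b, input_id, head_ids, taps, meta = list()) {
  structure(list(name = b$name, nodes = b$nodes, input_id = input_id,
                 head_ids = as.integer(head_ids), taps = taps, meta = meta),
            class = "ld_model")
}

#' @export
print.ld_model <- function(x, ...) {
  cat(sprintf("<ld_model '%s': %d nodes, %s parameters%s>\n", x$name,
              length(x$nodes), format(count_parameters(x), big.mark = ","),
              if (params_materialized(x)) "" else " (unmaterialized)"))
  invisible(x)
}

params_materialized <- function(model) {
  for (nd in model$nodes)
    if (length(nd$p$shapes)) return(!is.null(nd$p[[names(nd$p$shapes)[1]]]))
  TRUE
}

#' Materialize model parameters
#'
#' Architecture builders return structure-only models (enough for the
#' audit); this allocates and initialises the parameter arrays so the model
#' can run a forward pass or be trained. Convolutions get He-style random
#' weights, detection heads the rare-object prior biases, and implicit
#' vectors start at identity.
#'
#' @param model An `ld_model`.
#' @param seed Optional RNG seed for reproducible initialisation.
#' @return The model, invisibly (parameters live in per-node environments
#'   and are updated in place).
#' @export
materialize_params <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (nd in model$nodes) {
    sh <- nd$p$shapes
    if (!length(sh)) next
    if (nd$op == "conv") {
      fan_in <- prod(sh$W[1:3])
      nd$p$W <- array(stats::rnorm(prod(sh$W), sd = sqrt(2 / fan_in)), dim = sh$W)
      if (!is.null(sh$b)) {
        b <- numeric(sh$b)
        hi <- nd$cfg$head_init
        if (!is.null(hi)) {
          stride5c <- 5L + hi$C
          for (a in seq_len(hi$per_level)) {
            b[(a - 1L) * stride5c + 5L] <- hi$obj_bias
            b[(a - 1L) * stride5c + 5L + seq_len(hi$C)] <- hi$cls_bias
          }
        }
        nd$p$b <- b
      }
    } else if (nd$op == "implicit_add") {
      nd$p$v <- numeric(sh$v)
    } else if (nd$op == "implicit_mul") {
      nd$p$v <- rep(1, sh$v)
    }
  }
  invisible(model)
}

act_fw <- function(x, kind) {
  switch(kind,
    silu = x * stats::plogis(x),
    relu = pmax(x, 0),
    sigmoid = stats::plogis(x),
    h_sigmoid = pmin(pmax(x + 3, 0), 6) / 6,
    h_swish = x * pmin(pmax(x + 3, 0), 6) / 6,
    linear = x,
    stop("unknown activation: ", kind))
}

act_bw <- function(x, g, kind) {
  switch(kind,
    silu = { s <- stats::plogis(x); g * (s * (1 + x * (1 - s))) },
    relu = g * (x > 0),
    sigmoid = { s <- stats::plogis(x); g * s * (1 - s) },
    h_sigmoid = g * ((x > -3 & x < 3) / 6),
    h_swish = {
      hs <- pmin(pmax(x + 3, 0), 6) / 6
      g * (hs + x * ((x > -3 & x < 3) / 6))
    },
    linear = g,
    stop("unknown activation: ", kind))
}

upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample2_bw <- function(g, xdim) {
  d <- dim(g)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  out <- g[io, jo, , , drop = FALSE] + g[io + 1L, jo, , , drop = FALSE] +
         g[io, jo + 1L, , , drop = FALSE] + g[io + 1L, jo + 1L, , , drop = FALSE]
  dim(out) <- xdim
  out
}

# Forward pass. Returns list(acts = per-node activations, aux = per-node extras).
nn_forward <- function(model, x, keep = TRUE) {
  nodes <- model$nodes
  acts <- vector("list", length(nodes))
  aux <- vector("list", length(nodes))
  for (nd in nodes) {
    y <- switch(nd$op,
      input = x,
      conv = {
        xin <- acts[[nd$inputs[1]]]
        if (dim(xin)[3] != nd$cfg$in_ch)
          stop(sprintf("conv node %d: expected %d input channels, got %d",
                       nd$id, nd$cfg$in_ch, dim(xin)[3]))
        .conv2d_fw(xin, nd$p$W, if (nd$cfg$bias) nd$p$b else numeric(0),
                   nd$cfg$stride, nd$cfg$pad, nd$cfg$groups)
      },
      act = act_fw(acts[[nd$inputs[1]]], nd$cfg$kind),
      add = {
        y <- acts[[nd$inputs[1]]]
        for (i in nd$inputs[-1]) y <- y + acts[[i]]
        y
      },
      concat = {
        parts <- acts[nd$inputs]
        d1 <- dim(parts[[1]])
        ch <- vapply(parts, function(p) dim(p)[3], integer(1))
        out <- array(0, c(d1[1], d1[2], sum(ch), d1[4]))
        at <- 0L
        for (p in parts) {
          out[, , at + seq_len(dim(p)[3]), ] <- p
          at <- at + dim(p)[3]
        }
        out
      },
      upsample2 = upsample2_fw(acts[[nd$inputs[1]]]),
      maxpool = {
        r <- .maxpool_fw(acts[[nd$inputs[1]]], nd$cfg$k, 1L,
                         (nd$cfg$k - 1L) %/% 2L)
        aux[[nd$id]] <- r$arg
        r$y
      },
      gap = {
        xin <- acts[[nd$inputs[1]]]
        d <- dim(xin)
        m <- colMeans(matrix(xin, d[1] * d[2], d[3] * d[4]))
        array(m, c(1, 1, d[3], d[4]))
      },
      bmul = {
        xin <- acts[[nd$inputs[1]]]; s <- acts[[nd$inputs[2]]]
        d <- dim(xin)
        xin * rep(as.vector(s), each = d[1] * d[2])
      },
      implicit_add = {
        xin <- acts[[nd$inputs[1]]]
        xin + rep(nd$p$v, each = dim(xin)[1] * dim(xin)[2])
      },
      implicit_mul = {
        xin <- acts[[nd$inputs[1]]]
        xin * rep(nd$p$v, each = dim(xin)[1] * dim(xin)[2])
      },
      stop("unknown op: ", nd$op))
    acts[[nd$id]] <- y
  }
  list(acts = acts, aux = aux)
}

# Reverse sweep. `grads` is a list keyed by node id (character) holding the
# loss gradient w.r.t. that node's output; gradients may be injected at any
# node (head outputs, feature taps, ...). Parameter gradients accumulate into
# node$p$dW / $db / $dv.
nn_backward <- function(model, fw, grads) {
  nodes <- model$nodes
  acts <- fw$acts
  gbuf <- vector("list", length(nodes))
  for (k in names(grads)) {
    id <- as.integer(k)
    gbuf[[id]] <- if (is.null(gbuf[[id]])) grads[[k]] else gbuf[[id]] + grads[[k]]
  }
  for (i in rev(seq_along(nodes))) {
    g <- gbuf[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    switch(nd$op,
      input = NULL,
      conv = {
        xin <- acts[[nd$inputs[1]]]
        r <- .conv2d_bw(xin, nd$p$W, g, nd$cfg$stride, nd$cfg$pad,
                        nd$cfg$groups, nd$cfg$bias)
        nd$p$dW <- if (is.null(nd$p$dW)) r$dw else nd$p$dW + r$dw
        if (nd$cfg$bias)
          nd$p$db <- if (is.null(nd$p$db)) r$db else nd$p$db + r$db
        j <- nd$inputs[1]
        gbuf[[j]] <- if (is.null(gbuf[[j]])) r$dx else gbuf[[j]] + r$dx
      },
      act = {
        j <- nd$inputs[1]
        dg <- act_bw(acts[[j]], g, nd$cfg$kind)
        gbuf[[j]] <- if (is.null(gbuf[[j]])) dg else gbuf[[j]] + dg
      },
      add = {
        for (j in nd$inputs)
          gbuf[[j]] <- if (is.null(gbuf[[j]])) g else gbuf[[j]] + g
      },
      concat = {
        at <- 0L
        for (j in nd$inputs) {
          ch <- dim(acts[[j]])[3]
          part <- g[, , at + seq_len(ch), , drop = FALSE]
          gbuf[[j]] <- if (is.null(gbuf[[j]])) part else gbuf[[j]] + part
          at <- at + ch
        }
      },
      upsample2 = {
        j <- nd$inputs[1]
        dg <- upsample2_bw(g, dim(acts[[j]]))
        gbuf[[j]] <- if (is.null(gbuf[[j]])) dg else gbuf[[j]] + dg
      },
      maxpool = {
        j <- nd$inputs[1]
        dg <- .maxpool_bw(g, fw$aux[[nd$id]], dim(acts[[j]]))
        gbuf[[j]] <- if (is.null(gbuf[[j]])) dg else gbuf[[j]] + dg
      },
      gap = {
        j <- nd$inputs[1]
        d <- dim(acts[[j]])
        dg <- array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), d)
        gbuf[[j]] <- if (is.null(gbuf[[j]])) dg else gbuf[[j]] + dg
      },
      bmul = {
        j1 <- nd$inputs[1]; j2 <- nd$inputs[2]
        xin <- acts[[j1]]; s <- acts[[j2]]
        d <- dim(xin)
        dx <- g * rep(as.vector(s), each = d[1] * d[2])
        ds <- colSums(matrix(g * xin, d[1] * d[2], d[3] * d[4]))
        ds <- array(ds, c(1, 1, d[3], d[4]))
        gbuf[[j1]] <- if (is.null(gbuf[[j1]])) dx else gbuf[[j1]] + dx
        gbuf[[j2]] <- if (is.null(gbuf[[j2]])) ds else gbuf[[j2]] + ds
      },
      implicit_add = {
        j <- nd$inputs[1]
        d <- dim(g)
        dv <- rowSums(matrix(colSums(matrix(g, d[1] * d[2], d[3] * d[4])),
                             d[3], d[4]))
        nd$p$dv <- if (is.null(nd$p$dv)) dv else nd$p$dv + dv
        gbuf[[j]] <- if (is.null(gbuf[[j]])) g else gbuf[[j]] + g
      },
      implicit_mul = {
        j <- nd$inputs[1]
        xin <- acts[[j]]
        d <- dim(g)
        dv <- rowSums(matrix(colSums(matrix(g * xin, d[1] * d[2], d[3] * d[4])),
                             d[3], d[4]))
        nd$p$dv <- if (is.null(nd$p$dv)) dv else nd$p$dv + dv
        dx <- g * rep(nd$p$v, each = d[1] * d[2])
        gbuf[[j]] <- if (is.null(gbuf[[j]])) dx else gbuf[[j]] + dx
      })
  }
  invisible(gbuf)
}

param_nodes <- function(model) {
  Filter(function(nd) length(nd$p$shapes) > 0, model$nodes)
}

zero_grads <- function(model) {
  for (nd in param_nodes(model)) {
    nd$p$dW <- NULL; nd$p$db <- NULL; nd$p$dv <- NULL
  }
  invisible(model)
}

# Scale all parameter gradients so their global L2 norm is at most max_norm.
clip_grads <- function(model, max_norm, extra = list()) {
  envs <- c(lapply(param_nodes(model), function(nd) nd$p), extra)
  sq <- 0
  for (p in envs)
    for (nm in names(p$shapes)) {
      g <- p[[paste0("d", nm)]]
      if (!is.null(g)) sq <- sq + sum(g * g)
    }
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm) {
    s <- max_norm / nrm
    for (p in envs)
      for (nm in names(p$shapes)) {
        gnm <- paste0("d", nm)
        if (!is.null(p[[gnm]])) p[[gnm]] <- p[[gnm]] * s
      }
  }
  invisible(nrm)
}

# SGD with momentum and decoupled weight decay on conv weights.
sgd_step <- function(model, lr, momentum = 0.937, weight_decay = 0.0005) {
  for (nd in param_nodes(model)) {
    p <- nd$p
    for (nm in names(p$shapes)) {
      gnm <- paste0("d", nm)
      g <- p[[gnm]]
      if (is.null(g)) next
      if (nm == "W" && weight_decay > 0) g <- g + weight_decay * p[[nm]]
      mnm <- paste0("m_", nm)
      v <- if (is.null(p[[mnm]])) g else momentum * p[[mnm]] + g
      p[[mnm]] <- v
      p[[nm]] <- p[[nm]] - lr * v
    }
  }
  invisible(model)
}

# Flattened copy of all parameter values (for hashing / restore).
get_params <- function(model) {
  lapply(param_nodes(model), function(nd) {
    p <- nd$p
    stats::setNames(lapply(names(p$shapes), function(nm) p[[nm]]), names(p$shapes))
  })
}

set_params <- function(model, values) {
  pn <- param_nodes(model)
  stopifnot(length(pn) == length(values))
  for (i in seq_along(pn))
    for (nm in names(values[[i]])) pn[[i]]$p[[nm]] <- values[[i]][[nm]]
  invisible(model)
}

# md5 of the serialized parameter values; used for freeze/no-op contracts.
param_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(get_params(model), f, compress = FALSE)
  unname(tools::md5sum(f))
}

# Which scopes ("backbone", "neck", "head") currently hold nonzero parameter
# gradients.
scopes_with_grads <- function(model, tol = 0) {
  hit <- character(0)
  for (nd in param_nodes(model)) {
    p <- nd$p
    nz <- any(vapply(paste0("d", names(p$shapes)), function(g)
      !is.null(p[[g]]) && any(abs(p[[g]]) > tol), logical(1)))
    if (nz) hit <- union(hit, nd$scope)
  }
  sort(hit)
}
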