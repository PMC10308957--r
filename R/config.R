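# ---------------------------------------------------------------------------
# Configuration parsing/validation and the thin command-line orchestration
# layer (subcommand dispatch, run manifests, seed fan-out).
# ---------------------------------------------------------------------------

ld_default_config <- function() {
  list(
    model = list(name = "yolor-light-v1", num_classes = 17L),
    train = list(epochs = 300L, batch_size = 12L, lr0 = 0.01,
                 momentum = 0.937, weight_decay = 5e-4, warmup_epochs = 2,
                 seed = 1L),
    total = list(alpha = 1e-5, beta = 1e-8, theta = 1.0, gamma = 0.5),
    distill = list(
      head = list(w1 = 0.5, w2 = 1.0, w3 = 0.05),
      dm = list(w1 = 0.5, w2 = 1.0, w3 = 0.05),
      backbone = list(temperature = 0.5, w_fg = 1e-3, w_bg = 5e-4,
                      w_attention = 5e-4, w_global = 5e-6),
      neck = list(temperature = 0.5, w_fg = 1e-3, w_bg = 5e-4,
                  w_attention = 5e-4, w_global = 5e-6)),
    nms = list(iou_threshold = 0.65, score_threshold = 0.001),
    assign = list(ratio_threshold = 4.0),
    eval = list(interpolation = "101"),
    synth = list(n_train = 600L, n_test = 150L, image_size = 64L,
                 multi_class_fraction = 0.0074, corruption_fraction = 0,
                 seed = 1L))
}

# Leaf validators keyed by dotted path: list(check, constraint description).
ld_config_rules <- function() {
  pos <- function(x) is.numeric(x) && x > 0
  nonneg <- function(x) is.numeric(x) && x >= 0
  frac <- function(x) is.numeric(x) && x >= 0 && x <= 1
  count <- function(x) is.numeric(x) && x >= 0 && x == round(x)
  rules <- list(
    "model.name" = list(function(x) is.character(x), "must be a string"),
    "model.num_classes" = list(function(x) count(x) && x >= 1, ">= 1 integer"),
    "train.epochs" = list(count, ">= 0 integer"),
    "train.batch_size" = list(function(x) count(x) && x >= 1, ">= 1 integer"),
    "train.lr0" = list(pos, "> 0"),
    "train.momentum" = list(function(x) is.numeric(x) && x >= 0 && x < 1, "in [0, 1)"),
    "train.weight_decay" = list(nonneg, ">= 0"),
    "train.warmup_epochs" = list(nonneg, ">= 0"),
    "train.seed" = list(count, ">= 0 integer"),
    "nms.iou_threshold" = list(frac, "in [0, 1]"),
    "nms.score_threshold" = list(frac, "in [0, 1]"),
    "assign.ratio_threshold" = list(function(x) is.numeric(x) && x > 1, "> 1"),
    "eval.interpolation" = list(function(x) x %in% c("101", "11"),
                                "one of '101', '11'"),
    "synth.n_train" = list(count, ">= 0 integer"),
    "synth.n_test" = list(count, ">= 0 integer"),
    "synth.image_size" = list(function(x) count(x) && x %% 64 == 0,
                              "multiple of 64"),
    "synth.multi_class_fraction" = list(frac, "in [0, 1]"),
    "synth.corruption_fraction" = list(frac, "in [0, 1]"),
    "synth.seed" = list(count, ">= 0 integer"))
  for (k in c("total.alpha", "total.beta", "total.theta", "total.gamma",
              "distill.head.w1", "distill.head.w2", "distill.head.w3",
              "distill.dm.w1", "distill.dm.w2", "distill.dm.w3"))
    rules[[k]] <- list(nonneg, ">= 0")
  for (st in c("backbone", "neck")) {
    rules[[paste0("distill.", st, ".temperature")]] <- list(pos, "> 0")
    for (w in c("w_fg", "w_bg", "w_attention", "w_global"))
      rules[[paste0("distill.", st, ".", w)]] <- list(nonneg, ">= 0")
  }
  rules
}

flatten_config <- function(x, prefix = NULL) {
  if (!is.list(x)) return(stats::setNames(list(x), prefix))
  out <- list()
  for (nm in names(x))
    out <- c(out, flatten_config(x[[nm]],
                                 if (is.null(prefix)) nm else paste0(prefix, ".", nm)))
  out
}

assign_path <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- cfg
  if (length(parts) == 1L) { cfg[[parts]] <- value; return(cfg) }
  sub <- cfg[[parts[1]]]
  cfg[[parts[1]]] <- assign_path(sub, paste(parts[-1], collapse = "."), value)
  cfg
}

#' Parse and validate a configuration
#'
#' Missing keys are filled from the defaults, which carry the reference
#' hyperparameters (loss weights `alpha = 1e-5, beta = 1e-8, theta = 1,
#' gamma = 0.5`; SGD momentum 0.937, weight decay 0.0005, 300 epochs, batch
#' size 12). Unknown keys are rejected; violations name the key path and
#' the constraint.
#'
#' @param path Optional YAML file.
#' @param overrides Named list with dotted key paths, e.g.
#'   `list("total.alpha" = 0)`.
#' @return The validated configuration tree.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- ld_default_config()
  known <- names(flatten_config(cfg))
  apply_flat <- function(cfg, flat, origin) {
    for (k in names(flat)) {
      if (!(k %in% known))
        stop("unknown config key '", k, "' (", origin, ")")
      cfg <- assign_path(cfg, k, flat[[k]])
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- apply_flat(cfg, flatten_config(user), path)
  }
  if (length(overrides)) cfg <- apply_flat(cfg, overrides, "override")
  rules <- ld_config_rules()
  flat <- flatten_config(cfg)
  for (k in names(rules)) {
    v <- flat[[k]]
    if (!rules[[k]][[1]](v))
      stop("config key ", k, " ", rules[[k]][[2]], " (got ",
           deparse(v), ")")
  }
  cfg
}

#' Derive a component seed from the global seed
#'
#' A single global seed fans out to per-component seeds through a fixed
#' offset table, so components are independent yet reproducible.
#' @param seed Global integer seed.
#' @param component One of `"synth"`, `"anchors"`, `"train"`, `"distill"`,
#'   `"eval"`.
#' @export
derive_seed <- function(seed, component) {
  offsets <- c(synth = 101L, anchors = 211L, train = 307L, distill = 401L,
               eval = 503L)
  if (!component %in% names(offsets)) stop("unknown component: ", component)
  (as.integer(seed) * 1009L + offsets[[component]]) %% 2147483587L
}

train_config_from <- function(cfg, seed = NULL, epochs = NULL) {
  train_config(
    epochs = epochs %||% cfg$train$epochs,
    batch_size = cfg$train$batch_size, lr0 = cfg$train$lr0,
    warmup_epochs = cfg$train$warmup_epochs, momentum = cfg$train$momentum,
    weight_decay = cfg$train$weight_decay,
    seed = seed %||% cfg$train$seed,
    dm_weights = do.call(distill_weights, cfg$distill$dm),
    head_weights = do.call(distill_weights, cfg$distill$head),
    stage_weights = do.call(stage_loss_weights, cfg$total),
    distiller = distiller_config(
      temperature = cfg$distill$backbone$temperature,
      w_fg = cfg$distill$backbone$w_fg, w_bg = cfg$distill$backbone$w_bg,
      w_attention = cfg$distill$backbone$w_attention,
      w_global = cfg$distill$backbone$w_global),
    ratio_threshold = cfg$assign$ratio_threshold)
}

write_run_manifest <- function(dir, subcommand, cfg, seed, outputs = list(),
                               metrics = list(), status = "ok") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(
    list(subcommand = subcommand, status = status,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = cfg, outputs = outputs, metrics = metrics),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}

cli_opts <- function(args) {
  opts <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_usage <- function() {
  paste(
    "usage: leafdistill <subcommand> [--options]",
    "subcommands:",
    "  synth   --out DIR [--config FILE] [--seed N]   generate synthetic data",
    "  clean   --data DIR --report FILE               clean labels, write report",
    "  anchors --data DIR --out FILE [--k N] [--seed N]  estimate anchors",
    "  train   --data DIR --out DIR [--model NAME] [--epochs N] [--seed N]",
    "  distill --teacher FILE --data DIR --out DIR [--epochs N] [--seed N]",
    "  eval    --data DIR --model FILE --out DIR      evaluate a checkpoint",
    "  audit   --model NAME [--input-size N]          structural audit",
    sep = "\n")
}

cli_fail <- function(msg) {
  message(msg)
  2L
}

load_train_records <- function(dir, split = "train") {
  recs <- load_synthetic_dataset(dir)
  Filter(function(r) identical(r$split, split), recs)
}

#' Command-line dispatch
#'
#' Entry point behind the `leafdistill` CLI script: parses `argv`, runs the
#' named subcommand, writes a run manifest tying the result to its config
#' and seed, and returns the exit code (0 success, 1 runtime failure,
#' 2 usage error).
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit code, invisibly.
#' @export
dispatch <- function(argv) {
  if (!length(argv)) { message(cli_usage()); return(invisible(2L)) }
  sub <- argv[1]
  parsed <- cli_opts(argv[-1])
  o <- parsed$opts
  need <- function(keys) {
    miss <- setdiff(keys, names(o))
    if (length(miss)) {
      return(cli_fail(paste0("missing required flag --", miss[1], "\n",
                             cli_usage())))
    }
    NULL
  }
  code <- tryCatch(switch(sub,
    synth = {
      if (!is.null(r <- need("out"))) return(invisible(r))
      cfg <- parse_config(o$config)
      seed <- as.integer(o$seed %||% cfg$synth$seed)
      scfg <- synth_config(n_train = cfg$synth$n_train,
                           n_test = cfg$synth$n_test,
                           image_size = cfg$synth$image_size,
                           multi_class_fraction = cfg$synth$multi_class_fraction,
                           corruption_fraction = cfg$synth$corruption_fraction,
                           seed = derive_seed(seed, "synth"))
      recs <- generate_synthetic_dataset(scfg, out_dir = o$out)
      write_run_manifest(o$out, "synth", cfg, seed,
                         outputs = list(dir = o$out),
                         metrics = list(n_images = length(recs)))
      0L
    },
    clean = {
      if (!is.null(r <- need(c("data", "report")))) return(invisible(r))
      recs <- load_synthetic_dataset(o$data)
      cl <- clean_labels(recs)
      dir.create(dirname(o$report), showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(cl$report, o$report, auto_unbox = TRUE)
      write_run_manifest(dirname(o$report), "clean", list(data = o$data),
                         NA, outputs = list(report = o$report),
                         metrics = cl$report)
      0L
    },
    anchors = {
      if (!is.null(r <- need(c("data", "out")))) return(invisible(r))
      recs <- load_synthetic_dataset(o$data, load_images = FALSE)
      wh <- do.call(rbind, lapply(recs, function(r)
        as.matrix(r$instances[, c("w", "h"), drop = FALSE])))
      seed <- as.integer(o$seed %||% 1L)
      aset <- kmeans_anchors(wh, as.integer(o$k %||% 12L),
                             seed = derive_seed(seed, "anchors"))
      write_anchors(aset, o$out)
      write_run_manifest(dirname(o$out), "anchors", list(k = o$k %||% 12L),
                         seed, outputs = list(anchors = o$out))
      0L
    },
    train = ,
    distill = {
      if (!is.null(r <- need(c("data", "out")))) return(invisible(r))
      cfg <- parse_config(o$config)
      seed <- as.integer(o$seed %||% cfg$train$seed)
      data <- load_train_records(o$data)
      wh <- do.call(rbind, lapply(data, function(r)
        as.matrix(r$instances[, c("w", "h"), drop = FALSE])))
      aset <- kmeans_anchors(wh, 12L, seed = derive_seed(seed, "anchors"))
      ncls <- max(vapply(data, function(r)
        if (nrow(r$instances)) max(r$instances$class_id) else 0L, numeric(1)))
      tcfg <- train_config_from(cfg, seed = derive_seed(seed, sub),
                                epochs = as.integer(o$epochs %||% 8L))
      pair <- build_tiny_pair(0.05, ncls, aset)
      if (sub == "train") {
        student <- materialize_params(pair$student, tcfg$seed)
        res <- train_plain(student, data, tcfg)
      } else {
        if (!is.null(r <- need("teacher"))) return(invisible(r))
        teacher <- readRDS(o$teacher)
        student <- materialize_params(pair$student, tcfg$seed)
        res <- train_distilled(teacher, student, data, tcfg)
      }
      dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
      saveRDS(res$model, file.path(o$out, "model.rds"))
      utils::write.csv(res$history, file.path(o$out, "history.csv"),
                       row.names = FALSE)
      write_run_manifest(o$out, sub, cfg, seed,
                         outputs = list(model = file.path(o$out, "model.rds"),
                                        history = file.path(o$out, "history.csv")),
                         metrics = list(final_total =
                           utils::tail(res$history$total, 1)))
      0L
    },
    eval = {
      if (!is.null(r <- need(c("data", "model", "out")))) return(invisible(r))
      model <- readRDS(o$model)
      data <- load_train_records(o$data, split = "test")
      X <- batch_tensor(data, seq_along(data))
      dets <- ld_detect(model, X)
      gts <- lapply(data, function(r) r$instances)
      ev <- evaluate_detections(dets, gts, model$meta$num_classes)
      dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(list(map50 = ev$map50, map5095 = ev$map5095),
                           file.path(o$out, "eval.json"), auto_unbox = TRUE,
                           digits = NA)
      write_run_manifest(o$out, "eval", list(data = o$data), NA,
                         outputs = list(eval = file.path(o$out, "eval.json")),
                         metrics = list(map50 = ev$map50, map5095 = ev$map5095))
      0L
    },
    audit = {
      if (!is.null(r <- need("model"))) return(invisible(r))
      sz <- as.integer(o[["input-size"]] %||% 64L)
      m <- build_model(o$model, num_classes = 17L)
      a <- audit_model(m, c(sz, sz))
      print(a)
      0L
    },
    {
      message("unknown subcommand: ", sub, "\n", cli_usage())
      2L
    }),
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    })
  invisible(code)
}
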