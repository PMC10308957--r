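# ---------------------------------------------------------------------------
# Seeded synthetic multi-crop / multi-disease scene generator: small
# lesion-like blobs on textured leaf backgrounds, visually similar class
# pairs, a small fraction of mixed-disease images, and optional label
# corruption (inflated recorded sizes) to exercise the cleaning pass.
# ---------------------------------------------------------------------------

default_lesion_classes <- function() {
  list(
    list(name = "rust_a", color = c(0.62, 0.33, 0.08), shape = "round",  ring = 0.00),
    list(name = "rust_b", color = c(0.58, 0.30, 0.10), shape = "round",  ring = 0.35),
    list(name = "spot_a", color = c(0.30, 0.28, 0.24), shape = "angular", ring = 0.00),
    list(name = "spot_b", color = c(0.26, 0.26, 0.26), shape = "angular", ring = 0.30),
    list(name = "blight", color = c(0.75, 0.64, 0.18), shape = "streak", ring = 0.00),
    list(name = "mildew", color = c(0.88, 0.88, 0.82), shape = "round",  ring = 0.00))
}

#' Synthetic dataset configuration
#'
#' Defaults form the standard desk-scale benchmark: 600 train / 150 test
#' images of 64x64 px, 6 classes including two visually similar pairs
#' (rust_a/rust_b and spot_a/spot_b differ only by a faint ring and small
#' color offsets), 1-3 lesions per image, and 0.74% of images containing
#' two disease classes.
#'
#' @param n_train,n_test Split sizes.
#' @param image_size Square image side, pixels.
#' @param classes Lesion appearance list (see `default_lesion_classes`).
#' @param lesions_min,lesions_max Per-image lesion count range.
#' @param multi_class_fraction Fraction of images holding two classes.
#' @param corruption_fraction Fraction of records whose recorded label size
#'   is inflated by a factor in `corruption_range` (boxes scaled to match),
#'   the ground truth for cleaning tests.
#' @param corruption_range Inflation factor range.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @export
synth_config <- function(n_train = 600L, n_test = 150L, image_size = 64L,
                         classes = default_lesion_classes(),
                         lesions_min = 1L, lesions_max = 3L,
                         multi_class_fraction = 0.0074,
                         corruption_fraction = 0,
                         corruption_range = c(1.5, 3), seed = 1L) {
  stopifnot(n_train >= 0, n_test >= 0, length(classes) >= 2,
            multi_class_fraction >= 0, multi_class_fraction <= 1,
            corruption_fraction >= 0, corruption_fraction <= 1)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 image_size = as.integer(image_size), classes = classes,
                 lesions_min = as.integer(lesions_min),
                 lesions_max = as.integer(lesions_max),
                 multi_class_fraction = multi_class_fraction,
                 corruption_fraction = corruption_fraction,
                 corruption_range = corruption_range, seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
class_names <- function(cfg) vapply(cfg$classes, `[[`, character(1), "name")

# One lesion: elliptical (optionally angular-modulated or elongated) blob
# with smooth falloff; returns the alpha mask and its tight bounding box.
render_lesion <- function(sz, spec, cx, cy, rx, ry, angle, phase) {
  xs <- matrix(rep(seq_len(sz) - 0.5, each = sz), sz, sz) # columns -> x
  ys <- matrix(rep(seq_len(sz) - 0.5, times = sz), sz, sz) # rows -> y
  dx <- xs - cx; dy <- ys - cy
  xr <- dx * cos(angle) + dy * sin(angle)
  yr <- -dx * sin(angle) + dy * cos(angle)
  if (spec$shape == "streak") { rx <- rx * 1.8; ry <- ry * 0.45 }
  d <- sqrt((xr / rx)^2 + (yr / ry)^2)
  if (spec$shape == "angular") {
    th <- atan2(yr / ry, xr / rx)
    d <- d / (1 + 0.22 * sin(5 * th + phase))
  }
  alpha <- exp(-3 * pmax(d, 0)^4)
  alpha[alpha < 0.05] <- 0
  ring <- if (spec$ring > 0) spec$ring * exp(-((d - 0.85) / 0.12)^2) else 0
  sel <- which(alpha > 0, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  # pixel (row i, col j) covers [j-1, j] x [i-1, i] in continuous coords
  x1 <- min(sel[, 2]) - 1; x2 <- max(sel[, 2])
  y1 <- min(sel[, 1]) - 1; y2 <- max(sel[, 1])
  list(alpha = alpha, ring = ring, box = bbox_from_corners(x1, y1, x2, y2))
}

leaf_background <- function(sz) {
  base <- c(stats::runif(1, 0.15, 0.30), stats::runif(1, 0.42, 0.60),
            stats::runif(1, 0.12, 0.25))
  u <- (seq_len(sz) - 0.5) / sz
  f1 <- stats::runif(1, 1, 3); f2 <- stats::runif(1, 2, 5)
  p1 <- stats::runif(2, 0, 2 * pi)
  tex <- outer(sin(2 * pi * f1 * u + p1[1]), cos(2 * pi * f2 * u + p1[2])) * 0.05
  vein <- 0.04 * exp(-((matrix(rep(u, each = sz), sz, sz) -
                        matrix(rep(u, times = sz), sz, sz)) / 0.04)^2)
  noise <- matrix(stats::rnorm(sz * sz, sd = 0.015), sz, sz)
  img <- array(0, c(sz, sz, 3))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + tex + vein + noise, 0), 1)
  img
}

#' Generate a synthetic lesion-scene dataset
#'
#' Deterministic for a fixed seed (pixel-identical images, byte-identical
#' annotations). Every lesion's recorded box is the tight bounding box of
#' its rendered extent. When `out_dir` is given, PNG images plus a JSON
#' manifest are written; records always carry their pixel data in memory
#' when `render = TRUE`.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Optional output directory.
#' @param render When `FALSE`, only layout records (no pixels) are produced
#'   -- cheap mode for statistical checks on large `n`; boxes then use the
#'   analytic ellipse extent.
#' @return List of records: [image_record()] fields plus `class_id` column
#'   in `instances`, `split`, and (render mode) `image` `[H, W, 3]`.
#' @export
generate_synthetic_dataset <- function(cfg = synth_config(), out_dir = NULL,
                                       render = TRUE) {
  n <- cfg$n_train + cfg$n_test
  if (n < 0) stop("negative image count")
  set.seed(cfg$seed)
  sz <- cfg$image_size
  cls_names <- class_names(cfg)
  nc <- length(cls_names)
  records <- vector("list", n)
  split <- rep(c("train", "test"), c(cfg$n_train, cfg$n_test))
  for (i in seq_len(n)) {
    k <- sample(cfg$lesions_min:cfg$lesions_max, 1)
    multi <- stats::runif(1) < cfg$multi_class_fraction
    if (multi) k <- max(k, 2L)
    c1 <- sample.int(nc, 1)
    lesion_cls <- rep(c1, k)
    if (multi) {
      c2 <- sample(setdiff(seq_len(nc), c1), 1)
      lesion_cls[sample.int(k, max(1L, k %/% 2L))] <- c2
    }
    img <- if (render) leaf_background(sz)
    inst <- NULL
    for (j in seq_len(k)) {
      spec <- cfg$classes[[lesion_cls[j]]]
      rx <- stats::runif(1, 4, 11); ry <- stats::runif(1, 4, 11)
      cx <- stats::runif(1, rx + 2, sz - rx - 2)
      cy <- stats::runif(1, ry + 2, sz - ry - 2)
      angle <- stats::runif(1, 0, pi); phase <- stats::runif(1, 0, 2 * pi)
      jit <- stats::rnorm(3, 0, 0.03)
      if (render) {
        les <- render_lesion(sz, spec, cx, cy, rx, ry, angle, phase)
        if (is.null(les)) next
        col <- pmin(pmax(spec$color + jit, 0), 1)
        a <- les$alpha * 0.9
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] * (1 - a) + (col[ch] - les$ring) * a
        box <- les$box
      } else {
        rxe <- if (spec$shape == "streak") rx * 1.8 else rx
        rye <- if (spec$shape == "streak") ry * 0.45 else ry
        ex <- sqrt((rxe * cos(angle))^2 + (rye * sin(angle))^2)
        ey <- sqrt((rxe * sin(angle))^2 + (rye * cos(angle))^2)
        box <- bbox(cx, cy, 2 * ex, 2 * ey)
      }
      inst <- rbind(inst, data.frame(class = cls_names[lesion_cls[j]],
                                     class_id = lesion_cls[j],
                                     cx = box[, 1], cy = box[, 2],
                                     w = box[, 3], h = box[, 4]))
    }
    if (is.null(inst))
      inst <- data.frame(class = character(0), class_id = integer(0),
                         cx = numeric(0), cy = numeric(0), w = numeric(0),
                         h = numeric(0))
    rec <- image_record(sprintf("img_%05d.png", i), c(sz, sz), c(sz, sz),
                        inst, split = split[i])
    if (render) {
      # quantize to 8-bit so in-memory pixels equal the PNG exactly
      img <- round(pmin(pmax(img, 0), 1) * 255) / 255
      rec$image <- img
    }
    records[[i]] <- rec
  }
  # label corruption: inflate recorded sizes, scale boxes to match
  if (cfg$corruption_fraction > 0 && n > 0) {
    nc_corrupt <- round(cfg$corruption_fraction * n)
    which_c <- sample.int(n, nc_corrupt)
    for (i in which_c) {
      f <- stats::runif(1, cfg$corruption_range[1], cfg$corruption_range[2])
      rec <- records[[i]]
      newsize <- round(rec$actual_size * f)
      sx <- newsize[1] / rec$actual_size[1]
      sy <- newsize[2] / rec$actual_size[2]
      rec$instances$cx <- rec$instances$cx * sx
      rec$instances$w <- rec$instances$w * sx
      rec$instances$cy <- rec$instances$cy * sy
      rec$instances$h <- rec$instances$h * sy
      rec$recorded_size <- newsize
      rec$corrupted <- TRUE
      records[[i]] <- rec
    }
  }
  if (!is.null(out_dir)) write_synthetic_dataset(records, cfg, out_dir)
  records
}

write_synthetic_dataset <- function(records, cfg, out_dir) {
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE, recursive = TRUE)
  for (rec in records)
    if (!is.null(rec$image))
      png::writePNG(rec$image, file.path(out_dir, "images", rec$path))
  manifest <- list(
    class_names = class_names(cfg),
    image_size = cfg$image_size,
    seed = cfg$seed,
    records = lapply(records, function(rec) {
      img_path <- file.path(out_dir, "images", rec$path)
      list(path = rec$path, split = rec$split,
           recorded_size = rec$recorded_size, actual_size = rec$actual_size,
           corrupted = isTRUE(rec$corrupted),
           md5 = if (file.exists(img_path))
             unname(tools::md5sum(img_path)) else NA,
           instances = rec$instances)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Load a synthetic dataset written by [generate_synthetic_dataset()]
#' @param dir Dataset directory containing `manifest.json` and `images/`.
#' @param load_images Read PNG pixel data into each record.
#' @export
load_synthetic_dataset <- function(dir, load_images = TRUE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$records, function(m) {
    inst <- as.data.frame(do.call(rbind, lapply(m$instances, function(r)
      data.frame(class = r$class, class_id = r$class_id, cx = r$cx,
                 cy = r$cy, w = r$w, h = r$h))))
    if (!length(m$instances))
      inst <- data.frame(class = character(0), class_id = integer(0),
                         cx = numeric(0), cy = numeric(0), w = numeric(0),
                         h = numeric(0))
    rec <- image_record(m$path, unlist(m$recorded_size),
                        unlist(m$actual_size), inst, split = m$split)
    if (load_images) {
      img <- png::readPNG(file.path(dir, "images", m$path))
      rec$image <- img
      rec$actual_size <- c(dim(img)[2], dim(img)[1])
    }
    rec
  })
}
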