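# ---------------------------------------------------------------------------
# Annotation I/O (Pascal-VOC XML and COCO JSON dialects) and the
# label-cleaning pass (recorded-size repair, clipping, degenerate-box drop).
#
# Internal convention: continuous center-form boxes (cx, cy, w, h), origin
# top-left. VOC files store 1-based inclusive integer pixel corners, so a
# VOC box spans [xmin-1, xmax] in continuous coordinates; COCO stores
# top-left + width/height floats.
# ---------------------------------------------------------------------------

#' Image record
#'
#' @param path Image file name (relative to the dataset root).
#' @param recorded_size `c(w, h)` as stated by the label file.
#' @param actual_size `c(w, h)` of the image itself (NA when unreadable).
#' @param instances Data frame with columns `class` (name), `cx, cy, w, h`.
#' @param split Optional split membership (`"train"` / `"test"`).
#' @export
image_record <- function(path, recorded_size, actual_size = recorded_size,
                         instances = NULL, split = NA_character_) {
  if (is.null(instances))
    instances <- data.frame(class = character(0), cx = numeric(0),
                            cy = numeric(0), w = numeric(0), h = numeric(0))
  structure(list(path = path, recorded_size = as.numeric(recorded_size),
                 actual_size = as.numeric(actual_size),
                 instances = instances, split = split),
            class = "image_record")
}

voc_from_corners <- function(xmin, ymin, xmax, ymax) {
  bbox_from_corners(xmin - 1, ymin - 1, xmax, ymax)
}

voc_to_corners <- function(b) {
  co <- box_corners(b)
  cbind(xmin = round(co[, 1] + 1), ymin = round(co[, 2] + 1),
        xmax = round(co[, 3]), ymax = round(co[, 4]))
}

read_voc_file <- function(f, classes = NULL) {
  doc <- tryCatch(xml2::read_xml(f), error = function(e)
    stop("malformed VOC file ", f, ": ", conditionMessage(e)))
  need <- function(node, field, parent = doc) {
    x <- xml2::xml_find_first(parent, node)
    if (inherits(x, "xml_missing"))
      stop("malformed VOC file ", f, ": missing field ", field)
    x
  }
  w <- as.numeric(xml2::xml_text(need(".//size/width", "size/width")))
  h <- as.numeric(xml2::xml_text(need(".//size/height", "size/height")))
  fn <- xml2::xml_text(need(".//filename", "filename"))
  objs <- xml2::xml_find_all(doc, ".//object")
  inst <- do.call(rbind, lapply(objs, function(o) {
    nm <- xml2::xml_text(need(".//name", "object/name", o))
    if (!is.null(classes) && !(nm %in% classes))
      stop("unknown class '", nm, "' in ", f)
    bb <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(k)
      as.numeric(xml2::xml_text(need(paste0(".//bndbox/", k),
                                     paste0("bndbox/", k), o))), numeric(1))
    b <- voc_from_corners(bb[1], bb[2], bb[3], bb[4])
    data.frame(class = nm, cx = b[, 1], cy = b[, 2], w = b[, 3], h = b[, 4])
  }))
  if (is.null(inst))
    inst <- data.frame(class = character(0), cx = numeric(0), cy = numeric(0),
                       w = numeric(0), h = numeric(0))
  image_record(fn, c(w, h), c(w, h), inst)
}

#' Read object-detection annotations
#'
#' @param path VOC: a directory of `.xml` files (or a vector of files);
#'   COCO: a single JSON file.
#' @param dialect `"voc"` or `"coco"`.
#' @param classes Optional closed class list; unknown class names error.
#' @return List of [image_record()]s. `actual_size` is taken from the label
#'   file (use [clean_labels()] with readable images to reconcile).
#' @export
read_annotations <- function(path, dialect = c("voc", "coco"), classes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "voc") {
    files <- if (length(path) == 1L && dir.exists(path))
      list.files(path, pattern = "\\.xml$", full.names = TRUE) else path
    return(lapply(sort(files), read_voc_file, classes = classes))
  }
  if (!file.exists(path)) stop("malformed COCO file ", path, ": not found")
  j <- tryCatch(jsonlite::read_json(path), error = function(e)
    stop("malformed COCO file ", path, ": ", conditionMessage(e)))
  for (field in c("images", "annotations", "categories"))
    if (is.null(j[[field]]))
      stop("malformed COCO file ", path, ": missing field ", field)
  cats <- stats::setNames(
    vapply(j$categories, function(x) x$name, character(1)),
    vapply(j$categories, function(x) as.character(x$id), character(1)))
  if (!is.null(classes) && !all(cats %in% classes))
    stop("unknown class '", setdiff(cats, classes)[1], "' in ", path)
  anns_by_img <- split(j$annotations,
                       vapply(j$annotations, function(a)
                         as.character(a$image_id), character(1)))
  lapply(j$images, function(im) {
    anns <- anns_by_img[[as.character(im$id)]]
    inst <- do.call(rbind, lapply(anns, function(a) {
      bb <- as.numeric(unlist(a$bbox))
      data.frame(class = unname(cats[as.character(a$category_id)]),
                 cx = bb[1] + bb[3] / 2, cy = bb[2] + bb[4] / 2,
                 w = bb[3], h = bb[4])
    }))
    if (is.null(inst))
      inst <- data.frame(class = character(0), cx = numeric(0),
                         cy = numeric(0), w = numeric(0), h = numeric(0))
    image_record(im$file_name, c(im$width, im$height),
                 c(im$width, im$height), inst)
  })
}

#' Write object-detection annotations
#'
#' Inverse of [read_annotations()]. VOC output rounds to the dialect's
#' integer corner convention; COCO output keeps float precision and carries
#' the standard `images` / `annotations` / `categories` fields.
#'
#' @param records List of [image_record()]s.
#' @param path VOC: output directory; COCO: output JSON file.
#' @param dialect `"voc"` or `"coco"`.
#' @export
write_annotations <- function(records, path, dialect = c("voc", "coco")) {
  dialect <- match.arg(dialect)
  if (dialect == "voc") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (rec in records) {
      doc <- xml2::xml_new_root("annotation")
      xml2::xml_add_child(doc, "filename", rec$path)
      sz <- xml2::xml_add_child(doc, "size")
      xml2::xml_add_child(sz, "width", format(rec$recorded_size[1]))
      xml2::xml_add_child(sz, "height", format(rec$recorded_size[2]))
      if (nrow(rec$instances)) {
        co <- voc_to_corners(as.matrix(rec$instances[, c("cx", "cy", "w", "h")]))
        for (i in seq_len(nrow(rec$instances))) {
          ob <- xml2::xml_add_child(doc, "object")
          xml2::xml_add_child(ob, "name", rec$instances$class[i])
          bb <- xml2::xml_add_child(ob, "bndbox")
          for (k in colnames(co))
            xml2::xml_add_child(bb, k, format(co[i, k]))
        }
      }
      out <- file.path(path, paste0(tools::file_path_sans_ext(basename(rec$path)),
                                    ".xml"))
      xml2::write_xml(doc, out)
    }
    return(invisible(path))
  }
  classes <- sort(unique(unlist(lapply(records, function(r) r$instances$class))))
  ann_id <- 0L
  anns <- list(); imgs <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    imgs[[i]] <- list(id = i, file_name = rec$path,
                      width = rec$recorded_size[1], height = rec$recorded_size[2])
    if (nrow(rec$instances))
      for (k in seq_len(nrow(rec$instances))) {
        ann_id <- ann_id + 1L
        inst <- rec$instances[k, ]
        anns[[ann_id]] <- list(
          id = ann_id, image_id = i,
          category_id = match(inst$class, classes),
          bbox = c(inst$cx - inst$w / 2, inst$cy - inst$h / 2, inst$w, inst$h),
          area = inst$w * inst$h, iscrowd = 0L)
      }
  }
  jsonlite::write_json(
    list(images = imgs, annotations = anns,
         categories = lapply(seq_along(classes), function(i)
           list(id = i, name = classes[i]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Clean annotation records
#'
#' Per-instance rule order: (1) if the recorded image size differs from the
#' actual size, rescale boxes by `actual/recorded` per axis and fix the
#' record; (2) clip boxes to the image bounds; (3) drop boxes whose width or
#' height is `<= min_size` pixels after clipping. Each instance is tallied
#' once, with precedence dropped > rescaled > clipped > unchanged. The pass
#' is idempotent and never adds instances. Records whose image could not be
#' read (`actual_size` NA) are quarantined, not cleaned.
#'
#' @param records List of [image_record()]s with `actual_size` filled in.
#' @param min_size Post-clip side length at or below which a box is dropped.
#' @return List with `records` (cleaned), `report` (counts `n_rescaled,
#'   n_clipped, n_dropped, n_unchanged`) and `quarantined` (paths).
#' @export
clean_labels <- function(records, min_size = 1) {
  rep <- c(n_rescaled = 0L, n_clipped = 0L, n_dropped = 0L, n_unchanged = 0L)
  quarantined <- character(0)
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (any(is.na(rec$actual_size))) {
      quarantined <- c(quarantined, rec$path)
      out[[i]] <- rec
      next
    }
    inst <- rec$instances
    if (!nrow(inst)) {
      rec$recorded_size <- rec$actual_size
      out[[i]] <- rec
      next
    }
    rescaled <- rep(FALSE, nrow(inst))
    if (any(rec$recorded_size != rec$actual_size)) {
      sx <- rec$actual_size[1] / rec$recorded_size[1]
      sy <- rec$actual_size[2] / rec$recorded_size[2]
      inst$cx <- inst$cx * sx; inst$w <- inst$w * sx
      inst$cy <- inst$cy * sy; inst$h <- inst$h * sy
      rec$recorded_size <- rec$actual_size
      rescaled[] <- TRUE
    }
    co <- box_corners(as.matrix(inst[, c("cx", "cy", "w", "h")]))
    cl <- cbind(pmax(co[, 1], 0), pmax(co[, 2], 0),
                pmin(co[, 3], rec$actual_size[1]),
                pmin(co[, 4], rec$actual_size[2]))
    clipped <- apply(abs(cl - co) > 1e-12, 1, any)
    cl[, 3] <- pmax(cl[, 3], cl[, 1]); cl[, 4] <- pmax(cl[, 4], cl[, 2])
    nb <- bbox_from_corners(cl[, 1], cl[, 2], cl[, 3], cl[, 4])
    inst$cx <- nb[, 1]; inst$cy <- nb[, 2]; inst$w <- nb[, 3]; inst$h <- nb[, 4]
    drop <- inst$w <= min_size | inst$h <= min_size
    rep["n_dropped"] <- rep["n_dropped"] + sum(drop)
    rep["n_rescaled"] <- rep["n_rescaled"] + sum(rescaled & !drop)
    rep["n_clipped"] <- rep["n_clipped"] + sum(clipped & !rescaled & !drop)
    rep["n_unchanged"] <- rep["n_unchanged"] + sum(!clipped & !rescaled & !drop)
    rec$instances <- inst[!drop, , drop = FALSE]
    rownames(rec$instances) <- NULL
    out[[i]] <- rec
  }
  list(records = out, report = as.list(rep), quarantined = quarantined)
}
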