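# Labeled images and annotation I/O (Pascal VOC XML and YOLO txt).
#
# Internal convention: boxes are center-format (cx, cy, w, h) in 0-based,
# half-open pixel coordinates.  The VOC corner view is 1-based inclusive
# (xmin = x1 + 1, xmax = x2); YOLO lines are "class cx cy w h" normalized
# to [0, 1] by the image size.

#' Labeled image container
#'
#' @param image H x W x 3 array with values in `[0, 1]`.
#' @param boxes n x 4 matrix of center-format boxes (`cx, cy, w, h`, pixels),
#'   or `NULL`.
#' @param class_ids integer class per box (default all 1, class `"spike"`).
#' @param id source identifier string.
#' @return list of class `labeled_image`.
#' @export
labeled_image <- function(image, boxes = NULL, class_ids = NULL, id = "img") {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be an H x W x 3 array")
  if (!is.null(boxes) && nrow(boxes)) {
    boxes <- as_box_matrix(boxes)
    cc <- xywh_to_xyxy(boxes)
    eps <- 1e-6
    if (any(cc[, 1] < -eps) || any(cc[, 2] < -eps) ||
        any(cc[, 3] > d[2] + eps) || any(cc[, 4] > d[1] + eps)) {
      stop("boxes must lie within image bounds")
    }
    if (is.null(class_ids)) class_ids <- rep(1L, nrow(boxes))
  } else {
    boxes <- matrix(numeric(0), 0, 4,
                    dimnames = list(NULL, c("cx", "cy", "w", "h")))
    class_ids <- integer(0)
  }
  structure(list(image = image, boxes = boxes,
                 class_ids = as.integer(class_ids), id = id),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_image '%s': %dx%d px, %d boxes>\n",
              x$id, d[2], d[1], nrow(x$boxes)))
  invisible(x)
}

#' Read / write Pascal VOC XML annotations
#'
#' @param path XML file path.
#' @param classes class-name vector mapping names to integer ids
#'   (default `"spike"`).
#' @return `read_voc_xml` returns a list with `size = c(h, w)`, `boxes`
#'   (center format, pixels) and `class_ids`.
#' @export
read_voc_xml <- function(path, classes = "spike") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML '", path, "': ",
                                           conditionMessage(e)))
  size <- xml2::xml_find_first(doc, ".//size")
  if (is.na(xml2::xml_find_first(doc, ".//size"))) {
    stop("VOC XML '", path, "': missing <size> element")
  }
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (!is.finite(w) || !is.finite(h)) {
    stop("VOC XML '", path, "': non-numeric <width>/<height>")
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- matrix(numeric(0), 0, 4)
  ids <- integer(0)
  for (ob in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "./name"))
    bb <- xml2::xml_find_first(ob, "./bndbox")
    if (is.na(bb)) stop("VOC XML '", path, "': <object> without <bndbox>")
    co <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(tag) {
      v <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
      if (!is.finite(v)) {
        stop("VOC XML '", path, "': bad <", tag, "> in <bndbox>")
      }
      v
    }, numeric(1))
    # 1-based inclusive corners -> 0-based half-open
    boxes <- rbind(boxes, c(co[1] - 1, co[2] - 1, co[3], co[4]))
    id <- match(nm, classes)
    ids <- c(ids, if (is.na(id)) 1L else id)
  }
  boxes <- if (nrow(boxes)) xyxy_to_xywh(boxes) else
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("cx", "cy", "w", "h")))
  list(size = c(h = h, w = w), boxes = boxes, class_ids = ids)
}

#' @rdname read_voc_xml
#' @param item a [labeled_image()].
#' @export
write_voc_xml <- function(item, path, classes = "spike") {
  d <- dim(item$image)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(item$id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(d[2]))
  xml2::xml_add_child(size, "height", as.character(d[1]))
  xml2::xml_add_child(size, "depth", "3")
  if (nrow(item$boxes)) {
    cc <- xywh_to_xyxy(item$boxes)
    for (i in seq_len(nrow(cc))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", classes[item$class_ids[i]])
      xml2::xml_add_child(ob, "difficult", "0")
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(cc[i, 1] + 1, digits = 10))
      xml2::xml_add_child(bb, "ymin", format(cc[i, 2] + 1, digits = 10))
      xml2::xml_add_child(bb, "xmax", format(cc[i, 3], digits = 10))
      xml2::xml_add_child(bb, "ymax", format(cc[i, 4], digits = 10))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write YOLO txt annotations
#'
#' One line per box: `class cx cy w h`, all coordinates normalized to
#' `[0, 1]` by the image width/height; class ids are 0-based on disk.
#'
#' @param path txt file path.
#' @param img_w,img_h image dimensions in pixels (needed to denormalize).
#' @return `read_yolo_txt` returns `boxes` (center format, pixels) and
#'   `class_ids`; an empty or absent-object file yields zero boxes.
#' @export
read_yolo_txt <- function(path, img_w, img_h) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  boxes <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("cx", "cy", "w", "h")))
  ids <- integer(0)
  for (i in seq_along(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 5L || any(!is.finite(f))) {
      stop("YOLO txt '", path, "' line ", i, ": expected 'class cx cy w h'")
    }
    boxes <- rbind(boxes, c(f[2] * img_w, f[3] * img_h,
                            f[4] * img_w, f[5] * img_h))
    ids <- c(ids, as.integer(f[1]) + 1L)
  }
  list(boxes = boxes, class_ids = ids)
}

#' @rdname read_yolo_txt
#' @param item a [labeled_image()].
#' @export
write_yolo_txt <- function(item, path) {
  d <- dim(item$image)
  lines <- character(0)
  if (nrow(item$boxes)) {
    b <- item$boxes
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", item$class_ids - 1L,
                     b[, 1] / d[2], b[, 2] / d[1], b[, 3] / d[2], b[, 4] / d[1])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a labeled dataset from an images/ + labels/ directory layout
#'
#' Reads every PNG in `dir/images` and its matching annotation from
#' `dir/labels` (YOLO `<stem>.txt`, falling back to VOC `<stem>.xml`).
#'
#' @param dir dataset root directory.
#' @return list of [labeled_image()] objects.
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no PNG images under ", file.path(dir, "images"))
  lapply(imgs, function(f) {
    stem <- sub("\\.png$", "", basename(f))
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    img <- img[, , 1:3, drop = FALSE]
    d <- dim(img)
    txt <- file.path(dir, "labels", paste0(stem, ".txt"))
    xml <- file.path(dir, "labels", paste0(stem, ".xml"))
    ann <- if (file.exists(txt)) read_yolo_txt(txt, d[2], d[1])
    else if (file.exists(xml)) read_voc_xml(xml)
    else list(boxes = NULL, class_ids = NULL)
    labeled_image(img, ann$boxes, ann$class_ids, id = stem)
  })
}
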