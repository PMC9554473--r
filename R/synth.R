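# Deterministic generator of wheat-field-like scenes.
#
# Spikes are rendered as textured, rotated ellipses with a few awn-like
# strokes extending from the tip, over a low-frequency textured background.
# The generator's contract is geometric: exact per-spike tight bounding
# boxes, controllable density/overlap, and a background that may share the
# spike's hue ("green_similar") or contrast with it ("yellow_contrast").
# Rendering is a stylized stand-in for field imagery, not photorealism.

#' Scene specification
#'
#' @param canvas `c(h, w)` canvas size in pixels.
#' @param n_spikes number of spikes to render.
#' @param length_range,width_range spike major/minor axis ranges (pixels).
#' @param orientation_range orientation range in degrees.
#' @param overlap_target fraction of spikes whose box should intersect
#'   another spike's box; the realized fraction tracks this within about
#'   0.1 for 30 or more spikes.
#' @param background `"green_similar"` (background hue close to the spikes)
#'   or `"yellow_contrast"`.
#' @param seed integer seed; scenes are byte-identical per seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(canvas = c(640L, 640L), n_spikes = 40L,
                       length_range = c(42, 80), width_range = c(12, 20),
                       orientation_range = c(-90, 90),
                       overlap_target = 0.3,
                       background = c("green_similar", "yellow_contrast"),
                       seed = 1L) {
  background <- match.arg(background)
  stopifnot(n_spikes >= 0, all(length_range > 0), all(width_range > 0),
            overlap_target >= 0, overlap_target <= 1, length(canvas) == 2)
  if (min(canvas) < max(length_range) * 1.4) {
    stop("canvas too small for the requested spike length range")
  }
  structure(list(canvas = as.integer(canvas), n_spikes = as.integer(n_spikes),
                 length_range = length_range, width_range = width_range,
                 orientation_range = orientation_range,
                 overlap_target = overlap_target, background = background,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth value-noise field via a coarse random grid upsampled bilinearly
value_noise <- function(h, w, cell = 32L, amp = 1) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- array(stats::runif(gh * gw, -amp, amp), dim = c(gh, gw, 1L))
  bilinear_resize(g, h, w)[, , 1]
}

snap8 <- function(x) round(clamp(x, 0, 1) * 255) / 255

#' Render one synthetic wheat-field scene
#'
#' @param spec a [scene_spec()].
#' @return a [labeled_image()] with one tight box per rendered spike; the
#'   realized overlap fraction is stored in attribute `"overlap_fraction"`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  h <- spec$canvas[1]; w <- spec$canvas[2]

  bg_col <- if (spec$background == "green_similar") c(0.30, 0.42, 0.22)
  else c(0.72, 0.66, 0.30)
  spike_col <- c(0.38, 0.52, 0.26)

  img <- array(0, dim = c(h, w, 3L))
  coarse <- value_noise(h, w, 48L, 0.08)
  fine <- matrix(stats::runif(h * w, -0.03, 0.03), h, w)
  for (c in 1:3) img[, , c] <- bg_col[c] + coarse + fine

  boxes <- NULL
  placed <- list()  # corner boxes of placed spikes
  overlaps <- logical(0)
  margin <- max(spec$length_range) / 2 + 6

  for (i in seq_len(spec$n_spikes)) {
    a <- stats::runif(1, spec$length_range[1], spec$length_range[2]) / 2
    b <- stats::runif(1, spec$width_range[1], spec$width_range[2]) / 2
    th <- stats::runif(1, spec$orientation_range[1],
                       spec$orientation_range[2]) * pi / 180
    frac_now <- if (length(overlaps)) mean(overlaps) else 0
    want_overlap <- length(placed) > 0 && frac_now < spec$overlap_target
    # predicted half-extents of the resulting box (ellipse plus awns)
    ex <- abs(cos(th)) * 1.7 * a + abs(sin(th)) * b + 2
    ey <- abs(sin(th)) * 1.7 * a + abs(cos(th)) * b + 2
    ok_center <- NULL
    for (try in 1:60) {
      if (want_overlap) {
        # prefer a partner already counted as overlapping, so the realized
        # fraction moves up by only one spike at a time
        pool <- which(overlaps)
        if (!length(pool)) pool <- seq_along(placed)
        j <- pool[sample.int(length(pool), 1)]
        pc <- placed[[j]]
        cand <- c(stats::runif(1, pc$cx - pc$a, pc$cx + pc$a),
                  stats::runif(1, pc$cy - pc$a, pc$cy + pc$a))
        ok_center <- clamp(cand, margin, c(w, h) - margin)
        break
      }
      cand <- c(stats::runif(1, margin, w - margin),
                stats::runif(1, margin, h - margin))
      hits <- any(vapply(placed, function(p) {
        cand[1] - ex < p$box[3] && p$box[1] < cand[1] + ex &&
          cand[2] - ey < p$box[4] && p$box[2] < cand[2] + ey
      }, logical(1)))
      if (!hits || try == 60) { ok_center <- cand; break }
    }
    cx <- ok_center[1]; cy <- ok_center[2]

    # rasterize the rotated ellipse on a local patch
    ext <- ceiling(a + 8)
    px <- clamp(round(cx) + (-ext:ext), 1, w)
    py <- clamp(round(cy) + (-ext:ext), 1, h)
    px <- unique(px); py <- unique(py)
    X <- matrix(px, length(py), length(px), byrow = TRUE) - cx
    Y <- matrix(py, length(py), length(px)) - cy
    U <- X * cos(th) + Y * sin(th)
    V <- -X * sin(th) + Y * cos(th)
    mask <- (U / a)^2 + (V / b)^2 <= 1

    # awn strokes from the spike tip
    tipx <- cx + a * cos(th); tipy <- cy + a * sin(th)
    awn_pts <- NULL
    for (k in 1:3) {
      ang <- th + stats::runif(1, -0.35, 0.35)
      len <- stats::runif(1, 0.15, 0.3) * 2 * a
      t <- seq(0, 1, length.out = max(4L, ceiling(len)))
      ax <- round(tipx + t * len * cos(ang))
      ay <- round(tipy + t * len * sin(ang))
      keep <- ax >= 1 & ax <= w & ay >= 1 & ay <= h
      if (any(keep)) awn_pts <- rbind(awn_pts, cbind(ay[keep], ax[keep]))
    }

    # paint: grain texture along the spike axis plus speckle
    sel <- which(mask, arr.ind = TRUE)
    if (nrow(sel)) {
      rows <- py[sel[, 1]]; cols <- px[sel[, 2]]
      tex <- 0.10 * sin(U[sel] * 1.4) + stats::runif(nrow(sel), -0.06, 0.06)
      for (c in 1:3) {
        img[cbind(rows, cols, c)] <- spike_col[c] + tex
      }
    }
    if (!is.null(awn_pts)) {
      for (c in 1:3) {
        img[cbind(awn_pts[, 1], awn_pts[, 2], c)] <- spike_col[c] + 0.08
      }
    }

    # tight box over every rendered pixel (ellipse + awns)
    all_r <- c(if (nrow(sel)) py[sel[, 1]],
               if (!is.null(awn_pts)) awn_pts[, 1])
    all_c <- c(if (nrow(sel)) px[sel[, 2]],
               if (!is.null(awn_pts)) awn_pts[, 2])
    x1 <- min(all_c) - 1; x2 <- max(all_c)   # 0-based half-open
    y1 <- min(all_r) - 1; y2 <- max(all_r)
    nb <- c(x1, y1, x2, y2)
    hit <- length(placed) > 0 && any(vapply(placed, function(p) {
      nb[1] < p$box[3] && p$box[1] < nb[3] && nb[2] < p$box[4] &&
        p$box[2] < nb[4]
    }, logical(1)))
    if (hit) {
      # mark both members of the intersecting pair
      for (j in seq_along(placed)) {
        p <- placed[[j]]
        if (nb[1] < p$box[3] && p$box[1] < nb[3] && nb[2] < p$box[4] &&
            p$box[2] < nb[4]) overlaps[j] <- TRUE
      }
    }
    overlaps <- c(overlaps, hit)
    placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, a = a, box = nb)
    boxes <- rbind(boxes, xyxy_to_xywh(nb))
  }

  out <- labeled_image(snap8(img), boxes, id = sprintf("scene%06d", spec$seed))
  attr(out, "overlap_fraction") <- if (length(overlaps)) mean(overlaps) else 0
  out
}

#' Write a synthetic labeled dataset to disk
#'
#' Generates `n_images` scenes with per-image seeds derived from the master
#' seed, writes each as `images/<stem>.png` plus both annotation formats
#' (`labels/<stem>.txt` YOLO, `labels/<stem>.xml` VOC), and records a
#' manifest (`manifest.json`) with per-image box counts, mean overlap
#' fraction and file checksums.
#'
#' @param dir output directory.
#' @param n_images number of scenes.
#' @param spec base [scene_spec()]; its seed is replaced per image.
#' @param n_spikes_range optional range from which each scene's spike count
#'   is drawn (defaults to the spec's fixed count).
#' @param seed master seed.
#' @return the manifest list, invisibly.
#' @export
generate_dataset <- function(dir, n_images, spec = scene_spec(),
                             n_spikes_range = NULL, seed = 1L) {
  stopifnot(n_images >= 1)
  dir.create(file.path(dir, "images"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "labels"), showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_len(n_images)) {
    si <- spec
    si$seed <- derive_seed(seed, i)
    if (!is.null(n_spikes_range)) {
      old <- local_seed(derive_seed(seed, 100000 + i))
      si$n_spikes <- as.integer(round(stats::runif(1, n_spikes_range[1],
                                                   n_spikes_range[2])))
      restore_seed(old)
    }
    sc <- generate_scene(si)
    stem <- sprintf("scene_%04d", i)
    sc$id <- stem
    png_path <- file.path(dir, "images", paste0(stem, ".png"))
    png::writePNG(sc$image, png_path)
    write_yolo_txt(sc, file.path(dir, "labels", paste0(stem, ".txt")))
    write_voc_xml(sc, file.path(dir, "labels", paste0(stem, ".xml")))
    entries[[i]] <- list(stem = stem, n_boxes = nrow(sc$boxes),
                         overlap_fraction = attr(sc, "overlap_fraction"),
                         md5 = unname(tools::md5sum(png_path)))
  }
  manifest <- list(
    n_images = n_images, seed = seed,
    background = spec$background,
    mean_boxes = mean(vapply(entries, `[[`, numeric(1), "n_boxes")),
    mean_overlap = mean(vapply(entries, `[[`, numeric(1),
                               "overlap_fraction")),
    images = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
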