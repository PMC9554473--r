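# Letterbox, mosaic, tiling, anchors, annotation I/O.

test_that("letterbox geometry reproduces hand-computed cases", {
  g <- letterbox_geometry(1024, 1024)
  expect_equal(g$scale, 0.625)
  expect_equal(c(g$out_w, g$out_h), c(640L, 640L))
  expect_equal(unname(g$pad), c(0L, 0L, 0L, 0L))

  g2 <- letterbox_geometry(720, 960)              # h x w
  expect_equal(g2$scale, 2 / 3)
  expect_equal(c(g2$new_w, g2$new_h), c(640L, 480L))
  expect_equal(sum(g2$pad), 0L)                   # 480 is a stride multiple

  g3 <- letterbox_geometry(700, 1000)
  expect_equal(g3$scale, 0.64)
  expect_equal(c(g3$new_w, g3$new_h), c(640L, 448L))
  expect_equal(sum(g3$pad), 0L)
})

test_that("letterbox padding is minimal, stride-divisible, and invertible", {
  set.seed(21)
  for (r in 1:500) {
    h <- sample(33:1400, 1); w <- sample(33:1400, 1)
    g <- letterbox_geometry(h, w)
    expect_equal(g$out_w %% 32, 0)
    expect_equal(g$out_h %% 32, 0)
    # minimality: one stride less would not cover the scaled image
    expect_lt(g$out_w - 32, g$new_w)
    expect_lt(g$out_h - 32, g$new_h)
    expect_gte(g$out_w, g$new_w)
    expect_gte(g$out_h, g$new_h)
  }
  # coordinate round trip through an actual letterboxed image
  img <- array(runif(300 * 500 * 3), dim = c(300, 500, 3))
  lb <- letterbox(img)
  pts <- cbind(c(10, 250, 499.5), c(5, 150, 299.5))
  fwd <- cbind(pts[, 1] * lb$scale + lb$pad[["left"]],
               pts[, 2] * lb$scale + lb$pad[["top"]])
  back <- letterbox_invert(fwd, lb)
  expect_equal(back, pts, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(dim(lb$image), c(lb$pad[["top"]] + lb$pad[["bottom"]] +
                                  round(300 * lb$scale), 640, 3))
})

test_that("mosaic is deterministic, bounded, and box-conserving", {
  set.seed(22)
  items <- lapply(1:4, function(i) {
    h <- sample(60:120, 1); w <- sample(60:120, 1)
    nb <- sample(0:4, 1)
    boxes <- if (nb > 0) {
      cbind(runif(nb, 15, w - 15), runif(nb, 15, h - 15),
            runif(nb, 8, 20), runif(nb, 8, 20))
    }
    labeled_image(array(runif(h * w * 3), c(h, w, 3)), boxes,
                  id = paste0("m", i))
  })
  m1 <- mosaic(items, canvas = 192, seed = 99)
  m2 <- mosaic(items, canvas = 192, seed = 99)
  expect_identical(m1, m2)
  expect_identical(dim(m1$image), c(192L, 192L, 3L))
  if (nrow(m1$boxes)) {
    cc <- xywh_to_xyxy(m1$boxes)
    expect_true(all(cc[, 1] >= 0 & cc[, 2] >= 0 &
                      cc[, 3] <= 192 & cc[, 4] <= 192))
  }
  expect_lte(nrow(m1$boxes), sum(vapply(items, function(i) nrow(i$boxes), 0)))

  blank <- lapply(1:4, function(i) tiny_labeled(60, 60, id = paste0("b", i)))
  expect_equal(nrow(mosaic(blank, canvas = 128, seed = 1)$boxes), 0)
  expect_error(mosaic(items[1:3], canvas = 128, seed = 1), "exactly 4")
})

test_that("best possible recall follows the per-dimension ratio rule", {
  wh <- rbind(c(10, 20), c(30, 15), c(60, 60))
  expect_equal(best_possible_recall(wh, wh), 1)
  expect_equal(best_possible_recall(c(10, 10), c(50, 50)), 0)  # ratio 5
  expect_equal(best_possible_recall(c(10, 10), c(20, 20)), 1)  # ratio 2
  expect_error(best_possible_recall(matrix(numeric(0), 0, 2),
                                    default_anchors()), "empty")
  # monotone in the threshold and under anchor-set inclusion
  set.seed(23)
  wh <- cbind(runif(200, 5, 200), runif(200, 5, 200))
  anc <- default_anchors()
  b1 <- best_possible_recall(wh, anc, 2)
  b2 <- best_possible_recall(wh, anc, 4)
  b3 <- best_possible_recall(wh, anc, 8)
  expect_true(b1 <= b2 && b2 <= b3)
  expect_lte(best_possible_recall(wh, anc[1:4, ]),
             best_possible_recall(wh, anc))
})

test_that("anchor fitting recovers planted clusters and never degrades BPR", {
  set.seed(24)
  centers <- cbind(w = c(12, 25, 40, 60, 85, 115, 150, 200, 300),
                   h = c(18, 20, 55, 45, 120, 90, 200, 180, 320))
  wh <- centers[rep(1:9, each = 40), ] * matrix(runif(720, 0.98, 1.02), 360)
  anc <- fit_anchors(wh, 9, seed = 3)
  ord <- order(centers[, 1] * centers[, 2])
  expect_equal(anc, centers[ord, ], tolerance = 0.05, ignore_attr = TRUE)

  same <- matrix(rep(c(50, 30), 20), ncol = 2, byrow = TRUE)
  anc_same <- fit_anchors(same, 9, seed = 1, default = NULL)
  expect_true(all(abs(anc_same[, 1] - 50) < 1e-6 &
                    abs(anc_same[, 2] - 30) < 1e-6))

  for (s in 1:5) {
    whr <- cbind(runif(60, 5, 400), runif(60, 5, 400))
    expect_gte(best_possible_recall(whr, fit_anchors(whr, 9, seed = s)),
               best_possible_recall(whr, default_anchors()))
  }
  expect_error(fit_anchors(same[1:5, ], 9), "at least k")
})

test_that("tiling covers the image and routes boxes to the right tiles", {
  img <- array(runif(720 * 960 * 3), c(720, 960, 3))
  boxes <- rbind(c(100, 100, 40, 30),   # fully inside tile (0,0) only
                 c(800, 600, 50, 50))
  it <- labeled_image(img, boxes, id = "big")
  tiles <- tile_image(it, tile = 640, stride = 320)
  expect_length(tiles, 4)
  offs <- t(vapply(tiles, function(t) {
    c(attr(t, "offset_x"), attr(t, "offset_y"))
  }, numeric(2)))
  expect_equal(sort(unique(offs[, 1])), c(0, 320))
  expect_equal(sort(unique(offs[, 2])), c(0, 80))
  # the small box appears only in tiles fully containing it
  has_b1 <- vapply(tiles, function(t) {
    nrow(t$boxes) > 0 && any(abs(t$boxes[, 3] - 40) < 1e-9)
  }, logical(1))
  expect_equal(sum(has_b1), sum(offs[, 1] <= 80 & offs[, 2] <= 85))

  one <- tile_image(tiny_labeled(640, 640), tile = 640)
  expect_length(one, 1)
  expect_equal(one[[1]]$image, tiny_image(640, 640))
})

test_that("VOC and YOLO annotations round-trip losslessly", {
  boxes <- rbind(c(100.5, 60.5, 41, 25), c(320, 240, 100, 80))
  it <- labeled_image(array(0.5, c(480, 640, 3)), boxes, id = "rt")
  xml <- tempfile(fileext = ".xml")
  txt <- tempfile(fileext = ".txt")
  write_voc_xml(it, xml)
  write_yolo_txt(it, txt)
  rv <- read_voc_xml(xml)
  expect_equal(rv$size, c(h = 480, w = 640))
  expect_equal(rv$boxes, boxes, ignore_attr = TRUE, tolerance = 1e-6)
  ry <- read_yolo_txt(txt, 640, 480)
  expect_equal(ry$boxes, boxes, ignore_attr = TRUE, tolerance = 1e-3)

  # corner conventions: VOC (1,1,640,640) on 640x640 <-> YOLO (0.5,0.5,1,1)
  full <- labeled_image(array(0, c(640, 640, 3)),
                        matrix(c(320, 320, 640, 640), 1), id = "full")
  write_voc_xml(full, xml)
  doc <- xml2::read_xml(xml)
  co <- as.numeric(xml2::xml_text(xml2::xml_find_all(doc, ".//bndbox/*")))
  expect_equal(co, c(1, 1, 640, 640))
  write_yolo_txt(full, txt)
  expect_equal(scan(txt, quiet = TRUE), c(0, 0.5, 0.5, 1, 1))

  writeLines(character(0), txt)
  expect_equal(nrow(read_yolo_txt(txt, 100, 100)$boxes), 0)
  writeLines("0 0.5 0.5", txt)
  expect_error(read_yolo_txt(txt, 100, 100), "line 1")
  writeLines("<annotation><object></object></annotation>", xml)
  expect_error(read_voc_xml(xml), "size")
  unlink(c(xml, txt))
})
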