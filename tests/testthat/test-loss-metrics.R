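# IoU / CIoU localization loss, composite training loss, evaluation metrics.

test_that("IoU matches hand-derived values and is symmetric", {
  a <- c(5, 5, 4, 4)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(50, 50, 4, 4)), 0)
  # corners (0,0,2,2) vs (1,1,3,3): intersection 1, union 7
  expect_equal(iou(c(1, 1, 2, 2), c(2, 2, 2, 2)), 1 / 7)
  set.seed(11)
  A <- random_boxes(50); B <- random_boxes(50)
  expect_equal(iou(A, B), iou(B, A))
  expect_true(all(iou(A, B) >= 0 & iou(A, B) <= 1))
  expect_error(iou(c(0, 0, 0, 1), a), "degenerate")
})

test_that("CIoU loss reproduces closed-form cases", {
  expect_equal(ciou_loss(c(3, 3, 2, 5), c(3, 3, 2, 5)), 0,
               ignore_attr = TRUE)
  # concentric squares 2x2 in 4x4: IoU 0.25, centered, same aspect
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(0, 0, 4, 4)), 0.75,
               ignore_attr = TRUE)
  tm <- ciou_terms(c(0, 0, 1, 1), c(0, 0, 2, 1))
  expect_equal(tm$v, (4 / pi^2) * (atan(2) - atan(1))^2)
  expect_equal(tm$v, 0.041957, tolerance = 1e-4)
})

test_that("CIoU respects its structural bounds on random box pairs", {
  set.seed(12)
  A <- random_boxes(500); B <- random_boxes(500)
  tm <- ciou_terms(A, B)
  expect_true(all(tm$loss >= (1 - tm$iou) - 1e-12))
  expect_true(all(tm$loss >= 0))
  expect_true(all(tm$rho2 <= tm$c2 + 1e-9))
  expect_equal(ciou_loss(A, A), rep(0, 500), ignore_attr = TRUE)
})

test_that("confusion-count accuracy and recall follow their definitions", {
  expect_equal(accuracy(confusion_counts(7, 2, 3, 0)), 7 / 12)
  expect_equal(accuracy(confusion_counts(4, 0, 0, 3)), 1)
  expect_equal(accuracy(confusion_counts(0, 2, 5, 0)), 0)
  expect_equal(recall(confusion_counts(9, 0, 1)), 0.9)
  expect_equal(recall(confusion_counts(5, 3, 0)), 1)
  expect_equal(recall(confusion_counts(0, 0, 4)), 0)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "undefined")
  expect_error(recall(confusion_counts(0, 5, 0)), "undefined")
  # invariance to scaling all counts
  for (k in c(2, 7)) {
    expect_equal(accuracy(confusion_counts(7 * k, 2 * k, 3 * k, k)),
                 accuracy(confusion_counts(7, 2, 3, 1)))
    expect_equal(recall(confusion_counts(9 * k, 0, k)),
                 recall(confusion_counts(9, 0, 1)))
  }
})

test_that("average precision agrees with a brute-force oracle", {
  gts <- data.frame(image = "a", cx = c(10, 40), cy = c(10, 40),
                    w = c(8, 8), h = c(8, 8))
  # perfect: each ground truth matched by one top-ranked detection
  dets <- cbind(gts, score = c(0.9, 0.8))
  expect_equal(average_precision(dets, gts), 1)
  # no detections at all
  none <- dets[0, ]
  expect_equal(average_precision(none, gts), 0)
  # one GT, TP ranked above FP: interpolated AP stays 1
  g1 <- gts[1, ]
  d2 <- rbind(cbind(g1, score = 0.9),
              data.frame(image = "a", cx = 90, cy = 90, w = 8, h = 8,
                         score = 0.5))
  expect_equal(average_precision(d2, g1), 1)
  expect_error(average_precision(dets, gts[0, ]), "zero ground truths")

  set.seed(13)
  for (r in 1:15) {
    n_gt <- sample(2:6, 1)
    gts <- data.frame(image = sample(c("a", "b"), n_gt, replace = TRUE),
                      cx = runif(n_gt, 10, 90), cy = runif(n_gt, 10, 90),
                      w = runif(n_gt, 5, 15), h = runif(n_gt, 5, 15))
    n_d <- sample(1:10, 1)
    base <- gts[sample(n_gt, n_d, replace = TRUE), ]
    dets <- data.frame(image = base$image,
                       cx = base$cx + rnorm(n_d, 0, 4),
                       cy = base$cy + rnorm(n_d, 0, 4),
                       w = base$w, h = base$h, score = runif(n_d))
    expect_equal(average_precision(dets, gts), ap_bruteforce(dets, gts))
  }
})

test_that("counting errors follow their formulas and MAE <= RMSE always", {
  expect_equal(rmse(c(3, 5), c(3, 5)), 0)
  expect_equal(rmse(c(3, 5), c(1, 1)), sqrt(10))
  expect_equal(rmse(5, 2), 3)
  expect_equal(mae(c(3, 5), c(1, 1)), 3)
  expect_equal(mae(c(1, 1), c(3, 5)), 3)  # sign-insensitive
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  set.seed(14)
  for (r in 1:50) {
    n <- sample(1:30, 1)
    q <- rpois(n, 40)
    p <- q + sample(-10:10, n, replace = TRUE)
    expect_lte(mae(p, q), rmse(p, q) + 1e-12)
  }
})

test_that("relative count error and accuracy are percentages", {
  r <- mean_error_accuracy(c(10, 20), c(10, 20))
  expect_equal(r$mean_error, 0)
  expect_equal(r$mean_accuracy, 100)
  r2 <- mean_error_accuracy(8, 10)
  expect_equal(r2$mean_error, 20)
  expect_equal(r2$mean_accuracy, 80)
  r3 <- mean_error_accuracy(c(15, 9), c(10, 10))
  expect_equal(r3$mean_error, 30)
  expect_equal(r3$mean_accuracy, 70)
  expect_error(mean_error_accuracy(c(1, 2), c(1, 0)), "undefined")
  # the accuracy floor at 0
  expect_equal(mean_error_accuracy(30, 10)$mean_accuracy, 0)
})

make_raw <- function(grids = c(8, 4, 2), nc = 1L, fill = -20) {
  raw <- lapply(grids, function(g) array(fill, dim = c(g, g, 3 * (5 + nc), 1)))
  attr(raw, "strides") <- c(8L, 16L, 32L)
  attr(raw, "anchors") <- default_anchors()
  attr(raw, "nc") <- nc
  raw
}

test_that("detection loss handles empty targets and a perfect encoding", {
  raw0 <- make_raw(fill = -30)  # objectness logits far negative
  ls0 <- detection_loss(raw0, list(NULL))
  expect_equal(ls0$box, 0)
  expect_equal(ls0$cls, 0)
  expect_lt(ls0$obj, 1e-10)
  expect_equal(ls0$n_matched, 0)

  # encode one target exactly at its matched cell with saturated confidence
  tgt <- c(27.2, 10.4, 23.04, 10.8)  # decodes exactly from the logits below
  raw <- make_raw(fill = -30)
  lg <- function(p) log(p / (1 - p))
  for (a in 1:3) {
    anc <- default_anchors()[a, ]
    tw <- lg(sqrt(tgt[3] / anc[["w"]]) / 2)
    th <- lg(sqrt(tgt[4] / anc[["h"]]) / 2)
    if (!is.finite(tw) || !is.finite(th)) next
    base <- (a - 1) * 6
    raw[[1]][2, 4, base + 1, 1] <- lg((27.2 / 8 - 3 + 0.5) / 2)
    raw[[1]][2, 4, base + 2, 1] <- lg((10.4 / 8 - 1 + 0.5) / 2)
    raw[[1]][2, 4, base + 3, 1] <- tw
    raw[[1]][2, 4, base + 4, 1] <- th
    raw[[1]][2, 4, base + 5, 1] <- 30
    raw[[1]][2, 4, base + 6, 1] <- 30
  }
  ls <- detection_loss(raw, list(matrix(tgt, 1)))
  expect_gt(ls$n_matched, 0)
  expect_lt(ls$box, 1e-8)
  expect_lt(ls$cls, 1e-8)
  expect_lt(ls$total, 0.05)  # residual: matched-cell objectness BCE only
})

test_that("detection loss equals a hand-summed oracle for one match", {
  nc <- 1L
  raw <- make_raw(fill = -20)
  set.seed(15)
  tgt <- matrix(c(20, 12, 30, 61), 1)  # matches anchor 4 exactly by size
  vals <- rnorm(6, 0, 0.5)
  raw[[2]][1, 2, 6 + 1:6, 1] <- vals   # scale 2 cell gi=1, gj=0, anchor 2
  ls <- detection_loss(raw, list(tgt))
  # oracle: which entries matched
  ns <- asNamespace("spikedet")
  tt <- ns$build_targets(list(tgt), default_anchors(), c(8, 16, 32),
                         rbind(c(8, 8), c(4, 4), c(2, 2)))
  expect_true(all(tt$gx == 20))
  sig <- function(z) 1 / (1 + exp(-z))
  box_terms <- numeric(0)
  cls_terms <- numeric(0)
  for (i in seq_len(nrow(tt))) {
    e <- tt[i, ]
    st <- c(8, 16, 32)[e$scale]
    anc <- default_anchors()[(e$scale - 1) * 3 + e$anchor, ]
    v <- raw[[e$scale]][e$gj + 1, e$gi + 1, (e$anchor - 1) * 6 + 1:6, 1]
    pb <- c((2 * sig(v[1]) - 0.5 + e$gi) * st,
            (2 * sig(v[2]) - 0.5 + e$gj) * st,
            (2 * sig(v[3]))^2 * anc[["w"]],
            (2 * sig(v[4]))^2 * anc[["h"]])
    box_terms <- c(box_terms, as.numeric(ciou_loss(pb, c(e$gx, e$gy, e$gw, e$gh))))
    cls_terms <- c(cls_terms, -log(sig(v[6])))
  }
  expect_equal(ls$box, mean(box_terms), tolerance = 1e-8)
  expect_equal(ls$cls, mean(cls_terms), tolerance = 1e-8)
  expect_equal(ls$total, 0.05 * ls$box + 1.0 * ls$obj + 0.5 * ls$cls)
})

test_that("count report writes per-image CSV and summary JSON", {
  rep <- count_report(c("a", "b"), c(9, 11), c(10, 10))
  dir <- tempfile()
  write_count_report(rep, dir)
  csv <- read.csv(file.path(dir, "counts.csv"))
  expect_equal(csv$p, c(9, 11))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$mae, 1)
  expect_equal(js$mean_error, 10)
  unlink(dir, recursive = TRUE)
})
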