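# Network assembly, parameter accounting, forward pass, decode + NMS.

table1 <- c(3520, 18560, 18819, 73984, 115715, 295424, 625155, 1180672,
            656896, 1182723, 131584, 0, 0, 361984, 33024, 0, 0, 90880,
            147712, 0, 296448, 590336, 0, 1182720, 8622262)

test_that("per-layer parameter counts match the published table row by row", {
  model <- spike_yolo()
  tab <- layer_param_counts(model)
  expect_equal(tab$params, table1)
  expect_equal(sum(tab$params), 15628418)
  expect_equal(tab$module[c(1, 3, 9, 25)], c("Focus", "ECA-C3", "SPP", "Detect"))
  expect_equal(tab$from[c(13, 25)], c("-1,6", "17,20,23"))
  # parameter-free layers
  expect_equal(tab$params[tab$module %in% c("Upsample", "Concat")],
               rep(0, 6))
})

test_that("every ECA-C3 stage costs exactly 3 parameters over plain C3", {
  stages <- list(c(64, 1), c(128, 2), c(256, 3), c(512, 1))
  for (s in stages) {
    plain <- module_param_count(c3_block(s[1], s[1], s[2], TRUE))
    gated <- module_param_count(eca_c3_block(s[1], s[1], s[2], TRUE))
    expect_equal(gated - plain, 3)
  }
})

test_that("removing the GAMs reduces the detection stage to its 1x1 convs", {
  cfg <- spike_yolo_config(use_gam = FALSE)
  tab <- layer_param_counts(spike_yolo(cfg))
  expect_equal(tab$params[25], (128 + 256 + 512) * 18 + 54)
  expect_equal(tab$params[25], 16182)
})

test_that("forward emits three scales at strides 8/16/32 and is deterministic", {
  model <- spike_yolo(seed = 2)
  x <- array(runif(96 * 128 * 3 * 2), dim = c(96, 128, 3, 2))
  raw <- forward_detector(model, x)
  expect_length(raw, 3)
  expect_identical(dim(raw[[1]]), c(12L, 16L, 18L, 2L))
  expect_identical(dim(raw[[2]]), c(6L, 8L, 18L, 2L))
  expect_identical(dim(raw[[3]]), c(3L, 4L, 18L, 2L))
  expect_true(all(vapply(raw, function(a) all(is.finite(a)), logical(1))))
  raw2 <- forward_detector(model, x)
  expect_identical(raw, raw2)
  expect_error(forward_detector(model, array(0, c(90, 96, 3, 1))),
               "divisible")
})

test_that("decoded boxes match the closed-form mapping at a planted cell", {
  nc <- 1L
  raw <- lapply(c(8, 4, 2), function(g) array(-20, dim = c(g, g, 18, 1)))
  attr(raw, "strides") <- c(8L, 16L, 32L)
  attr(raw, "anchors") <- default_anchors()
  attr(raw, "nc") <- nc
  # plant one confident detection: scale 1 (stride 8), anchor 2, gi=3, gj=1
  lg <- function(p) log(p / (1 - p))
  base <- (2 - 1) * 6
  raw[[1]][2, 4, base + 1, 1] <- lg(0.7)   # tx
  raw[[1]][2, 4, base + 2, 1] <- lg(0.4)   # ty
  raw[[1]][2, 4, base + 3, 1] <- lg(0.6)   # tw
  raw[[1]][2, 4, base + 4, 1] <- lg(0.3)   # th
  raw[[1]][2, 4, base + 5, 1] <- 8         # objectness
  raw[[1]][2, 4, base + 6, 1] <- 8         # class
  out <- decode_and_nms(raw, conf_thresh = 0.25, iou_thresh = 0.45)
  expect_equal(nrow(out[[1]]), 1)
  anc <- default_anchors()[2, ]
  expect_equal(out[[1]]$cx, (2 * 0.7 - 0.5 + 3) * 8)
  expect_equal(out[[1]]$cy, (2 * 0.4 - 0.5 + 1) * 8)
  expect_equal(out[[1]]$w, (2 * 0.6)^2 * anc[["w"]])
  expect_equal(out[[1]]$h, (2 * 0.3)^2 * anc[["h"]])

  # an impossible confidence threshold empties the output
  expect_equal(nrow(decode_and_nms(raw, 1.0, 0.45)[[1]]), 0)
})

test_that("NMS keeps the top-scoring of duplicates and separated survivors", {
  b <- rbind(c(10, 10, 8, 8), c(10, 10, 8, 8), c(40, 40, 8, 8))
  keep <- nms(b, c(0.9, 0.8, 0.7), 0.5)
  expect_identical(keep, c(1L, 3L))
  # survivors are a subset with pairwise IoU below the threshold
  set.seed(5)
  for (r in 1:20) {
    boxes <- random_boxes(15)
    sc <- runif(15)
    k <- nms(boxes, sc, 0.5)
    expect_true(all(k %in% 1:15))
    if (length(k) > 1) {
      pair <- utils::combn(k, 2)
      ious <- iou(boxes[pair[1, ], , drop = FALSE],
                  boxes[pair[2, ], , drop = FALSE])
      expect_true(all(ious < 0.5))
    }
  }
})

test_that("checkpoints round-trip to identical predictions", {
  model <- spike_yolo(seed = 7)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  p1 <- predict(model, x, conf_thresh = 0.001)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  m2 <- load_checkpoint(path)
  expect_identical(predict(m2, x, conf_thresh = 0.001), p1)
  unlink(path)
})

test_that("layer backward passes agree with finite differences", {
  set.seed(31)
  ns <- asNamespace("spikedet")
  cases <- list(
    list(ns$conv_block(3, 4, 3, 2), c(8, 8, 3, 2)),
    list(ns$nn_batchnorm(4), c(5, 5, 4, 2)),
    list(ns$nn_focus(6), c(8, 8, 3, 1)),
    list(ns$c3_block(8, 8, 2, TRUE), c(6, 6, 8, 2)),
    list(ns$eca_c3_block(8, 8, 1, TRUE), c(6, 6, 8, 1)),
    list(ns$spp_block(8, 8), c(8, 8, 8, 1)),
    list(gam(8, 4), c(6, 6, 8, 2))
  )
  h <- 1e-6
  for (case in cases) {
    m <- case[[1]]
    x <- array(rnorm(prod(case[[2]])), case[[2]])
    fwd <- function() m$forward(x, train = TRUE)
    y <- fwd()
    dy <- array(rnorm(length(y)), dim(y))
    ns$zero_grads(m)
    y <- fwd()
    m$backward(dy)
    for (leaf in ns$collect_modules(m)) {
      p <- leaf$param_names[1]
      i <- sample(length(leaf[[p]]), 1)
      po <- leaf[[p]][i]
      leaf[[p]][i] <- po + h; lu <- sum(fwd() * dy)
      leaf[[p]][i] <- po - h; ld <- sum(fwd() * dy)
      leaf[[p]][i] <- po
      num <- (lu - ld) / (2 * h)
      ana <- leaf[[paste0("d", p)]][i]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})
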