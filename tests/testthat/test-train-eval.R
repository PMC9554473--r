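# Training loop contracts and the counting/evaluation pipeline.

tiny_scenes <- function(n = 2, seed0 = 300) {
  lapply(seq_len(n), function(i) generate_scene(
    scene_spec(canvas = c(96, 96), n_spikes = 3, length_range = c(18, 28),
               width_range = c(6, 9), overlap_target = 0.2,
               seed = seed0 + i)))
}

test_that("a zero learning rate leaves every parameter unchanged", {
  scenes <- tiny_scenes(2)
  fit <- train_spike_yolo(scenes, epochs = 1, batch_size = 2, imgsz = 96,
                          lr0 = 0, augment = FALSE, seed = 11,
                          verbose = FALSE)
  ref <- spike_yolo(fit$model$cfg, seed = spikedet:::derive_seed(11, 1))
  l1 <- spikedet:::collect_modules_model(fit$model)
  l2 <- spikedet:::collect_modules_model(ref)
  for (i in seq_along(l1)) {
    for (p in l1[[i]]$param_names) {
      expect_identical(l1[[i]][[p]], l2[[i]][[p]])
    }
  }
})

test_that("training is deterministic for a fixed seed", {
  scenes <- tiny_scenes(2)
  f1 <- train_spike_yolo(scenes, epochs = 1, batch_size = 2, imgsz = 96,
                         augment = FALSE, seed = 13, verbose = FALSE)
  f2 <- train_spike_yolo(scenes, epochs = 1, batch_size = 2, imgsz = 96,
                         augment = FALSE, seed = 13, verbose = FALSE)
  expect_identical(f1$log$total[1], f2$log$total[1])
})

test_that("the anchor gate keeps anchors at BPR >= 0.98 and refits below it", {
  scenes <- tiny_scenes(2)
  # well-matched boxes: the default priors cover these sizes
  expect_message(
    train_spike_yolo(scenes, epochs = 1, batch_size = 2, imgsz = 96,
                     augment = FALSE, seed = 1),
    "anchors kept")
  # extreme aspect ratios defeat every default prior
  thin <- lapply(1:2, function(i) {
    labeled_image(tiny_image(96, 96),
                  cbind(runif(9, 30, 60), runif(9, 30, 60), 60, 1.2),
                  id = paste0("thin", i))
  })
  expect_message(
    fit <- train_spike_yolo(thin, epochs = 1, batch_size = 2, imgsz = 96,
                            augment = FALSE, seed = 1),
    "refitting anchors")
  expect_false(identical(fit$anchors, default_anchors()))
})

test_that("a ground-truth-echo detector scores perfectly end to end", {
  scenes <- tiny_scenes(3)
  dets <- lapply(scenes, function(s) {
    data.frame(cx = s$boxes[, 1], cy = s$boxes[, 2], w = s$boxes[, 3],
               h = s$boxes[, 4], score = 1)
  })
  names(dets) <- vapply(scenes, `[[`, character(1), "id")
  rep <- evaluate_detections(dets, scenes)
  expect_equal(rep$summary$rmse, 0)
  expect_equal(rep$summary$mae, 0)
  expect_equal(rep$summary$mean_accuracy, 100)
  expect_equal(rep$summary$recall, 1)
  expect_equal(rep$summary$map50, 1)
  expect_equal(rep$summary$map50_95, 1)
})

test_that("an off-by-one counting stub yields MAE 1 and 10% error", {
  scenes <- lapply(1:4, function(i) generate_scene(
    scene_spec(canvas = c(128, 128), n_spikes = 10, length_range = c(14, 20),
               width_range = c(5, 7), overlap_target = 0.2, seed = 400 + i)))
  dets <- lapply(scenes, function(s) {
    b <- rbind(s$boxes, c(20, 20, 10, 6))   # one spurious extra detection
    data.frame(cx = b[, 1], cy = b[, 2], w = b[, 3], h = b[, 4], score = 1)
  })
  names(dets) <- vapply(scenes, `[[`, character(1), "id")
  rep <- evaluate_detections(dets, scenes)
  expect_equal(rep$summary$mae, 1)
  expect_equal(rep$summary$rmse, 1)
  expect_equal(rep$summary$mean_error, 10)
  expect_equal(rep$summary$mean_accuracy, 90)
})

test_that("metrics are invariant to image ordering and ids must match", {
  scenes <- tiny_scenes(3)
  dets <- lapply(scenes, function(s) {
    data.frame(cx = s$boxes[, 1], cy = s$boxes[, 2], w = s$boxes[, 3],
               h = s$boxes[, 4], score = runif(nrow(s$boxes)))
  })
  names(dets) <- vapply(scenes, `[[`, character(1), "id")
  r1 <- evaluate_detections(dets, scenes)
  r2 <- evaluate_detections(dets[c(3, 1, 2)], scenes)
  expect_equal(r1$summary, r2$summary)
  bad <- dets
  names(bad)[1] <- "missing-image"
  expect_error(evaluate_detections(bad, scenes), "missing-image")
})

test_that("an impossible confidence threshold counts zero everywhere", {
  scenes <- tiny_scenes(2)
  model <- spike_yolo(seed = 5)
  rep <- count_spikes(model, scenes, conf_thresh = 1.0, imgsz = 96)
  expect_equal(rep$per_image$p, c(0, 0))
})

test_that("checkpoints reproduce identical evaluation metrics", {
  scenes <- tiny_scenes(2)
  model <- spike_yolo(seed = 8)
  r1 <- count_spikes(model, scenes, conf_thresh = 0.05, imgsz = 96)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  r2 <- count_spikes(path, scenes, conf_thresh = 0.05, imgsz = 96)
  expect_equal(r1, r2)
  unlink(path)
})
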