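# Training and counting/evaluation pipeline.

prep_item <- function(item, imgsz) {
  lb <- letterbox(item$image, imgsz)
  boxes <- item$boxes
  if (!is.null(boxes) && nrow(boxes)) {
    boxes <- scale_boxes(boxes, lb$scale, lb$scale)
    boxes[, 1] <- boxes[, 1] + lb$pad[["left"]]
    boxes[, 2] <- boxes[, 2] + lb$pad[["top"]]
  }
  list(image = lb$image, boxes = boxes, lb = lb, id = item$id)
}

sgd_state <- function(model) {
  leaves <- collect_modules_model(model)
  lapply(leaves, function(leaf) {
    v <- lapply(leaf$param_names, function(p) leaf[[p]] * 0)
    names(v) <- leaf$param_names
    v
  })
}

sgd_step <- function(model, state, lr, momentum, weight_decay) {
  leaves <- collect_modules_model(model)
  for (i in seq_along(leaves)) {
    leaf <- leaves[[i]]
    for (p in leaf$param_names) {
      g <- leaf[[paste0("d", p)]]
      if (startsWith(p, "W")) g <- g + weight_decay * leaf[[p]]
      state[[i]][[p]] <- momentum * state[[i]][[p]] - lr * g
      leaf[[p]] <- leaf[[p]] + state[[i]][[p]]
    }
  }
  state
}

#' Train the spike detector
#'
#' Stochastic gradient descent with momentum 0.937, weight decay 0.0005 and
#' initial learning rate 0.01 (the published optimizer settings), a 3-epoch
#' linear warmup and cosine decay to `lrf * lr0`.  Before training, the
#' anchor set is checked against the labels with the best-possible-recall
#' rule: anchors are kept when BPR >= 0.98 and refitted by k-means otherwise.
#'
#' @param data list of [labeled_image()] objects, or a dataset directory for
#'   [read_dataset()].
#' @param cfg a [spike_yolo_config()].
#' @param epochs training epochs (default 60).
#' @param batch_size images per batch (default 8).
#' @param imgsz square input size, multiple of 32 (default 640).
#' @param lr0 initial learning rate.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param lrf final learning-rate fraction of `lr0`.
#' @param warmup_epochs linear warmup length.
#' @param augment apply mosaic augmentation (probability 1) during training;
#'   disable to overfit a small set.
#' @param seed master seed; training is deterministic given the seed.
#' @param checkpoint_dir if given, `last.rds` is rewritten every epoch and
#'   `best.rds` tracks the lowest-loss epoch.
#' @param verbose print per-epoch loss lines.
#' @return object of class `spikedet_fit`: list with `$model`, `$log`
#'   (per-epoch data frame of loss components), `$anchors`, `$imgsz`.
#' @export
train_spike_yolo <- function(data, cfg = spike_yolo_config(), epochs = 60L,
                             batch_size = 8L, imgsz = 640L, lr0 = 0.01,
                             momentum = 0.937, weight_decay = 5e-4,
                             lrf = 0.01, warmup_epochs = 3L, augment = TRUE,
                             seed = 1L, checkpoint_dir = NULL,
                             verbose = TRUE) {
  if (is.character(data)) data <- read_dataset(data)
  if (!length(data)) stop("empty dataset")
  stopifnot(epochs >= 1, batch_size >= 1, imgsz %% 32 == 0, lr0 >= 0)
  items <- lapply(data, prep_item, imgsz = imgsz)

  wh <- do.call(rbind, lapply(items, function(it) {
    if (!is.null(it$boxes) && nrow(it$boxes)) it$boxes[, 3:4, drop = FALSE]
  }))
  if (is.null(wh) || !nrow(wh)) stop("dataset has no boxes")
  bpr <- best_possible_recall(wh, cfg$anchors)
  if (bpr >= 0.98) {
    if (verbose) {
      message(sprintf("anchors kept: best possible recall %.4f >= 0.98", bpr))
    }
  } else {
    if (verbose) {
      message(sprintf(
        "best possible recall %.4f < 0.98: refitting anchors by k-means", bpr))
    }
    cfg$anchors <- fit_anchors(wh, 9L, seed = derive_seed(seed, 5),
                               default = cfg$anchors)
  }

  model <- spike_yolo(cfg, seed = derive_seed(seed, 1))
  state <- sgd_state(model)
  n <- length(items)
  steps_per_epoch <- ceiling(n / batch_size)
  warmup_steps <- warmup_epochs * steps_per_epoch
  log <- data.frame(epoch = integer(0), box = numeric(0), obj = numeric(0),
                    cls = numeric(0), total = numeric(0), lr = numeric(0))
  best <- Inf
  step <- 0L
  for (ep in seq_len(epochs)) {
    old <- local_seed(derive_seed(seed, 1000 + ep))
    ord <- sample.int(n)
    ep_loss <- c(box = 0, obj = 0, cls = 0, total = 0)
    lr_ep <- lr0 * (lrf + 0.5 * (1 - lrf) * (1 + cos(pi * (ep - 1) / epochs)))
    for (bi in seq_len(steps_per_epoch)) {
      step <- step + 1L
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      xs <- vector("list", length(idx))
      tg <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        if (augment && n >= 4L) {
          picks <- c(idx[j], sample.int(n, 3L, replace = TRUE))
          mz <- mosaic(data[picks], canvas = imgsz,
                       seed = derive_seed(seed, 7000L * ep + 13L * step + j))
          xs[[j]] <- mz$image
          tg[[j]] <- mz$boxes
        } else {
          xs[[j]] <- items[[idx[j]]]$image
          tg[[j]] <- items[[idx[j]]]$boxes
        }
      }
      x <- array(unlist(xs), dim = c(dim(xs[[1]]), length(xs)))
      zero_grads_model(model)
      raw <- forward_detector(model, x, train = TRUE)
      ls <- detection_loss(raw, tg, with_grad = TRUE)
      backward_detector(model, ls$grads)
      lr <- if (step <= warmup_steps) lr_ep * step / max(warmup_steps, 1)
      else lr_ep
      state <- sgd_step(model, state, lr, momentum, weight_decay)
      ep_loss <- ep_loss +
        c(ls$box, ls$obj, ls$cls, ls$total) / steps_per_epoch
    }
    restore_seed(old)
    log <- rbind(log, data.frame(epoch = ep, box = ep_loss[1],
                                 obj = ep_loss[2], cls = ep_loss[3],
                                 total = ep_loss[4], lr = lr_ep))
    if (verbose) {
      message(sprintf(
        "epoch %3d/%d  box %.4f  obj %.4f  cls %.4f  total %.4f",
        ep, epochs, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, file.path(checkpoint_dir, "last.rds"))
      if (ep_loss[4] < best) {
        best <- ep_loss[4]
        save_checkpoint(model, file.path(checkpoint_dir, "best.rds"))
      }
    }
  }
  rownames(log) <- NULL
  structure(list(model = model, log = log, anchors = cfg$anchors,
                 imgsz = imgsz), class = "spikedet_fit")
}

zero_grads_model <- function(model) {
  for (l in model$layers) zero_grads(l$module)
  invisible(model)
}

#' @export
print.spikedet_fit <- function(x, ...) {
  cat(sprintf("<spikedet_fit: %d epochs, final total loss %.4f>\n",
              nrow(x$log), x$log$total[nrow(x$log)]))
  invisible(x)
}

# run the detector on labeled images, mapping detections back to original
# pixel coordinates
detect_images <- function(model, items, imgsz = 640L, conf_thresh = 0.25,
                          iou_thresh = 0.45) {
  lapply(items, function(it) {
    pi <- prep_item(it, imgsz)
    dets <- predict(model, pi$image, conf_thresh, iou_thresh)[[1]]
    if (nrow(dets)) {
      ctr <- letterbox_invert(cbind(dets$cx, dets$cy), pi$lb)
      dets$cx <- clamp(ctr[, 1], 0, pi$lb$orig[["w"]])
      dets$cy <- clamp(ctr[, 2], 0, pi$lb$orig[["h"]])
      dets$w <- dets$w / pi$lb$scale
      dets$h <- dets$h / pi$lb$scale
    }
    dets
  })
}

#' Detect and count spikes on a set of images
#'
#' Runs the detector on every image, takes the per-image number of
#' post-suppression detections as the predicted count, and (when ground
#' truth is present) assembles the full counting report.
#'
#' @param model a `spike_yolo` model or a [train_spike_yolo()] fit or a
#'   checkpoint path.
#' @param images list of [labeled_image()] objects or a dataset directory.
#' @param conf_thresh,iou_thresh detection thresholds (defaults 0.25 / 0.45).
#' @param imgsz network input size.
#' @return a [count_report()]; without ground truth, the summary is limited
#'   to the counts themselves.
#' @export
count_spikes <- function(model, images, conf_thresh = 0.25,
                         iou_thresh = 0.45, imgsz = 640L) {
  if (inherits(model, "spikedet_fit")) {
    imgsz <- model$imgsz
    model <- model$model
  }
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(images)) images <- read_dataset(images)
  dets <- detect_images(model, images, imgsz, conf_thresh, iou_thresh)
  names(dets) <- vapply(images, `[[`, character(1), "id")
  evaluate_detections(dets, images)
}

#' Evaluate detections against ground truth
#'
#' Shared endpoint of the counting/evaluation pipeline: takes per-image
#' detections (from the detector or from any external source) and emits the
#' counting and detection metrics in one report.
#'
#' @param dets named list of per-image detection data frames
#'   (`cx, cy, w, h, score`).
#' @param gts named list of [labeled_image()] objects or ground-truth box
#'   matrices; names must match `dets` (an error lists unmatched ids).
#' @return a [count_report()].
#' @export
evaluate_detections <- function(dets, gts) {
  ids_d <- names(dets)
  if (is.null(ids_d)) ids_d <- as.character(seq_along(dets))
  ids_g <- names(gts)
  if (is.null(ids_g)) {
    ids_g <- vapply(seq_along(gts), function(i) {
      it <- gts[[i]]
      if (inherits(it, "labeled_image")) it$id else as.character(i)
    }, character(1))
  }
  if (!setequal(ids_d, ids_g)) {
    bad <- c(setdiff(ids_d, ids_g), setdiff(ids_g, ids_d))
    stop("detection/ground-truth id mismatch: ", paste(bad, collapse = ", "))
  }
  gts <- gts[match(ids_d, ids_g)]
  gt_boxes <- lapply(gts, function(g) {
    if (inherits(g, "labeled_image")) g$boxes else as_box_matrix(g)
  })
  p <- vapply(dets, nrow, numeric(1))
  q <- vapply(gt_boxes, nrow, numeric(1))
  det_df <- do.call(rbind, lapply(seq_along(dets), function(i) {
    d <- dets[[i]]
    if (!nrow(d)) return(NULL)
    data.frame(image = ids_d[i], score = d$score, cx = d$cx, cy = d$cy,
               w = d$w, h = d$h, stringsAsFactors = FALSE)
  }))
  if (is.null(det_df)) {
    det_df <- data.frame(image = character(0), score = numeric(0),
                         cx = numeric(0), cy = numeric(0),
                         w = numeric(0), h = numeric(0))
  }
  gt_df <- do.call(rbind, lapply(seq_along(gt_boxes), function(i) {
    b <- gt_boxes[[i]]
    if (!nrow(b)) return(NULL)
    data.frame(image = ids_d[i], cx = b[, 1], cy = b[, 2], w = b[, 3],
               h = b[, 4], stringsAsFactors = FALSE)
  }))
  count_report(ids_d, p, q, dets = det_df, gts = gt_df)
}
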