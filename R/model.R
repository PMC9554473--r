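# Assembly of the improved single-stage detector: Focus stem,
# Conv / ECA-C3 / SPP backbone, FPN+PAN neck, GAM-augmented three-scale head.

#' Default anchor priors
#'
#' Nine (width, height) pixel pairs grouped three per detection scale
#' (strides 8, 16, 32), ascending in area.  Override per dataset with
#' [fit_anchors()] when [best_possible_recall()] falls below the 0.98 gate.
#'
#' @return a 9 x 2 numeric matrix with columns `w`, `h`.
#' @export
default_anchors <- function() {
  matrix(c(10, 13, 16, 30, 33, 23,
           30, 61, 62, 45, 59, 119,
           116, 90, 156, 198, 373, 326),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("w", "h")))
}

#' Detector configuration
#'
#' Declarative description of the 25-layer improved detector: a single
#' "spike" class, channel widths doubling across the backbone stages
#' (32..512), backbone C3 repeat counts (1, 2, 3, 1), neck C3 blocks with one
#' bottleneck and no shortcut, three detection scales with strides 8/16/32
#' and three anchors each.
#'
#' @param nc number of object classes (default 1, class `"spike"`).
#' @param widths backbone channel widths.
#' @param backbone_repeats C3 repeat counts of the four backbone stages.
#' @param anchors 9 x 2 anchor matrix (see [default_anchors()]).
#' @param strides detection-scale strides.
#' @param use_eca replace backbone C3 blocks by ECA-C3 blocks.
#' @param eca_mode ECA kernel mode, `"fixed3"` or `"adaptive"`.
#' @param use_gam insert a GAM before each prediction convolution.
#' @param gam_reduction GAM bottleneck reduction rate.
#' @return a list of class `spike_yolo_config`.
#' @export
spike_yolo_config <- function(nc = 1L,
                              widths = c(32L, 64L, 128L, 256L, 512L),
                              backbone_repeats = c(1L, 2L, 3L, 1L),
                              anchors = default_anchors(),
                              strides = c(8L, 16L, 32L),
                              use_eca = TRUE,
                              eca_mode = c("fixed3", "adaptive"),
                              use_gam = TRUE,
                              gam_reduction = 4L) {
  eca_mode <- match.arg(eca_mode)
  stopifnot(nc >= 1, length(widths) == 5, all(widths > 0),
            length(backbone_repeats) == 4,
            is.matrix(anchors), nrow(anchors) == 9, ncol(anchors) == 2,
            all(anchors > 0), length(strides) == 3)
  if (!all(widths[-1] == 2L * widths[-5])) {
    stop("backbone widths must double at each stage")
  }
  structure(list(nc = as.integer(nc), widths = as.integer(widths),
                 backbone_repeats = as.integer(backbone_repeats),
                 anchors = anchors, strides = as.integer(strides),
                 use_eca = use_eca, eca_mode = eca_mode,
                 use_gam = use_gam, gam_reduction = as.integer(gam_reduction)),
            class = "spike_yolo_config")
}

#' Build the improved detector
#'
#' Instantiates the 25-layer network: layers 2/4/6/9 are ECA-C3 blocks,
#' layer 8 is SPP with pools 5/9/13, layers 10-23 form the FPN+PAN neck
#' (neck C3 blocks without shortcut), and layer 24 is the detection stage
#' with one GAM per scale ahead of each 1x1 prediction convolution.
#'
#' @param cfg a [spike_yolo_config()].
#' @param seed optional integer; when given, weight initialization is
#'   reproducible.
#' @return an object of class `spike_yolo`: a list with `$layers` (each with
#'   `$index`, `$from`, `$name`, `$module`) and `$cfg`.
#' @examples
#' \donttest{
#' model <- spike_yolo()
#' layer_param_counts(model)
#' }
#' @export
spike_yolo <- function(cfg = spike_yolo_config(), seed = NULL) {
  if (!inherits(cfg, "spike_yolo_config")) stop("cfg must be a spike_yolo_config")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  w <- cfg$widths
  rep_bb <- cfg$backbone_repeats
  bb_c3 <- function(cin, cout, n) {
    if (cfg$use_eca) eca_c3_block(cin, cout, n, TRUE, cfg$eca_mode)
    else c3_block(cin, cout, n, TRUE)
  }
  c3name <- if (cfg$use_eca) "ECA-C3" else "C3"
  L <- list()
  add <- function(from, name, module) {
    L[[length(L) + 1L]] <<- list(index = length(L), from = as.integer(from),
                                 name = name, module = module)
  }
  add(-1, "Focus", nn_focus(w[1]))
  add(-1, "Conv", conv_block(w[1], w[2], 3L, 2L))
  add(-1, c3name, bb_c3(w[2], w[2], rep_bb[1]))
  add(-1, "Conv", conv_block(w[2], w[3], 3L, 2L))
  add(-1, c3name, bb_c3(w[3], w[3], rep_bb[2]))
  add(-1, "Conv", conv_block(w[3], w[4], 3L, 2L))
  add(-1, c3name, bb_c3(w[4], w[4], rep_bb[3]))
  add(-1, "Conv", conv_block(w[4], w[5], 3L, 2L))
  add(-1, "SPP", spp_block(w[5], w[5]))
  add(-1, c3name, bb_c3(w[5], w[5], rep_bb[4]))
  add(-1, "Conv", conv_block(w[5], w[4], 1L))
  add(-1, "Upsample", nn_upsample2())
  add(c(-1, 6), "Concat", nn_concat())
  add(-1, "C3", c3_block(2L * w[4], w[4], 1L, FALSE))
  add(-1, "Conv", conv_block(w[4], w[3], 1L))
  add(-1, "Upsample", nn_upsample2())
  add(c(-1, 4), "Concat", nn_concat())
  add(-1, "C3", c3_block(2L * w[3], w[3], 1L, FALSE))
  add(-1, "Conv", conv_block(w[3], w[3], 3L, 2L))
  add(c(-1, 14), "Concat", nn_concat())
  add(-1, "C3", c3_block(2L * w[3], w[4], 1L, FALSE))
  add(-1, "Conv", conv_block(w[4], w[4], 3L, 2L))
  add(c(-1, 10), "Concat", nn_concat())
  add(-1, "C3", c3_block(2L * w[4], w[5], 1L, FALSE))
  add(c(17, 20, 23), "Detect",
      nn_detect(c(w[3], w[4], w[5]), cfg$nc, cfg$strides,
                cfg$use_gam, cfg$gam_reduction))
  structure(list(layers = L, cfg = cfg), class = "spike_yolo")
}

#' @export
print.spike_yolo <- function(x, ...) {
  tab <- layer_param_counts(x)
  cat(sprintf("<spike_yolo: %d layers, %s trainable parameters>\n",
              nrow(tab), format(sum(tab$params), big.mark = ",")))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-layer trainable-parameter table
#'
#' @param model a [spike_yolo()] model.
#' @return a data frame with columns `index` (0-based), `from`, `params`,
#'   `module`; parameter-free layers (Upsample, Concat) report 0.
#' @export
layer_param_counts <- function(model) {
  stopifnot(inherits(model, "spike_yolo"))
  data.frame(
    index = vapply(model$layers, function(l) l$index, numeric(1)),
    from = vapply(model$layers, function(l) {
      paste(l$from, collapse = ",")
    }, character(1)),
    params = vapply(model$layers, function(l) {
      module_param_count(l$module)
    }, numeric(1)),
    module = vapply(model$layers, function(l) l$name, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Forward pass of the detector
#'
#' @param model a [spike_yolo()] model.
#' @param x input images as an H x W x 3 x N array (values in `[0, 1]`),
#'   H and W divisible by 32.
#' @param train keep activation caches for a subsequent backward pass and
#'   use batch statistics in the normalization layers.
#' @return list of three raw head tensors `Hs x Ws x (3*(5+nc)) x N` at
#'   strides 8/16/32, with attributes `strides` and `anchors`.
#' @export
forward_detector <- function(model, x, train = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input spatial dimensions must be divisible by 32")
  }
  outs <- vector("list", length(model$layers))
  for (l in model$layers) {
    inputs <- lapply(l$from, function(f) {
      if (f == -1) { if (l$index == 0) x else outs[[l$index]] }
      else outs[[f + 1L]]
    })
    y <- if (length(inputs) == 1L) l$module$forward(inputs[[1]], train)
    else l$module$forward(inputs, train)
    outs[[l$index + 1L]] <- y
  }
  raw <- outs[[length(outs)]]
  attr(raw, "strides") <- model$cfg$strides
  attr(raw, "anchors") <- model$cfg$anchors
  attr(raw, "nc") <- model$cfg$nc
  raw
}

# Backpropagate gradients of the three raw head tensors through the graph.
backward_detector <- function(model, dlist) {
  n <- length(model$layers)
  gacc <- vector("list", n)
  gacc[[n]] <- dlist
  for (i in rev(seq_len(n))) {
    g <- gacc[[i]]
    if (is.null(g)) next
    l <- model$layers[[i]]
    dins <- l$module$backward(g)
    if (length(l$from) == 1L) dins <- list(dins)
    for (j in seq_along(l$from)) {
      f <- l$from[j]
      tgt <- if (f == -1) i - 1L else f + 1L
      if (tgt < 1L) next  # gradient w.r.t. the input image: discarded
      gacc[[tgt]] <- if (is.null(gacc[[tgt]])) dins[[j]]
      else gacc[[tgt]] + dins[[j]]
    }
    gacc[[i]] <- NULL
  }
  invisible(NULL)
}

#' Run detection on images
#'
#' Forward pass plus box decoding and greedy non-maximum suppression.
#'
#' @param object a `spike_yolo` model.
#' @param images an H x W x 3 x N array (or single H x W x 3 image) already
#'   sized to a multiple of 32 (see [letterbox()]).
#' @param conf_thresh confidence threshold in `[0, 1]`.
#' @param iou_thresh NMS IoU threshold in `[0, 1]`.
#' @param ... unused.
#' @return list (one element per image) of data frames with columns
#'   `cx, cy, w, h, score, class`, sorted by descending score.
#' @export
predict.spike_yolo <- function(object, images, conf_thresh = 0.25,
                               iou_thresh = 0.45, ...) {
  raw <- forward_detector(object, images, train = FALSE)
  decode_and_nms(raw, conf_thresh, iou_thresh)
}

#' Decode raw head outputs and apply non-maximum suppression
#'
#' Grid-cell offsets are mapped to absolute pixel boxes with the usual
#' sigmoid parameterization (`xy = (2*sig - 0.5 + cell) * stride`,
#' `wh = (2*sig)^2 * anchor`), thresholded on `sigmoid(obj) * sigmoid(cls)`,
#' and pruned per class by greedy NMS.
#'
#' @param raw output of [forward_detector()].
#' @param conf_thresh,iou_thresh thresholds in `[0, 1]`.
#' @param anchors,strides,nc normally taken from `raw` attributes.
#' @return list per image of data frames `cx, cy, w, h, score, class`.
#' @export
decode_and_nms <- function(raw, conf_thresh = 0.25, iou_thresh = 0.45,
                           anchors = attr(raw, "anchors"),
                           strides = attr(raw, "strides"),
                           nc = attr(raw, "nc")) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1,
            iou_thresh >= 0, iou_thresh <= 1)
  N <- dim(raw[[1]])[4]
  empty <- data.frame(cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0), score = numeric(0), class = integer(0))
  out <- rep(list(empty), N)
  for (s in seq_along(raw)) {
    A <- raw[[s]]
    d <- dim(A)
    stride <- strides[s]
    anc <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
    for (n in seq_len(N)) {
      for (a in 1:3) {
        base <- (a - 1L) * (5L + nc)
        tx <- sigmoid(A[, , base + 1L, n])
        ty <- sigmoid(A[, , base + 2L, n])
        tw <- sigmoid(A[, , base + 3L, n])
        th <- sigmoid(A[, , base + 4L, n])
        obj <- sigmoid(A[, , base + 5L, n])
        cls <- sigmoid(A[, , base + 5L + seq_len(nc), n, drop = FALSE])
        dim(cls) <- c(d[1] * d[2], nc)
        best <- max.col(cls, ties.method = "first")
        score <- as.vector(obj) * cls[cbind(seq_len(d[1] * d[2]), best)]
        keep <- which(score >= conf_thresh & score > 0)
        if (conf_thresh >= 1) keep <- which(score >= 1)
        if (!length(keep)) next
        gj <- (keep - 1L) %% d[1]        # row -> y cell
        gi <- (keep - 1L) %/% d[1]       # col -> x cell
        cx <- (2 * as.vector(tx)[keep] - 0.5 + gi) * stride
        cy <- (2 * as.vector(ty)[keep] - 0.5 + gj) * stride
        w <- (2 * as.vector(tw)[keep])^2 * anc[a, 1]
        h <- (2 * as.vector(th)[keep])^2 * anc[a, 2]
        out[[n]] <- rbind(out[[n]],
                          data.frame(cx = cx, cy = cy, w = w, h = h,
                                     score = score[keep],
                                     class = best[keep]))
      }
    }
  }
  img_w <- dim(raw[[1]])[2] * strides[1]
  img_h <- dim(raw[[1]])[1] * strides[1]
  lapply(out, function(df) {
    if (!nrow(df)) return(df)
    keep_all <- integer(0)
    for (cl in unique(df$class)) {
      idx <- which(df$class == cl)
      kp <- nms(as.matrix(df[idx, c("cx", "cy", "w", "h")]),
                df$score[idx], iou_thresh)
      keep_all <- c(keep_all, idx[kp])
    }
    df <- df[keep_all, , drop = FALSE]
    df <- df[order(-df$score), , drop = FALSE]
    # clip decoded boxes to the image
    x1 <- pmax(df$cx - df$w / 2, 0); x2 <- pmin(df$cx + df$w / 2, img_w)
    y1 <- pmax(df$cy - df$h / 2, 0); y2 <- pmin(df$cy + df$h / 2, img_h)
    ok <- x2 > x1 & y2 > y1
    df <- df[ok, , drop = FALSE]
    df$cx <- (x1[ok] + x2[ok]) / 2; df$w <- x2[ok] - x1[ok]
    df$cy <- (y1[ok] + y2[ok]) / 2; df$h <- y2[ok] - y1[ok]
    rownames(df) <- NULL
    df
  })
}

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 matrix of center-format boxes (`cx, cy, w, h`).
#' @param scores numeric vector of length n.
#' @param iou_thresh suppression threshold; a box is removed when its IoU
#'   with an already-kept higher-scoring box is `>= iou_thresh`.
#' @return integer indices of the surviving boxes.
#' @export
nms <- function(boxes, scores, iou_thresh = 0.45) {
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (!length(ord)) break
    ious <- iou(boxes[rep(i, length(ord)), , drop = FALSE],
                boxes[ord, , drop = FALSE])
    ord <- ord[ious < iou_thresh]
  }
  keep
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized file holding the configuration, every
#' trainable parameter and the batch-norm running statistics, tagged with a
#' format version.
#'
#' @param model a `spike_yolo` model.
#' @param path file path.
#' @return `load_checkpoint` returns a rebuilt `spike_yolo` model.
#' @export
save_checkpoint <- function(model, path) {
  leaves <- collect_modules_model(model)
  state <- lapply(leaves, function(leaf) {
    s <- lapply(leaf$param_names, function(p) leaf[[p]])
    names(s) <- leaf$param_names
    if (leaf$type == "batchnorm") {
      s$running_mean <- leaf$running_mean
      s$running_var <- leaf$running_var
    }
    s
  })
  saveRDS(list(format = "spikedet-checkpoint-1", cfg = model$cfg,
               state = state), path)
  invisible(path)
}

collect_modules_model <- function(model) {
  out <- list()
  for (l in model$layers) out <- c(out, collect_modules_all(l$module))
  out
}

# like collect_modules() but also returns parameter-free stateful leaves
collect_modules_all <- function(m) {
  out <- list()
  if (length(m$param_names) > 0L || m$type == "batchnorm") {
    out[[length(out) + 1L]] <- m
  }
  for (ch in m$children) out <- c(out, collect_modules_all(ch))
  out
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "spikedet-checkpoint-1")) {
    stop("unrecognized checkpoint format")
  }
  model <- spike_yolo(ck$cfg)
  leaves <- collect_modules_model(model)
  if (length(leaves) != length(ck$state)) stop("checkpoint/model mismatch")
  for (i in seq_along(leaves)) {
    leaf <- leaves[[i]]
    for (p in leaf$param_names) leaf[[p]] <- ck$state[[i]][[p]]
    if (leaf$type == "batchnorm") {
      leaf$running_mean <- ck$state[[i]]$running_mean
      leaf$running_var <- ck$state[[i]]$running_var
    }
  }
  model
}
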