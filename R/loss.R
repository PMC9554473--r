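# Composite training loss: CIoU localization + binary cross-entropy
# objectness and class terms, with YOLO-style anchor-target assignment.
#
# Gradients of the BCE terms are analytic; the gradient of the CIoU term
# with respect to the four raw box activations is computed by central finite
# differences with the balance weight alpha frozen at its current value
# (alpha is excluded from gradient computation).

# Assign targets to (scale, anchor, cell) triples.  A target matches an
# anchor when max(w/aw, aw/w, h/ah, ah/h) < ratio_thresh; the containing
# grid cell takes the assignment.
build_targets <- function(targets, anchors, strides, grid_hw,
                          ratio_thresh = 4.0) {
  rows <- list()
  for (n in seq_along(targets)) {
    tb <- targets[[n]]
    if (is.null(tb) || !nrow(tb)) next
    tb <- as_box_matrix(tb)
    for (s in seq_along(strides)) {
      st <- strides[s]
      anc <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
      for (a in 1:3) {
        r <- pmax(tb[, 3] / anc[a, 1], anc[a, 1] / tb[, 3],
                  tb[, 4] / anc[a, 2], anc[a, 2] / tb[, 4])
        sel <- which(r < ratio_thresh)
        if (!length(sel)) next
        gi <- clamp(floor(tb[sel, 1] / st), 0, grid_hw[s, 2] - 1)
        gj <- clamp(floor(tb[sel, 2] / st), 0, grid_hw[s, 1] - 1)
        rows[[length(rows) + 1L]] <-
          data.frame(img = n, scale = s, anchor = a, gi = gi, gj = gj,
                     gx = tb[sel, 1], gy = tb[sel, 2],
                     gw = tb[sel, 3], gh = tb[sel, 4])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(img = integer(0), scale = integer(0),
                      anchor = integer(0), gi = integer(0), gj = integer(0),
                      gx = numeric(0), gy = numeric(0),
                      gw = numeric(0), gh = numeric(0)))
  }
  do.call(rbind, rows)
}

bce <- function(logit, target) {
  # numerically stable binary cross-entropy on logits
  pmax(logit, 0) - logit * target + log1p(exp(-abs(logit)))
}

#' Composite detection loss
#'
#' Box term: mean CIoU loss over matched anchor-target pairs.  Objectness:
#' binary cross-entropy against the matched pair's CIoU value (clamped to
#' `[0, 1]`, zero elsewhere), averaged per scale with balance weights
#' 4.0/1.0/0.4.  Class term: binary cross-entropy at matched cells.  Total
#' is the weighted sum with weights `box = 0.05, obj = 1.0, cls = 0.5`.
#'
#' @param raw output of [forward_detector()].
#' @param targets list (one per image) of ground-truth box matrices
#'   (`cx, cy, w, h` in input pixels); `NULL` or 0-row entries allowed.
#' @param anchors,strides,nc normally taken from `raw` attributes.
#' @param weights named vector of term weights.
#' @param ratio_thresh anchor match threshold.
#' @param with_grad also return gradients with respect to the raw head
#'   tensors (used by the trainer).
#' @return list with `total`, `box`, `obj`, `cls`, `n_matched` (and `grads`
#'   when requested); all terms finite and non-negative.
#' @export
detection_loss <- function(raw, targets,
                           anchors = attr(raw, "anchors"),
                           strides = attr(raw, "strides"),
                           nc = attr(raw, "nc"),
                           weights = c(box = 0.05, obj = 1.0, cls = 0.5),
                           ratio_thresh = 4.0,
                           with_grad = FALSE) {
  N <- dim(raw[[1]])[4]
  grid_hw <- t(vapply(raw, function(A) dim(A)[1:2], numeric(2)))
  tt <- build_targets(targets, anchors, strides, grid_hw, ratio_thresh)
  balance <- c(4.0, 1.0, 0.4)
  no <- 5L + nc

  grads <- if (with_grad) lapply(raw, function(A) array(0, dim = dim(A)))
  box_losses <- numeric(0)
  cls_loss_sum <- 0
  obj_loss <- 0
  n_matched <- nrow(tt)

  # per-scale objectness targets, filled in while walking matches
  obj_t <- lapply(raw, function(A) {
    array(0, dim = c(dim(A)[1], dim(A)[2], 3L, dim(A)[4]))
  })

  scale_entries <- split(seq_len(max(n_matched, 0)), if (n_matched) tt$scale
                         else integer(0))
  for (s in seq_along(raw)) {
    A <- raw[[s]]
    es <- scale_entries[[as.character(s)]]
    if (is.null(es) || !length(es)) next
    e <- tt[es, , drop = FALSE]
    st <- strides[s]
    anc <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
    base <- (e$anchor - 1L) * no
    ii <- cbind(e$gj + 1L, e$gi + 1L, 0L, e$img)   # template index
    idx <- function(ch) {
      m <- ii; m[, 3] <- base + ch; m
    }
    tx <- A[idx(1L)]; ty <- A[idx(2L)]
    tw <- A[idx(3L)]; th <- A[idx(4L)]
    aw <- anc[e$anchor, 1]; ah <- anc[e$anchor, 2]
    gtb <- cbind(e$gx, e$gy, e$gw, e$gh)

    decode_box <- function(tx, ty, tw, th) {
      cbind((2 * sigmoid(tx) - 0.5 + e$gi) * st,
            (2 * sigmoid(ty) - 0.5 + e$gj) * st,
            (2 * sigmoid(tw))^2 * aw,
            (2 * sigmoid(th))^2 * ah)
    }
    pb <- decode_box(tx, ty, tw, th)
    tm <- ciou_terms(pb, gtb)
    box_losses <- c(box_losses, tm$loss)

    # objectness target = CIoU value (detached), clamped to [0, 1]
    oidx <- cbind(e$gj + 1L, e$gi + 1L, e$anchor, e$img)
    obj_t[[s]][oidx] <- clamp(tm$iou - tm$rho2 / tm$c2 - tm$alpha * tm$v, 0, 1)

    # class loss (single positive class per target)
    cl <- A[idx(6L)]
    cls_loss_sum <- cls_loss_sum + sum(bce(cl, 1))

    if (with_grad) {
      h <- 1e-4
      dbox <- matrix(0, length(es), 4)
      acts <- list(tx, ty, tw, th)
      for (k in 1:4) {
        up <- acts; up[[k]] <- up[[k]] + h
        dn <- acts; dn[[k]] <- dn[[k]] - h
        lu <- ciou_terms(do.call(decode_box, up), gtb, alpha = tm$alpha)$loss
        ld <- ciou_terms(do.call(decode_box, dn), gtb, alpha = tm$alpha)$loss
        dbox[, k] <- (lu - ld) / (2 * h)
      }
      # duplicate (cell, anchor) assignments must accumulate, so convert to
      # linear indices and sum per index before adding
      d <- dim(A)
      lin <- function(ch) {
        (e$img - 1) * prod(d[1:3]) + (base + ch - 1) * d[1] * d[2] +
          e$gi * d[1] + e$gj + 1
      }
      add_at <- function(s, li, val) {
        agg <- rowsum(val, li)
        at <- as.numeric(rownames(agg))
        grads[[s]][at] <<- grads[[s]][at] + agg[, 1]
      }
      wb <- weights[["box"]] / max(n_matched, 1L)
      for (k in 1:4) add_at(s, lin(k), wb * dbox[, k])
      wc <- weights[["cls"]] / max(n_matched, 1L)
      add_at(s, lin(6L), wc * (sigmoid(cl) - 1))
    }
  }

  for (s in seq_along(raw)) {
    A <- raw[[s]]
    d <- dim(A)
    ol <- A[, , (0:2) * no + 5L, , drop = FALSE]
    tgt <- obj_t[[s]]
    obj_loss <- obj_loss + balance[s] * mean(bce(ol, tgt))
    if (with_grad) {
      gobj <- weights[["obj"]] * balance[s] * (sigmoid(ol) - tgt) / length(ol)
      grads[[s]][, , (0:2) * no + 5L, ] <- gobj
    }
  }

  box_loss <- if (length(box_losses)) mean(box_losses) else 0
  cls_loss <- if (n_matched) cls_loss_sum / n_matched else 0
  total <- weights[["box"]] * box_loss + weights[["obj"]] * obj_loss +
    weights[["cls"]] * cls_loss
  out <- list(total = total, box = box_loss, obj = obj_loss, cls = cls_loss,
              n_matched = n_matched)
  if (with_grad) out$grads <- grads
  out
}
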