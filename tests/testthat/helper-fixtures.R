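# Shared fixtures: small random boxes, tiny labeled images and a brute-force
# average-precision oracle used to cross-check the interpolated computation.

random_boxes <- function(n, lim = 100, wmax = 40) {
  cbind(cx = runif(n, wmax, lim - wmax), cy = runif(n, wmax, lim - wmax),
        w = runif(n, 1, wmax), h = runif(n, 1, wmax))
}

tiny_image <- function(h = 64, w = 64, value = 0.5) {
  array(value, dim = c(h, w, 3))
}

tiny_labeled <- function(h = 64, w = 64, boxes = NULL, id = "t") {
  labeled_image(tiny_image(h, w), boxes, id = id)
}

# independent AP oracle: explicit greedy matching loops plus direct
# 101-point interpolation over the raw precision/recall prefixes
ap_bruteforce <- function(dets, gts, iou_match = 0.5) {
  ord <- order(-dets$score)
  taken <- rep(FALSE, nrow(gts))
  tp <- logical(length(ord))
  for (r in seq_along(ord)) {
    k <- ord[r]
    best_i <- 0; best_v <- -1
    for (g in seq_len(nrow(gts))) {
      if (taken[g] || gts$image[g] != dets$image[k]) next
      v <- iou(unlist(dets[k, c("cx", "cy", "w", "h")]),
               unlist(gts[g, c("cx", "cy", "w", "h")]))
      if (v > best_v) { best_v <- v; best_i <- g }
    }
    if (best_i > 0 && best_v >= iou_match) { tp[r] <- TRUE; taken[best_i] <- TRUE }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(gts)
  mean(sapply(seq(0, 1, 0.01), function(r) {
    p <- prec[rec >= r - 1e-12]
    if (length(p)) max(p) else 0
  }))
}
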