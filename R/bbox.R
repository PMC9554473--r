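# Axis-aligned bounding boxes.  Everywhere in the package a box is a row of
# a numeric matrix in center format (cx, cy, w, h), in pixels; corner views
# (x1, y1, x2, y2) use 0-based, half-open coordinates.

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) < 4) stop("boxes need 4 columns (cx, cy, w, h)")
  b[, 1:4, drop = FALSE]
}

check_boxes <- function(b) {
  if (any(!is.finite(b))) stop("boxes must be finite")
  if (any(b[, 3] <= 0) || any(b[, 4] <= 0)) {
    stop("degenerate box: width and height must be positive")
  }
  b
}

#' Convert between center and corner box formats
#'
#' @param b matrix (or length-4 vector) of boxes.
#' @return matrix in the other format.
#' @export
xywh_to_xyxy <- function(b) {
  b <- as_box_matrix(b)
  cbind(x1 = b[, 1] - b[, 3] / 2, y1 = b[, 2] - b[, 4] / 2,
        x2 = b[, 1] + b[, 3] / 2, y2 = b[, 2] + b[, 4] / 2)
}

#' @rdname xywh_to_xyxy
#' @export
xyxy_to_xywh <- function(b) {
  b <- as_box_matrix(b)
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' Intersection over union of box pairs
#'
#' Rowwise IoU of two equally sized sets of center-format boxes.
#'
#' @param a,b n x 4 matrices (or length-4 vectors) `cx, cy, w, h`.
#' @return numeric vector of IoU values in `[0, 1]`.
#' @examples
#' iou(c(1, 1, 2, 2), c(2, 2, 2, 2))  # corners (0,0,2,2) vs (1,1,3,3): 1/7
#' @export
iou <- function(a, b) {
  a <- check_boxes(as_box_matrix(a))
  b <- check_boxes(as_box_matrix(b))
  ca <- xywh_to_xyxy(a); cb <- xywh_to_xyxy(b)
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  union <- a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter
  inter / union
}

# full IoU matrix between two box sets (rows of A x rows of B)
iou_matrix <- function(A, B) {
  A <- as_box_matrix(A); B <- as_box_matrix(B)
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B))) {
    out[, j] <- iou(A, B[rep(j, nrow(A)), , drop = FALSE])
  }
  out
}

#' Complete-IoU (CIoU) loss terms
#'
#' For each predicted/ground-truth box pair computes
#' \deqn{L = 1 - IoU + \rho^2(b, b^{gt})/c^2 + \alpha v,}
#' where \eqn{\rho^2} is the squared center distance, \eqn{c^2} the squared
#' diagonal of the smallest axis-aligned box enclosing both,
#' \eqn{v = 4/\pi^2 (\arctan(w^{gt}/h^{gt}) - \arctan(w/h))^2} the
#' aspect-ratio consistency term and \eqn{\alpha = v / ((1 - IoU) + v)} a
#' balance weight treated as a constant with respect to gradients.
#'
#' @param pred,gt n x 4 matrices (or length-4 vectors) of center-format boxes.
#' @param alpha optional fixed alpha (used when differentiating with alpha
#'   frozen); default recomputes it from the current pair.
#' @return data frame with columns `iou, rho2, c2, v, alpha, loss`.
#' @export
ciou_terms <- function(pred, gt, alpha = NULL) {
  pred <- check_boxes(as_box_matrix(pred))
  gt <- check_boxes(as_box_matrix(gt))
  i <- iou(pred, gt)
  rho2 <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  ca <- xywh_to_xyxy(pred); cb <- xywh_to_xyxy(gt)
  cw <- pmax(ca[, 3], cb[, 3]) - pmin(ca[, 1], cb[, 1])
  chh <- pmax(ca[, 4], cb[, 4]) - pmin(ca[, 2], cb[, 2])
  c2 <- cw^2 + chh^2
  v <- (4 / pi^2) * (atan(gt[, 3] / gt[, 4]) - atan(pred[, 3] / pred[, 4]))^2
  if (is.null(alpha)) alpha <- ifelse(v > 0, v / ((1 - i) + v), 0)
  loss <- 1 - i + rho2 / c2 + alpha * v
  data.frame(iou = i, rho2 = rho2, c2 = c2, v = v, alpha = alpha, loss = loss)
}

#' CIoU loss
#'
#' @inheritParams ciou_terms
#' @return numeric vector of non-negative losses (0 iff the boxes are
#'   identical), with the term breakdown attached as attribute `"terms"`.
#' @examples
#' ciou_loss(c(0, 0, 2, 2), c(0, 0, 4, 4))  # concentric squares: 0.75
#' @export
ciou_loss <- function(pred, gt, alpha = NULL) {
  tm <- ciou_terms(pred, gt, alpha)
  structure(tm$loss, terms = tm)
}
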