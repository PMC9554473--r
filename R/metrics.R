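# Detection and counting evaluation metrics.

#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(!is.finite(v))) stop("counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + FN + FP + TN)`.  For detection work the true-negative
#' count is ill-defined, so this applies to abstract counts only; counting
#' performance is reported via [mean_error_accuracy()].
#'
#' @param c a [confusion_counts()] object.
#' @return value in `[0, 1]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- c$tp + c$fn + c$fp + c$tn
  if (den == 0) stop("accuracy undefined for all-zero counts")
  (c$tp + c$tn) / den
}

#' Recall from confusion counts
#'
#' `TP / (TP + FN)`.
#'
#' @inheritParams accuracy
#' @return value in `[0, 1]`.
#' @export
recall <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) stop("recall undefined when TP + FN = 0")
  c$tp / (c$tp + c$fn)
}

# Greedy score-ranked matching of detections to ground truths at a fixed IoU
# threshold.  Returns the TP/FP flag per detection (score-sorted) and the
# total ground-truth count.
match_detections <- function(dets, gts, iou_match = 0.5) {
  n_gt <- nrow(gts)
  if (!nrow(dets)) {
    return(list(tp = logical(0), score = numeric(0), n_gt = n_gt))
  }
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  used <- lapply(split(seq_len(n_gt), gts$image), function(i) {
    list(idx = i, taken = rep(FALSE, length(i)))
  })
  tp <- logical(nrow(dets))
  for (k in seq_len(nrow(dets))) {
    img <- as.character(dets$image[k])
    u <- used[[img]]
    if (is.null(u) || all(u$taken)) next
    cand <- u$idx[!u$taken]
    ious <- iou(dets[rep(k, length(cand)), c("cx", "cy", "w", "h")],
                gts[cand, c("cx", "cy", "w", "h")])
    j <- which.max(ious)
    if (ious[j] >= iou_match) {
      tp[k] <- TRUE
      u$taken[which(!u$taken)[j]] <- TRUE
      used[[img]] <- u
    }
  }
  list(tp = tp, score = dets$score, n_gt = n_gt)
}

#' Average precision at a fixed IoU match threshold
#'
#' Detections are ranked by score and matched greedily to at most one ground
#' truth each (same image, IoU at least `iou_match`).  AP is the area under
#' the precision-recall envelope evaluated by 101-point interpolation.
#'
#' @param dets data frame with columns `image, score, cx, cy, w, h`.
#' @param gts data frame with columns `image, cx, cy, w, h`.
#' @param iou_match IoU threshold for a match (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_match = 0.5) {
  if (!nrow(gts)) stop("average precision undefined with zero ground truths")
  mm <- match_detections(dets, gts, iou_match)
  if (!length(mm$tp)) return(0)
  tp_cum <- cumsum(mm$tp)
  rec <- tp_cum / mm$n_gt
  prec <- tp_cum / seq_along(mm$tp)
  ap_interp(rec, prec)
}

ap_interp <- function(rec, prec, points = seq(0, 1, by = 0.01)) {
  mean(vapply(points, function(r) {
    p <- prec[rec >= r - 1e-12]
    if (length(p)) max(p) else 0
  }, numeric(1)))
}

#' Mean average precision over IoU thresholds
#'
#' @inheritParams average_precision
#' @param thresholds IoU thresholds; default `0.50, 0.55, ..., 0.95`.
#' @return mean of [average_precision()] over `thresholds`.
#' @export
mean_average_precision <- function(dets, gts,
                                   thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds, function(t) average_precision(dets, gts, t),
              numeric(1)))
}

check_series <- function(p, q) {
  if (length(p) != length(q) || !length(p)) {
    stop("count series must be non-empty and of equal length")
  }
  if (any(q < 0)) stop("ground-truth counts must be non-negative")
  invisible(NULL)
}

#' Root-mean-square counting error
#'
#' \eqn{\sqrt{\frac{1}{N}\sum_i (p_i - q_i)^2}} over per-image predicted
#' (`p`) and ground-truth (`q`) object counts.
#'
#' @param p,q numeric vectors of equal length `N >= 1`.
#' @return non-negative scalar; always `>=` [mae()].
#' @export
rmse <- function(p, q) {
  check_series(p, q)
  sqrt(mean((p - q)^2))
}

#' Mean absolute counting error
#'
#' \eqn{\frac{1}{N}\sum_i |p_i - q_i|}.
#'
#' @inheritParams rmse
#' @return non-negative scalar.
#' @export
mae <- function(p, q) {
  check_series(p, q)
  mean(abs(p - q))
}

#' Relative counting error and accuracy (percent)
#'
#' `mean_error = 100 * mean(|p_i - q_i| / q_i)` and
#' `mean_accuracy = max(0, 100 - mean_error)`.
#'
#' @inheritParams rmse
#' @return list with `mean_error` and `mean_accuracy`, both in percent.
#' @export
mean_error_accuracy <- function(p, q) {
  check_series(p, q)
  if (any(q == 0)) stop("relative error undefined when a ground-truth count is 0")
  me <- 100 * mean(abs(p - q) / q)
  list(mean_error = me, mean_accuracy = max(0, 100 - me))
}

#' Assemble a per-image counting report
#'
#' @param ids image identifiers.
#' @param p,q per-image predicted / ground-truth counts.
#' @param dets,gts optional detection/ground-truth data frames (columns as in
#'   [average_precision()]) enabling the mAP and recall entries.
#' @return list of class `count_report` with `$per_image` (data frame
#'   `id, p, q, error`) and `$summary` (RMSE, MAE, mean error/accuracy and,
#'   when detections are given, recall at IoU 0.5, mAP@0.5 and mAP@0.5:0.95).
#' @export
count_report <- function(ids, p, q, dets = NULL, gts = NULL) {
  check_series(p, q)
  per_image <- data.frame(id = ids, p = p, q = q, error = p - q,
                          stringsAsFactors = FALSE)
  summary <- list(rmse = rmse(p, q), mae = mae(p, q))
  if (all(q > 0)) summary <- c(summary, mean_error_accuracy(p, q))
  if (!is.null(dets) && !is.null(gts) && nrow(gts)) {
    mm <- match_detections(dets, gts, 0.5)
    tp <- sum(mm$tp)
    summary$recall <- tp / mm$n_gt
    summary$map50 <- average_precision(dets, gts, 0.5)
    summary$map50_95 <- mean_average_precision(dets, gts)
  }
  structure(list(per_image = per_image, summary = summary),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("Counting report over %d images\n", nrow(x$per_image)))
  for (nm in names(x$summary)) {
    cat(sprintf("  %-13s %.4f\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

#' Write a counting report to disk
#'
#' Writes `counts.csv` (per-image id, predicted, ground truth, error) and
#' `summary.json` into `dir`.
#'
#' @param report a [count_report()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_count_report <- function(report, dir) {
  stopifnot(inherits(report, "count_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_image, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
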