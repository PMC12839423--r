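#' Detection evaluation: matching, precision/recall/F1, AP and mAP
#'
#' Detections and ground truths are plain data frames in pixel center format.
#' Detections need columns `class_id`, `confidence`, `xc`, `yc`, `w`, `h` and
#' optionally `image` (evaluation is per image when present); ground truths
#' need `class_id`, `xc`, `yc`, `w`, `h` and optionally `image`.
#'
#' @name detection-metrics
NULL

check_det_frame <- function(dets) {
  need <- c("class_id", "confidence", "xc", "yc", "w", "h")
  if (!all(need %in% names(dets)))
    stop("detections need columns: ", paste(need, collapse = ", "))
  if (nrow(dets) && (any(dets$confidence < 0) || any(dets$confidence > 1)))
    stop("confidences must lie in [0, 1]")
  if (is.null(dets$image)) dets$image <- rep(1L, nrow(dets))
  dets
}

check_gt_frame <- function(gts) {
  need <- c("class_id", "xc", "yc", "w", "h")
  if (!all(need %in% names(gts)))
    stop("ground truths need columns: ", paste(need, collapse = ", "))
  if (is.null(gts$image)) gts$image <- rep(1L, nrow(gts))
  gts
}

# IoU matrix between all rows of two center-format box frames.
iou_matrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  out <- matrix(0, nrow(a), nrow(b))
  bm <- as.matrix(b[, c("xc", "yc", "w", "h")])
  for (i in seq_len(nrow(a))) {
    ai <- as.matrix(a[i, c("xc", "yc", "w", "h")])
    out[i, ] <- inner_iou(ai[rep(1L, nrow(b)), , drop = FALSE], bm, ratio = 1)
  }
  out
}

#' Greedy one-to-one matching of detections to ground truths
#'
#' Detections are processed in order of decreasing confidence; ties are
#' broken by box content (class, then center, then size), so the result is
#' invariant to the input row order. A detection is a true positive iff its
#' best IoU with a not-yet
#' matched ground-truth box of the same class, in the same image, reaches
#' `iou_threshold`; each ground truth is consumed by at most one detection.
#'
#' @param dets detection data frame (see [detection-metrics]).
#' @param gts ground-truth data frame.
#' @param iou_threshold IoU needed to call a detection correct (default 0.5).
#' @return list with `flags` (the detections, sorted by descending confidence,
#'   plus a logical `tp` column) and `counts` (per-class data frame of
#'   `tp`, `fp`, `fn`; `tp + fn` equals the ground-truth count of the class).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets <- check_det_frame(dets); gts <- check_gt_frame(gts)
  ord <- order(-dets$confidence, dets$class_id, dets$xc, dets$yc,
               dets$w, dets$h)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  gt_used <- logical(nrow(gts))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!gt_used & gts$class_id == dets$class_id[i] &
                    gts$image == dets$image[i])
    if (!length(cand)) next
    ious <- inner_iou(as.matrix(dets[i, c("xc", "yc", "w", "h")])[rep(1L, length(cand)), , drop = FALSE],
                      as.matrix(gts[cand, c("xc", "yc", "w", "h")]), ratio = 1)
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      gt_used[cand[j]] <- TRUE
    }
  }
  dets$tp <- tp
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  counts <- do.call(rbind, lapply(classes, function(k) {
    data.frame(class_id = k,
               tp = sum(tp[dets$class_id == k]),
               fp = sum(!tp[dets$class_id == k]),
               fn = sum(gts$class_id == k) - sum(tp[dets$class_id == k]))
  }))
  list(flags = dets, counts = counts)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. A zero denominator
#' yields 0 with a warning (the convention of common detection evaluators).
#' Inputs may be scalars or equal-length vectors (e.g. per class).
#'
#' @param tp,fp,fn non-negative counts, or a `counts` data frame from
#'   [match_detections()] passed as `tp` with `fp`/`fn` missing.
#' @return data frame with columns `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(tp = 8, fp = 2, fn = 4)
#' @export
precision_recall_f1 <- function(tp, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    counts <- tp; tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  }
  stopifnot(length(tp) == length(fp), length(tp) == length(fn))
  if (any(tp + fp == 0) || any(tp + fn == 0))
    warning("zero TP+FP or TP+FN; reporting 0 for the degenerate metric")
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  data.frame(precision = p, recall = r, f1 = f1)
}

#' F1 score from precision and recall
#'
#' Convenience harmonic mean `2PR/(P+R)` on whatever scale `p` and `r` share
#' (fractions or percentages).
#'
#' @param p,r precision and recall.
#' @return F1 on the same scale.
#' @examples
#' f1_score(93.03, 95.01)  # 94.01 to two decimals
#' @export
f1_score <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Precision-recall curve with all-point interpolation
#'
#' Builds the PR curve from confidence-sorted TP/FP flags: cumulative
#' precision and recall after each detection, plus the interpolated precision
#' `P_inter(r) = max(precision at recall >= r)`.
#'
#' @param tp logical vector of per-detection outcomes, already sorted by
#'   decreasing confidence (as returned in `flags` by [match_detections()]).
#' @param n_gt number of ground-truth boxes of the class; must be > 0.
#' @return object of class `pr_curve`: data frame with `recall`, `precision`,
#'   `p_inter`, including the leading `recall = 0` anchor point.
#' @export
pr_curve <- function(tp, n_gt) {
  if (n_gt <= 0) stop("AP is undefined without ground-truth boxes")
  tp <- as.logical(tp)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- c(0, recall)
  precision <- c(1, precision)
  # running max from the right: max precision at any recall >= r
  p_inter <- rev(cummax(rev(precision)))
  structure(data.frame(recall = recall, precision = precision,
                       p_inter = p_inter),
            class = c("pr_curve", "data.frame"))
}

#' Average precision (area under the interpolated PR curve)
#'
#' All-point interpolation: `AP = sum over consecutive recall points of
#' (r_{i+1} - r_i) * P_inter(r_{i+1})`, starting from the recall-0 anchor.
#'
#' @param curve a `pr_curve` object.
#' @return scalar in \[0, 1\].
#' @export
average_precision <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  n <- nrow(curve)
  if (n < 2L) return(0)
  sum(diff(curve$recall) * curve$p_inter[-1L])
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$recall, x$precision, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Recall", ylab = "Precision", ...)
  graphics::lines(x$recall, x$p_inter, type = "s", lty = 2)
  invisible(x)
}

#' Mean average precision over classes
#'
#' Arithmetic mean of per-class AP values; `NA` entries (classes absent from
#' the ground truth) are excluded with a warning.
#'
#' @param per_class_ap numeric vector of per-class AP values.
#' @return scalar mAP.
#' @export
mean_ap <- function(per_class_ap) {
  if (!length(per_class_ap)) stop("need at least one class")
  if (anyNA(per_class_ap)) {
    warning("excluding classes with undefined AP")
    per_class_ap <- per_class_ap[!is.na(per_class_ap)]
  }
  mean(per_class_ap)
}

#' Evaluate a detection set: per-class AP, mAP@50 and mAP@50-95
#'
#' Runs greedy matching and PR integration per class at one IoU threshold
#' (`evaluate_detections`) or over the standard threshold sweep
#' 0.50:0.05:0.95 (`map_50_95`).
#'
#' @inheritParams match_detections
#' @return `evaluate_detections`: list with `per_class` (data frame of class,
#'   AP, counts and P/R/F1 at the threshold) and `map`. `map_50_95`: list with
#'   `per_threshold` (data frame of threshold and mAP) and `map_50_95`.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets <- check_det_frame(dets); gts <- check_gt_frame(gts)
  m <- match_detections(dets, gts, iou_threshold)
  classes <- sort(unique(gts$class_id))
  ap <- vapply(classes, function(k) {
    n_gt <- sum(gts$class_id == k)
    fl <- m$flags[m$flags$class_id == k, , drop = FALSE]
    if (!nrow(fl)) return(0)
    average_precision(pr_curve(fl$tp, n_gt))
  }, numeric(1))
  counts <- m$counts[match(classes, m$counts$class_id), , drop = FALSE]
  prf <- precision_recall_f1(counts$tp, counts$fp, counts$fn)
  per_class <- cbind(data.frame(class_id = classes, ap = ap), counts[-1], prf)
  rownames(per_class) <- NULL
  list(per_class = per_class, map = mean_ap(ap))
}

#' @rdname evaluate_detections
#' @param thresholds IoU thresholds to sweep (default `seq(0.5, 0.95, 0.05)`).
#' @export
map_50_95 <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05)) {
  maps <- vapply(thresholds,
                 function(th) evaluate_detections(dets, gts, th)$map,
                 numeric(1))
  list(per_threshold = data.frame(iou_threshold = thresholds, map = maps),
       map_50_95 = mean(maps))
}
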