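#' Bounding-box constructors and IoU-family regression losses
#'
#' Boxes are center-format quadruples `(xc, yc, w, h)` in any common length
#' unit (pixels or normalized fractions), the convention used throughout the
#' package. All loss functions are vectorized: `pred` and `gt` may be numeric
#' vectors of length 4 or n x 4 matrices (one box per row).
#'
#' @name box-losses
NULL

as_box_matrix <- function(x, arg = "box") {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 4L) stop(sprintf("'%s' must have 4 elements (xc, yc, w, h)", arg))
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 4L) stop(sprintf("'%s' must be an n x 4 matrix", arg))
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
  if (any(x[, 3L] <= 0) || any(x[, 4L] <= 0))
    stop(sprintf("'%s' has non-positive width or height (degenerate box)", arg))
  colnames(x) <- c("xc", "yc", "w", "h")
  x
}

#' Auxiliary (inner) box at a given scale ratio
#'
#' Shrinks (ratio < 1) or grows (ratio > 1) a center-format box about its own
#' center: each side length is multiplied by `ratio`, the center is kept.
#' Returns edge coordinates, the operand of the inner-IoU overlap.
#'
#' @param box numeric vector `(xc, yc, w, h)` or n x 4 matrix.
#' @param ratio positive scale factor applied to both side lengths.
#' @return n x 4 matrix with columns `l`, `r`, `t`, `b` (left, right, top,
#'   bottom edges); width is `w * ratio`, height `h * ratio`.
#' @examples
#' inner_box(c(10, 10, 4, 2), ratio = 0.5)  # edges 9, 11, 9.5, 10.5
#' @export
inner_box <- function(box, ratio = 1) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("'ratio' must be a single positive number")
  b <- as_box_matrix(box)
  half_w <- b[, "w"] * ratio / 2
  half_h <- b[, "h"] * ratio / 2
  cbind(l = b[, "xc"] - half_w, r = b[, "xc"] + half_w,
        t = b[, "yc"] - half_h, b = b[, "yc"] + half_h)
}

#' Intersection-over-union of center-format boxes
#'
#' @param pred,gt boxes as `(xc, yc, w, h)` vectors or n x 4 matrices.
#' @return numeric vector of IoU values in \[0, 1\].
#' @export
box_iou <- function(pred, gt) {
  inner_iou(pred, gt, ratio = 1)
}

#' Inner-IoU: IoU of scale-`ratio` auxiliary boxes
#'
#' IoU computed between the two auxiliary boxes obtained by rescaling `pred`
#' and `gt` about their own centers by `ratio`. At `ratio = 1` this is the
#' ordinary IoU. The two factors of the intersection area are clamped at zero
#' before multiplying so that disjoint auxiliary boxes yield 0 (a product of
#' two negative extents would otherwise be spuriously positive).
#'
#' @inheritParams box_iou
#' @param ratio positive scale factor for the auxiliary boxes.
#' @return numeric vector of values in \[0, 1\].
#' @examples
#' inner_iou(c(0, 0, 2, 2), c(1, 0, 2, 2), ratio = 1)  # 1/3
#' @export
inner_iou <- function(pred, gt, ratio = 1) {
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  n <- max(nrow(p), nrow(g))
  if (nrow(p) == 1L && n > 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(g) == 1L && n > 1L) g <- g[rep(1L, n), , drop = FALSE]
  if (nrow(p) != nrow(g)) stop("'pred' and 'gt' must have the same number of boxes")
  ip <- inner_box(p, ratio); ig <- inner_box(g, ratio)
  iw <- pmax(0, pmin(ig[, "r"], ip[, "r"]) - pmax(ig[, "l"], ip[, "l"]))
  ih <- pmax(0, pmin(ig[, "b"], ip[, "b"]) - pmax(ig[, "t"], ip[, "t"]))
  inter <- iw * ih
  union <- g[, "w"] * g[, "h"] * ratio^2 + p[, "w"] * p[, "h"] * ratio^2 - inter
  unname(inter / union)
}

# CIoU internals shared by the loss and its gradient: the aspect term v and
# the weighting alpha = v / ((1 - IoU) + v), alpha conventionally frozen
# with respect to gradients.
ciou_terms <- function(p, g) {
  iou <- inner_iou(p, g, ratio = 1)
  # squared center distance over squared enclosing-box diagonal
  rho2 <- (p[, "xc"] - g[, "xc"])^2 + (p[, "yc"] - g[, "yc"])^2
  enc_w <- pmax(p[, "xc"] + p[, "w"] / 2, g[, "xc"] + g[, "w"] / 2) -
    pmin(p[, "xc"] - p[, "w"] / 2, g[, "xc"] - g[, "w"] / 2)
  enc_h <- pmax(p[, "yc"] + p[, "h"] / 2, g[, "yc"] + g[, "h"] / 2) -
    pmin(p[, "yc"] - p[, "h"] / 2, g[, "yc"] - g[, "h"] / 2)
  c2 <- enc_w^2 + enc_h^2
  v <- (4 / pi^2) * (atan(g[, "w"] / g[, "h"]) - atan(p[, "w"] / p[, "h"]))^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v), 0)
  list(iou = iou, rho2 = rho2, c2 = c2, v = v, alpha = alpha)
}

#' Complete-IoU (CIoU) regression loss
#'
#' `1 - IoU + rho^2(b, b_gt) / c^2 + alpha * v`, where `rho` is the distance
#' between box centers, `c` the diagonal of the smallest enclosing box,
#' `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2` the aspect-consistency term
#' and `alpha = v / ((1 - IoU) + v)` its weight.
#'
#' @inheritParams box_iou
#' @return numeric vector of non-negative loss values.
#' @examples
#' ciou_loss(c(0, 0, 2, 2), c(1, 0, 2, 2))  # 2/3 + 1/13
#' @export
ciou_loss <- function(pred, gt) {
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  n <- max(nrow(p), nrow(g))
  if (nrow(p) == 1L && n > 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(g) == 1L && n > 1L) g <- g[rep(1L, n), , drop = FALSE]
  tm <- ciou_terms(p, g)
  unname(1 - tm$iou + tm$rho2 / tm$c2 + tm$alpha * tm$v)
}

#' Inner-CIoU auxiliary-box regression loss
#'
#' The default (`variant = "additive"`) form is
#' `L = L_CIoU + IoU - InnerIoU(ratio)`: the CIoU loss plus the gap between
#' the plain IoU and the IoU of the `ratio`-scaled auxiliary boxes. At
#' `ratio = 1` the last two terms cancel exactly and the loss equals
#' `ciou_loss()`. `variant = "substituted"` instead substitutes the
#' auxiliary IoU for the plain IoU inside the CIoU expression
#' (`1 - InnerIoU + rho^2/c^2 + alpha v`), the original Inner-IoU
#' formulation. With `ratio > 1` the additive form can in principle go
#' slightly negative when the grown auxiliary boxes overlap more than the
#' penalty terms compensate; negative values are returned as computed,
#' never clipped.
#'
#' @inheritParams inner_iou
#' @param variant `"additive"` (default) or `"substituted"`.
#' @return numeric vector of loss values.
#' @export
inner_ciou_loss <- function(pred, gt, ratio = 1, variant = c("additive", "substituted")) {
  variant <- match.arg(variant)
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  n <- max(nrow(p), nrow(g))
  if (nrow(p) == 1L && n > 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(g) == 1L && n > 1L) g <- g[rep(1L, n), , drop = FALSE]
  tm <- ciou_terms(p, g)
  iiou <- inner_iou(p, g, ratio)
  if (variant == "additive") {
    unname((1 - tm$iou + tm$rho2 / tm$c2 + tm$alpha * tm$v) + tm$iou - iiou)
  } else {
    unname(1 - iiou + tm$rho2 / tm$c2 + tm$alpha * tm$v)
  }
}

#' Dynamic auxiliary-box ratio schedule
#'
#' Linear interpolation of the auxiliary-box scale factor from `r_start` at
#' step 0 to `r_end` at step `horizon`. Larger-than-1 ratios early in training
#' enlarge the potential intersection area (useful at low IoU); shrinking the
#' ratio later sharpens sensitivity to fine localization differences.
#'
#' @param r_start,r_end positive scale factors with `r_start >= r_end`.
#' @param horizon total number of training steps (or epochs) the schedule
#'   spans; must be >= 1.
#' @return an object of class `ratio_schedule`.
#' @examples
#' sch <- ratio_schedule(1.25, 0.75, horizon = 100)
#' ratio_at(sch, 0); ratio_at(sch, 50); ratio_at(sch, 100)
#' @export
ratio_schedule <- function(r_start = 1.25, r_end = 0.75, horizon = 100L) {
  stopifnot(is.numeric(r_start), is.numeric(r_end), r_start > 0, r_end > 0,
            horizon >= 1)
  if (r_start < r_end) stop("'r_start' must be >= 'r_end'")
  structure(list(r_start = r_start, r_end = r_end, horizon = as.numeric(horizon)),
            class = "ratio_schedule")
}

#' @rdname ratio_schedule
#' @param schedule a `ratio_schedule` object.
#' @param step training step, clamped to `[0, horizon]`.
#' @export
ratio_at <- function(schedule, step) {
  stopifnot(inherits(schedule, "ratio_schedule"))
  t <- pmin(pmax(step, 0), schedule$horizon) / schedule$horizon
  schedule$r_start + t * (schedule$r_end - schedule$r_start)
}

#' @export
print.ratio_schedule <- function(x, ...) {
  cat(sprintf("Auxiliary-box ratio schedule: %.3g -> %.3g over %g steps\n",
              x$r_start, x$r_end, x$horizon))
  invisible(x)
}

# Gradient of the inner-CIoU loss with respect to the predicted box, by
# central finite differences with alpha frozen (the CIoU convention). Cheap:
# the loss is a handful of scalar ops per box.
inner_ciou_grad <- function(pred, gt, ratio = 1, eps = 1e-5,
                            variant = "additive") {
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  grad <- matrix(0, nrow(p), 4L)
  for (k in 1:4) {
    ph <- p; ph[, k] <- ph[, k] + eps
    pl <- p; pl[, k] <- pl[, k] - eps
    # widths/heights must stay positive under perturbation
    ph[, 3:4] <- pmax(ph[, 3:4], 1e-8); pl[, 3:4] <- pmax(pl[, 3:4], 1e-8)
    grad[, k] <- (inner_ciou_loss(ph, g, ratio, variant) -
                    inner_ciou_loss(pl, g, ratio, variant)) / (2 * eps)
  }
  grad
}
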