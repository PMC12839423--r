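#' Training-time loss and desk-scale smoke training
#'
#' The detection loss combines an Inner-CIoU box-regression term on the
#' positive cells (gain 7.5) with a binary cross-entropy classification term
#' over all cells (gain 0.5), mirroring the usual YOLO loss gains. Target
#' assignment is the simple anchor-free rule: each ground-truth box is
#' assigned to the pyramid scale matching its size (side < 64 px to stride 8,
#' < 128 px to stride 16, else stride 32) and to the cell containing its
#' center. Distribution-focal-loss bin regression is delegated to the
#' surrounding framework and not re-implemented here.
#'
#' @name training
NULL

decode_cell_boxes <- function(out, stride) {
  d <- dim(out)
  tx <- out[, , 1L, , drop = FALSE]; ty <- out[, , 2L, , drop = FALSE]
  tw <- out[, , 3L, , drop = FALSE]; th <- out[, , 4L, , drop = FALSE]
  col <- matrix(rep(seq_len(d[2L]) - 1L, each = d[1L]), d[1L])
  row <- matrix(rep(seq_len(d[1L]) - 1L, times = d[2L]), d[1L])
  # cell offsets recycle across the (singleton channel x batch) trailing dims
  list(cx = (c(col) + stats::plogis(tx)) * stride,
       cy = (c(row) + stats::plogis(ty)) * stride,
       w = exp(pmin(pmax(tw, -6), 6)) * stride,
       h = exp(pmin(pmax(th, -6), 6)) * stride)
}

assign_scale <- function(w, h) {
  s <- sqrt(w * h)
  ifelse(s < 64, 1L, ifelse(s < 128, 2L, 3L))
}

#' Detection loss on raw per-scale outputs
#'
#' @param outs list of raw detect maps from [detector_forward()] (with a
#'   `strides` attribute).
#' @param targets list (length batch) of pixel-box data frames with
#'   `class_id`, `xc`, `yc`, `w`, `h` in input-image pixels.
#' @param nc number of classes.
#' @param gains named list of loss gains (`box`, `cls`).
#' @param ratio auxiliary-box scale factor for the Inner-CIoU term.
#' @param variant Inner-CIoU variant, see [inner_ciou_loss()].
#' @return list with `loss`, `box_loss`, `cls_loss`, `n_pos`, and `grads`
#'   (per-scale gradient arrays for the backward pass).
#' @export
detect_loss <- function(outs, targets, nc, gains = list(box = 7.5, cls = 0.5),
                        ratio = 1, variant = "additive") {
  strides <- attr(outs, "strides")
  nb <- dim(outs[[1L]])[4L]
  grads <- lapply(outs, function(o) array(0, dim(o)))
  n_logit <- sum(vapply(outs, function(o)
    prod(dim(o)[c(1L, 2L, 4L)]) * nc, numeric(1)))
  cls_sum <- 0
  # classification: BCE against one-hot targets (background cells all-zero)
  tgt_cls <- lapply(outs, function(o) array(0, c(dim(o)[1:2], nc, nb)))
  box_losses <- numeric(0)
  pos <- list()
  for (b in seq_len(nb)) {
    tb <- targets[[b]]
    if (is.null(tb) || !nrow(tb)) next
    sc <- assign_scale(tb$w, tb$h)
    for (t in seq_len(nrow(tb))) {
      s <- sc[t]; st <- strides[s]
      d <- dim(outs[[s]])
      i <- min(max(floor(tb$yc[t] / st) + 1L, 1L), d[1L])
      j <- min(max(floor(tb$xc[t] / st) + 1L, 1L), d[2L])
      key <- paste(s, i, j, b)
      if (!is.null(pos[[key]])) next       # one target per cell
      pos[[key]] <- TRUE
      tgt_cls[[s]][i, j, tb$class_id[t] + 1L, b] <- 1
      o <- outs[[s]][i, j, , b]
      pred <- c((j - 1L + stats::plogis(o[1L])) * st,
                (i - 1L + stats::plogis(o[2L])) * st,
                exp(min(max(o[3L], -6), 6)) * st,
                exp(min(max(o[4L], -6), 6)) * st)
      gt <- c(tb$xc[t], tb$yc[t], tb$w[t], tb$h[t])
      box_losses <- c(box_losses, inner_ciou_loss(pred, gt, ratio, variant))
      g <- inner_ciou_grad(pred, gt, ratio, variant = variant)[1L, ]
      # chain rule through the decoding
      dtx <- g[1L] * st * stats::plogis(o[1L]) * (1 - stats::plogis(o[1L]))
      dty <- g[2L] * st * stats::plogis(o[2L]) * (1 - stats::plogis(o[2L]))
      dtw <- g[3L] * pred[3L]
      dth <- g[4L] * pred[4L]
      grads[[s]][i, j, 1:4, b] <- grads[[s]][i, j, 1:4, b] +
        c(dtx, dty, dtw, dth)
    }
  }
  n_pos <- max(length(box_losses), 1L)
  for (s in seq_along(outs)) {
    logits <- outs[[s]][, , 4L + seq_len(nc), , drop = FALSE]
    p <- stats::plogis(logits)
    t <- tgt_cls[[s]]
    eps <- 1e-12
    cls_sum <- cls_sum + sum(-(t * log(p + eps) + (1 - t) * log(1 - p + eps)))
    grads[[s]][, , 4L + seq_len(nc), ] <- (p - t) * gains$cls / n_logit
    grads[[s]][, , 1:4, ] <- grads[[s]][, , 1:4, , drop = FALSE] *
      gains$box / n_pos
  }
  box_loss <- if (length(box_losses)) mean(box_losses) else 0
  cls_loss <- cls_sum / n_logit
  list(loss = gains$box * box_loss + gains$cls * cls_loss,
       box_loss = box_loss, cls_loss = cls_loss,
       n_pos = length(box_losses), grads = grads)
}

sgd_step <- function(model, lr, momentum = 0.937, weight_decay = 0.001) {
  for (layer in model$layers) {
    module_walk(layer, function(m) {
      if (!length(m$params)) return()
      if (is.null(m$vel)) m$vel <- lapply(m$params, function(p) p * 0)
      for (nm in names(m$params)) {
        g <- m$grads[[nm]] + weight_decay * m$params[[nm]]
        m$vel[[nm]] <- momentum * m$vel[[nm]] - lr * g
        m$params[[nm]] <- m$params[[nm]] + m$vel[[nm]]
      }
    })
  }
}

model_zero_grads <- function(model) {
  for (layer in model$layers) zero_grads(layer)
}

scene_to_input <- function(images) {
  # stack grayscale matrices into an H x W x 3 x N array
  d <- dim(images[[1L]])
  x <- array(0, c(d[1L], d[2L], 3L, length(images)))
  for (b in seq_along(images)) x[, , , b] <- rep(images[[b]], 3L)
  x
}

#' Desk-scale smoke training
#'
#' Runs plain SGD with momentum over the scene list for a small number of
#' epochs, batching images and applying the dynamic auxiliary-box ratio
#' schedule across steps. Intended to demonstrate optimizability (the loss
#' decreasing under training), not to reach publication-scale accuracy.
#'
#' @param model a `drought_detector`.
#' @param scenes list of `list(image=, labels=)` scenes (grayscale matrices
#'   with normalized labels).
#' @param epochs,batch_size training schedule (defaults 2 and 2).
#' @param lr,momentum,weight_decay SGD settings (momentum and weight decay
#'   follow the published training configuration; the learning rate is the
#'   desk-scale default).
#' @param schedule a [ratio_schedule()] spanning the run, or `NULL` for a
#'   constant ratio of 1.
#' @param seed RNG seed for batch shuffling.
#' @return list with `epoch_loss` (mean total loss per epoch) and
#'   `step_loss`.
#' @export
train_smoke <- function(model, scenes, epochs = 2L, batch_size = 2L,
                        lr = 0.01, momentum = 0.937, weight_decay = 0.001,
                        schedule = ratio_schedule(1.25, 0.75,
                                                  horizon = max(1L, epochs * ceiling(length(scenes) / batch_size))),
                        seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  side <- nrow(scenes[[1L]]$image)
  targets_all <- lapply(scenes, function(s)
    denormalize_labels(s$labels, side, side))
  step <- 0L
  step_loss <- numeric(0)
  epoch_loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(scenes))
    losses <- numeric(0)
    for (start in seq(1L, length(scenes), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(scenes))]
      x <- scene_to_input(lapply(scenes[idx], `[[`, "image"))
      model_zero_grads(model)
      outs <- detector_forward(model, x)
      ratio <- if (is.null(schedule)) 1 else ratio_at(schedule, step)
      ls <- detect_loss(outs, targets_all[idx], model$nc, ratio = ratio)
      detector_backward(model, ls$grads, dim(x))
      sgd_step(model, lr, momentum, weight_decay)
      losses <- c(losses, ls$loss)
      step <- step + 1L
      step_loss <- c(step_loss, ls$loss)
    }
    epoch_loss[ep] <- mean(losses)
  }
  list(epoch_loss = epoch_loss, step_loss = step_loss)
}

#' Decode raw detector outputs into detections
#'
#' Applies the cell decoding, filters by confidence, and runs greedy
#' per-class non-maximum suppression.
#'
#' @param outs raw per-scale outputs from [detector_forward()].
#' @param nc number of classes.
#' @param conf_threshold minimum class probability.
#' @param nms_iou IoU above which a lower-scoring overlapping detection of
#'   the same class is suppressed.
#' @param batch which batch element to decode.
#' @param top_k at most this many highest-confidence candidates enter NMS
#'   (the usual pre-NMS cap); `max_det` bounds the final detection count.
#' @return detection data frame (`class_id`, `confidence`, `xc`, `yc`, `w`,
#'   `h` in input pixels).
#' @export
decode_detections <- function(outs, nc, conf_threshold = 0.25, nms_iou = 0.5,
                              batch = 1L, top_k = 1000L, max_det = 300L) {
  strides <- attr(outs, "strides")
  rows <- list()
  for (s in seq_along(outs)) {
    o <- outs[[s]][, , , batch, drop = FALSE]
    d <- dim(o)
    bx <- decode_cell_boxes(o, strides[s])
    probs <- stats::plogis(o[, , 4L + seq_len(nc), 1L, drop = FALSE])
    for (k in seq_len(nc)) {
      pk <- probs[, , k, 1L]
      hit <- which(pk >= conf_threshold, arr.ind = TRUE)
      if (!nrow(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = k - 1L,
        confidence = pk[hit],
        xc = bx$cx[cbind(hit, 1L, 1L)], yc = bx$cy[cbind(hit, 1L, 1L)],
        w = bx$w[cbind(hit, 1L, 1L)], h = bx$h[cbind(hit, 1L, 1L)])
    }
  }
  if (!length(rows))
    return(data.frame(class_id = integer(), confidence = numeric(),
                      xc = numeric(), yc = numeric(), w = numeric(),
                      h = numeric()))
  dets <- do.call(rbind, rows)
  if (nrow(dets) > top_k)
    dets <- dets[order(-dets$confidence)[seq_len(top_k)], , drop = FALSE]
  # greedy per-class NMS on plain matrices
  boxes <- as.matrix(dets[, c("xc", "yc", "w", "h")])
  iou_one_many <- function(b, M) {
    iw <- pmax(0, pmin(b[1] + b[3] / 2, M[, 1] + M[, 3] / 2) -
                 pmax(b[1] - b[3] / 2, M[, 1] - M[, 3] / 2))
    ih <- pmax(0, pmin(b[2] + b[4] / 2, M[, 2] + M[, 4] / 2) -
                 pmax(b[2] - b[4] / 2, M[, 2] - M[, 4] / 2))
    inter <- iw * ih
    inter / (b[3] * b[4] + M[, 3] * M[, 4] - inter)
  }
  keep <- logical(nrow(dets))
  for (k in unique(dets$class_id)) {
    idx <- which(dets$class_id == k)
    idx <- idx[order(-dets$confidence[idx])]
    n_kept <- 0L
    while (length(idx) && n_kept < max_det) {
      keep[idx[1L]] <- TRUE
      n_kept <- n_kept + 1L
      if (length(idx) == 1L) break
      ious <- iou_one_many(boxes[idx[1L], ], boxes[idx[-1L], , drop = FALSE])
      idx <- idx[-1L][ious < nms_iou]
    }
  }
  out <- dets[keep, , drop = FALSE]
  if (nrow(out) > max_det)
    out <- out[order(-out$confidence)[seq_len(max_det)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tiled (mosaic) inference
#'
#' Composes `x^2` labelled or unlabelled images into one mosaic, resizes it
#' to the detector's nominal input side, runs a single forward pass, rescales
#' the detections to the mosaic frame, and splits them back into each tile's
#' normalized coordinate system.
#'
#' @param model a `drought_detector`.
#' @param images list of `x^2` grayscale matrices.
#' @param x tiles per side.
#' @param ... passed to [decode_detections()].
#' @return list with `per_tile` detections (as [split_detections()]) and the
#'   mosaic-frame detections.
#' @export
predict_mosaic <- function(model, images, x, ...) {
  items <- lapply(images, function(im) list(image = im, labels = empty_labels()))
  mos <- compose_mosaic(items, x)
  side <- model$input_side
  im <- resize_image(mos$image, side, side)
  outs <- detector_forward(model, im)
  dets <- decode_detections(outs, model$nc, ...)
  # back to mosaic pixel frame
  sx <- mos$layout$canvas_w / side; sy <- mos$layout$canvas_h / side
  dets$xc <- dets$xc * sx; dets$w <- dets$w * sx
  dets$yc <- dets$yc * sy; dets$h <- dets$h * sy
  list(per_tile = split_detections(dets, mos$layout), mosaic = dets)
}
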