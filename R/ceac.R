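#' Compound-eye mosaic tiling (CEAC)
#'
#' Mimicking the parallel sampling of an apposition compound eye, `x^2`
#' equally sized sub-images are pasted onto one gap-free square-grid canvas so
#' a detector sees them in a single pass; afterwards, detections made in the
#' mosaic frame are mapped back into each sub-image's own normalized
#' coordinate system. The geometry is fully described by a `mosaic_layout`:
#' tiles per side `x`, canvas and tile dimensions, and per-tile top-left
#' origins at exactly `(col * tile_w, row * tile_h)`.
#'
#' @name ceac
NULL

#' Mosaic layout geometry
#'
#' @param x tiles per side (integer >= 1); the mosaic holds `x^2` tiles.
#' @param tile_w,tile_h tile dimensions in pixels.
#' @return object of class `mosaic_layout` with fields `x`, `canvas_w`,
#'   `canvas_h`, `tile_w`, `tile_h` and an `origins` data frame (`row`, `col`
#'   0-based, `x0`, `y0` top-left pixel corners, row-major order).
#' @examples
#' mosaic_layout(3, 640, 640)
#' @export
mosaic_layout <- function(x, tile_w, tile_h = tile_w) {
  if (x < 1 || x != round(x)) stop("'x' must be a positive integer")
  if (tile_w <= 0 || tile_h <= 0) stop("invalid geometry: tile dims must be positive")
  x <- as.integer(x)
  grid <- expand.grid(col = 0:(x - 1L), row = 0:(x - 1L))[, 2:1]
  origins <- data.frame(row = grid$row, col = grid$col,
                        x0 = grid$col * tile_w, y0 = grid$row * tile_h)
  structure(list(x = x, canvas_w = x * tile_w, canvas_h = x * tile_h,
                 tile_w = tile_w, tile_h = tile_h, origins = origins),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("Mosaic layout: %d x %d tiles of %g x %g px (canvas %g x %g)\n",
              x$x, x$x, x$tile_w, x$tile_h, x$canvas_w, x$canvas_h))
  invisible(x)
}

#' @export
format.mosaic_layout <- function(x, ...) {
  sprintf("mosaic_layout(x = %d, tile = %g x %g)", x$x, x$tile_w, x$tile_h)
}

#' Serialize and restore a mosaic layout
#'
#' Writes/reads the layout as a small YAML document (`x`, canvas and tile
#' dimensions) so a split step can run in a separate process from compose.
#'
#' @param layout a `mosaic_layout`.
#' @param path file path.
#' @export
write_mosaic_layout <- function(layout, path) {
  yaml::write_yaml(list(x = layout$x, canvas_w = layout$canvas_w,
                        canvas_h = layout$canvas_h, tile_w = layout$tile_w,
                        tile_h = layout$tile_h), path)
  invisible(path)
}

#' @rdname write_mosaic_layout
#' @export
read_mosaic_layout <- function(path) {
  y <- yaml::read_yaml(path)
  mosaic_layout(y$x, y$tile_w, y$tile_h)
}

#' Tile containing a point
#'
#' Tiles are half-open in both axes (`[start, start + size)`), so a center
#' exactly on an interior seam belongs to the tile with the larger index
#' (right/bottom neighbour); a point exactly on the canvas's outer edge
#' belongs to the last tile. Points outside the canvas are an error.
#'
#' @param layout a `mosaic_layout`.
#' @param xpix,ypix point coordinates in mosaic-frame pixels (vectorized).
#' @return data frame with 0-based `row`, `col` tile indices.
#' @export
tile_of <- function(layout, xpix, ypix) {
  if (any(xpix < 0 | xpix > layout$canvas_w | ypix < 0 | ypix > layout$canvas_h))
    stop("assignment error: point center lies outside every tile")
  col <- pmin(floor(xpix / layout$tile_w), layout$x - 1L)
  row <- pmin(floor(ypix / layout$tile_h), layout$x - 1L)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Re-express a mosaic-frame pixel box in a tile's normalized frame
#'
#' Subtracts the tile origin and divides by the tile dimensions:
#' `cx = (xc - x0)/tile_w`, `cy = (yc - y0)/tile_h`, `w = w/tile_w`,
#' `h = h/tile_h`. Boxes straddling the tile edge are clipped to the unit
#' square (the straddle rule); the retained-area fraction is reported so
#' callers can drop mostly-out-of-tile boxes.
#'
#' @param boxes pixel-box data frame (`class_id`, `xc`, `yc`, `w`, `h`,
#'   optional `confidence`) in the mosaic frame.
#' @param layout a `mosaic_layout`.
#' @param tile optional length-2 vector `c(row, col)` (0-based). By default
#'   each box is assigned to the tile containing its center ([tile_of()]).
#' @return normalized label frame with extra columns `tile_row`, `tile_col`
#'   and `retained` (clipped area / original area).
#' @export
renormalize_to_tile <- function(boxes, layout, tile = NULL) {
  stopifnot(inherits(layout, "mosaic_layout"))
  if (!nrow(boxes)) {
    out <- empty_labels(confidence = !is.null(boxes$confidence))
    out$tile_row <- integer(); out$tile_col <- integer(); out$retained <- numeric()
    return(out)
  }
  if (is.null(tile)) {
    tl <- tile_of(layout, boxes$xc, boxes$yc)
  } else {
    tl <- data.frame(row = rep(as.integer(tile[1L]), nrow(boxes)),
                     col = rep(as.integer(tile[2L]), nrow(boxes)))
    inside <- boxes$xc >= tl$col * layout$tile_w &
      boxes$xc <= (tl$col + 1) * layout$tile_w &
      boxes$yc >= tl$row * layout$tile_h &
      boxes$yc <= (tl$row + 1) * layout$tile_h
    if (!all(inside)) stop("assignment error: box center outside the requested tile")
  }
  cx <- (boxes$xc - tl$col * layout$tile_w) / layout$tile_w
  cy <- (boxes$yc - tl$row * layout$tile_h) / layout$tile_h
  w <- boxes$w / layout$tile_w
  h <- boxes$h / layout$tile_h
  # clip to the unit square, keeping track of the surviving area fraction
  l <- pmax(0, cx - w / 2); r <- pmin(1, cx + w / 2)
  t <- pmax(0, cy - h / 2); b <- pmin(1, cy + h / 2)
  retained <- pmax(0, r - l) * pmax(0, b - t) / (w * h)
  out <- data.frame(class_id = boxes$class_id,
                    cx = (l + r) / 2, cy = (t + b) / 2,
                    w = pmax(r - l, 0), h = pmax(b - t, 0))
  if (!is.null(boxes$confidence)) out$confidence <- boxes$confidence
  out$tile_row <- tl$row; out$tile_col <- tl$col; out$retained <- retained
  out
}

#' Map a tile's normalized labels into the mosaic frame
#'
#' Exact inverse of [renormalize_to_tile()] for unclipped boxes: the label is
#' denormalized by the tile dimensions, offset by the tile origin, and
#' renormalized by the canvas dimensions.
#'
#' @param labels normalized label frame in the tile's own frame.
#' @param layout a `mosaic_layout`.
#' @param tile length-2 vector `c(row, col)`, 0-based.
#' @return normalized label frame in the mosaic frame.
#' @export
tile_to_mosaic <- function(labels, layout, tile) {
  stopifnot(inherits(layout, "mosaic_layout"))
  row <- as.integer(tile[1L]); col <- as.integer(tile[2L])
  out <- data.frame(class_id = labels$class_id,
                    cx = (col * layout$tile_w + labels$cx * layout$tile_w) / layout$canvas_w,
                    cy = (row * layout$tile_h + labels$cy * layout$tile_h) / layout$canvas_h,
                    w = labels$w * layout$tile_w / layout$canvas_w,
                    h = labels$h * layout$tile_h / layout$canvas_h)
  if (!is.null(labels$confidence)) out$confidence <- labels$confidence
  out
}

#' Compose `x^2` labelled images into one mosaic
#'
#' Pastes the items row-major (item `i*x + j + 1` at tile row `i`, column
#' `j`), resizing any image whose dimensions differ from the first item's to
#' the common tile size, and maps every input label into the mosaic frame.
#' Label count is conserved exactly.
#'
#' @param items list of `x^2` elements, each a list with `image` (matrix or
#'   H x W x 3 array) and `labels` (normalized label frame).
#' @param x tiles per side.
#' @return list with `image` (the mosaic), `labels` (mosaic-frame normalized
#'   labels with a `tile_row`/`tile_col` lineage), and `layout`.
#' @export
compose_mosaic <- function(items, x) {
  x <- as.integer(x)
  if (length(items) != x^2)
    stop(sprintf("need exactly x^2 = %d items, got %d", x^2, length(items)))
  d1 <- dim(items[[1L]]$image)
  tile_h <- d1[1L]; tile_w <- d1[2L]
  channels <- if (length(d1) == 3L) d1[3L] else 1L
  layout <- mosaic_layout(x, tile_w, tile_h)
  canvas <- if (channels == 1L) {
    matrix(0, layout$canvas_h, layout$canvas_w)
  } else {
    array(0, c(layout$canvas_h, layout$canvas_w, channels))
  }
  all_labels <- vector("list", length(items))
  for (i in 0:(x - 1L)) for (j in 0:(x - 1L)) {
    k <- i * x + j + 1L
    img <- items[[k]]$image
    di <- dim(img)
    if ((length(di) == 3L) != (channels > 1L))
      stop("mismatched dims: items mix grayscale and color images")
    if (di[1L] != tile_h || di[2L] != tile_w)
      img <- resize_image(img, tile_h, tile_w)
    rows <- (i * tile_h + 1L):((i + 1L) * tile_h)
    cols <- (j * tile_w + 1L):((j + 1L) * tile_w)
    if (channels == 1L) canvas[rows, cols] <- img
    else canvas[rows, cols, ] <- img
    lab <- items[[k]]$labels
    if (is.null(lab)) lab <- empty_labels()
    ml <- tile_to_mosaic(lab, layout, c(i, j))
    if (nrow(ml)) { ml$tile_row <- i; ml$tile_col <- j }
    else { ml$tile_row <- integer(); ml$tile_col <- integer() }
    all_labels[[k]] <- ml
  }
  list(image = canvas, labels = do.call(rbind, all_labels), layout = layout)
}

#' Split mosaic-frame detections back into per-tile coordinates
#'
#' Each detection is assigned to the tile containing its center, re-expressed
#' in that tile's normalized frame, clipped to the tile, and dropped when the
#' clipped area falls below `retention` times the original area.
#'
#' @param dets data frame of mosaic-frame detections (`class_id`,
#'   `confidence`, `xc`, `yc`, `w`, `h` in mosaic pixels).
#' @param layout a `mosaic_layout`.
#' @param retention minimum surviving area fraction (default 0.1).
#' @return list of length `x^2` (row-major tile order); each element a
#'   normalized label frame with `confidence` for that tile.
#' @export
split_detections <- function(dets, layout, retention = 0.1) {
  stopifnot(inherits(layout, "mosaic_layout"))
  x <- layout$x
  out <- replicate(x^2, {
    e <- empty_labels(confidence = TRUE)
    e
  }, simplify = FALSE)
  names(out) <- sprintf("tile_%d_%d", layout$origins$row, layout$origins$col)
  if (is.null(dets) || !nrow(dets)) return(out)
  if (is.null(dets$confidence)) dets$confidence <- 1
  mapped <- renormalize_to_tile(dets, layout)
  keep <- mapped$retained >= retention & mapped$w > 0 & mapped$h > 0
  mapped <- mapped[keep, , drop = FALSE]
  for (k in seq_len(nrow(mapped))) {
    idx <- mapped$tile_row[k] * x + mapped$tile_col[k] + 1L
    out[[idx]] <- rbind(out[[idx]],
                        mapped[k, c("class_id", "cx", "cy", "w", "h", "confidence")])
  }
  out <- lapply(out, function(df) { rownames(df) <- NULL; df })
  out
}

#' Sample a training mosaic from an image pool
#'
#' Training-time CEAC wrapper: draws `x^2` items at random (with replacement
#' when the pool is smaller than `x^2`) and composes them into one mosaic with
#' remapped labels. Classes may mix freely across tiles.
#'
#' @param pool list of `list(image=, labels=)` items.
#' @param x tiles per side.
#' @return as [compose_mosaic()].
#' @export
ceac_sample_batch <- function(pool, x) {
  idx <- sample.int(length(pool), x^2, replace = length(pool) < x^2)
  compose_mosaic(pool[idx], x)
}
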