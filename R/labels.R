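#' YOLO-convention labels and image helpers
#'
#' Normalized labels follow the YOLO txt convention: one object per row with
#' columns `class_id`, `cx`, `cy`, `w`, `h`, all four coordinates fractions of
#' the image dimensions in \[0, 1\] (`cx`, `cy` the box center). Pixel boxes
#' use columns `xc`, `yc`, `w`, `h` in continuous pixel units with the origin
#' at the top-left corner, x rightward and y downward (no half-pixel offset).
#' Images are numeric matrices (grayscale, `height x width`) or arrays
#' (`height x width x 3`) with values in \[0, 1\].
#'
#' @name yolo-labels
NULL

empty_labels <- function(confidence = FALSE) {
  df <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                   w = numeric(), h = numeric())
  if (confidence) df$confidence <- numeric()
  df
}

#' Validate normalized labels
#'
#' Checks the label-frame contract: integer class ids >= 0, all coordinates in
#' \[0, 1\], positive width/height, and the box contained in the unit square
#' within `tol` (`cx +- w/2` and `cy +- h/2` inside \[0, 1\]).
#'
#' @param labels a label data frame.
#' @param tol containment tolerance (default 1e-6).
#' @return the labels, invisibly; errors describe the first violation.
#' @export
validate_labels <- function(labels, tol = 1e-6) {
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!all(need %in% names(labels)))
    stop("labels need columns: ", paste(need, collapse = ", "))
  if (!nrow(labels)) return(invisible(labels))
  if (any(labels$class_id < 0) || any(labels$class_id != round(labels$class_id)))
    stop("class_id must be a non-negative integer")
  co <- as.matrix(labels[, c("cx", "cy", "w", "h")])
  if (any(co < -tol) || any(co > 1 + tol))
    stop("label coordinates must lie in [0, 1]")
  if (any(labels$w <= 0) || any(labels$h <= 0))
    stop("label width and height must be positive")
  if (any(labels$cx - labels$w / 2 < -tol) || any(labels$cx + labels$w / 2 > 1 + tol) ||
      any(labels$cy - labels$h / 2 < -tol) || any(labels$cy + labels$h / 2 > 1 + tol))
    stop("box extends outside the unit square beyond tolerance")
  invisible(labels)
}

#' Read and write YOLO label txt files
#'
#' One `class cx cy w h` row per object, space-separated, coordinates
#' normalized to \[0, 1\]. Prediction files may carry a sixth `confidence`
#' column, which is preserved. A missing or empty file reads as zero labels.
#'
#' @param path file path.
#' @return `read_yolo_labels`: a label data frame.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(empty_labels())
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!ncol(m) %in% c(5L, 6L))
    stop("YOLO label rows must have 5 (or 6, with confidence) fields: ", path)
  df <- data.frame(class_id = as.integer(m[, 1L]), cx = m[, 2L], cy = m[, 3L],
                   w = m[, 4L], h = m[, 5L])
  if (ncol(m) == 6L) df$confidence <- m[, 6L]
  df
}

#' @rdname read_yolo_labels
#' @param labels label data frame, optionally with a `confidence` column.
#' @return `write_yolo_labels`: `path`, invisibly.
#' @export
write_yolo_labels <- function(labels, path) {
  cols <- c("class_id", "cx", "cy", "w", "h")
  if (!is.null(labels$confidence)) cols <- c(cols, "confidence")
  if (!nrow(labels)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- apply(labels[, cols, drop = FALSE], 1L, function(r) {
    paste(c(format(as.integer(r[[1L]])),
            formatC(as.numeric(r[-1L]), format = "g", digits = 12)),
          collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalized labels to pixel boxes and back
#'
#' `denormalize_labels` scales a normalized label frame by the canvas
#' dimensions: `xc = cx * width`, `yc = cy * height`, `w_px = w * width`,
#' `h_px = h * height`. `normalize_labels` is the exact inverse.
#'
#' @param labels normalized label frame (see [yolo-labels]).
#' @param width,height canvas dimensions in pixels; must be positive.
#' @return data frame of pixel boxes (`class_id`, `xc`, `yc`, `w`, `h`, plus
#'   `confidence` when present), or normalized labels for the inverse.
#' @export
denormalize_labels <- function(labels, width, height) {
  if (width <= 0 || height <= 0)
    stop("invalid geometry: canvas dimensions must be positive")
  out <- data.frame(class_id = labels$class_id,
                    xc = labels$cx * width, yc = labels$cy * height,
                    w = labels$w * width, h = labels$h * height)
  if (!is.null(labels$confidence)) out$confidence <- labels$confidence
  out
}

#' @rdname denormalize_labels
#' @param boxes pixel-box data frame with `xc`, `yc`, `w`, `h`.
#' @export
normalize_labels <- function(boxes, width, height) {
  if (width <= 0 || height <= 0)
    stop("invalid geometry: canvas dimensions must be positive")
  out <- data.frame(class_id = boxes$class_id,
                    cx = boxes$xc / width, cy = boxes$yc / height,
                    w = boxes$w / width, h = boxes$h / height)
  if (!is.null(boxes$confidence)) out$confidence <- boxes$confidence
  out
}

#' Read and write images as numeric arrays
#'
#' Thin wrappers over PNG I/O. Grayscale files load as `height x width`
#' matrices, color files as `height x width x 3` arrays, values in \[0, 1\].
#'
#' @param path PNG file path.
#' @return `load_image`: the image array.
#' @export
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3L) {
    img[, , 1L]
  } else img
}

#' @rdname load_image
#' @param image numeric matrix or array with values in \[0, 1\].
#' @export
save_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# Nearest-neighbour resize of a grayscale matrix or H x W x C array.
resize_image <- function(image, height, width) {
  d <- dim(image)
  rows <- pmin(d[1L], floor(seq_len(height) * d[1L] / height - d[1L] / (2 * height)) + 1L)
  cols <- pmin(d[2L], floor(seq_len(width) * d[2L] / width - d[2L] / (2 * width)) + 1L)
  rows <- pmax(rows, 1L); cols <- pmax(cols, 1L)
  if (length(d) == 2L) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}
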