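# Shared fixtures: tiny labelled images and random in-tile label frames.

random_labels <- function(n, margin = 0.02) {
  w <- runif(n, 0.05, 0.3)
  h <- runif(n, 0.05, 0.3)
  cx <- runif(n, w / 2 + margin, 1 - w / 2 - margin)
  cy <- runif(n, h / 2 + margin, 1 - h / 2 - margin)
  data.frame(class_id = sample(0:3, n, replace = TRUE),
             cx = cx, cy = cy, w = w, h = h)
}

tiny_item <- function(side = 64, n_labels = 2) {
  list(image = matrix(runif(side * side), side, side),
       labels = random_labels(n_labels))
}

# Brute-force IoU of two center-format boxes by rasterizing on a regular
# grid over their joint extent (independent of the analytic implementation).
raster_iou <- function(a, b, cells = 512L) {
  lo_x <- min(a[1] - a[3] / 2, b[1] - b[3] / 2)
  hi_x <- max(a[1] + a[3] / 2, b[1] + b[3] / 2)
  lo_y <- min(a[2] - a[4] / 2, b[2] - b[4] / 2)
  hi_y <- max(a[2] + a[4] / 2, b[2] + b[4] / 2)
  xs <- seq(lo_x, hi_x, length.out = cells)
  ys <- seq(lo_y, hi_y, length.out = cells)
  in_box <- function(box, X, Y)
    X >= box[1] - box[3] / 2 & X <= box[1] + box[3] / 2 &
    Y >= box[2] - box[4] / 2 & Y <= box[2] + box[4] / 2
  X <- matrix(xs, cells, cells)
  Y <- matrix(ys, cells, cells, byrow = TRUE)
  ia <- in_box(a, X, Y); ib <- in_box(b, X, Y)
  sum(ia & ib) / sum(ia | ib)
}

# Riemann-sum oracle for the area under the interpolated PR envelope.
riemann_ap <- function(curve, step = 1e-4) {
  grid <- seq(0, 1 - step, by = step) + step / 2
  p_at <- vapply(grid, function(r) {
    ok <- curve$recall >= r
    if (!any(ok)) 0 else max(curve$precision[ok])
  }, numeric(1))
  max_r <- max(curve$recall)
  mean(p_at[grid <= max_r]) * max_r
}
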