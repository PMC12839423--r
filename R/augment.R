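#' Augmentation suite for Fv/Fm scenes
#'
#' Photometric operations (HSV perturbation of a pseudo-color rendering,
#' mean/Gaussian/median blur, CutOut occlusion, random brightness) leave the
#' labels untouched; the only geometric operation, a D4 dihedral-group
#' transform, remaps the labels by the corresponding symmetry of the unit
#' square and is exactly invertible.
#'
#' @name augmentation
NULL

#' Construct an augmentation operation
#'
#' @param kind one of `"hsv"`, `"mean_blur"`, `"gaussian_blur"`,
#'   `"median_blur"`, `"cutout"`, `"d4"`, `"brightness"`.
#' @param ... kind-specific parameters: `hsv` takes jitter gains `h`, `s`,
#'   `v` (defaults 0.015, 0.4, 0.3); blurs take `ksize` (odd window, default
#'   3) or `sigma` (Gaussian, default 1); `cutout` takes `n_patches` (1-6) and
#'   `area_frac` (total occluded fraction, 0.05-0.40); `d4` takes `element`
#'   (0-7); `brightness` takes `gain`.
#' @return object of class `augment_op`.
#' @export
augment_op <- function(kind = c("hsv", "mean_blur", "gaussian_blur",
                                "median_blur", "cutout", "d4", "brightness"),
                       ...) {
  kind <- match.arg(kind)
  p <- list(...)
  defaults <- switch(kind,
    hsv = list(h = 0.015, s = 0.4, v = 0.3),
    mean_blur = list(ksize = 3L),
    gaussian_blur = list(sigma = 1),
    median_blur = list(ksize = 3L),
    cutout = list(n_patches = 3L, area_frac = 0.2),
    d4 = list(element = 1L),
    brightness = list(gain = 1.2))
  p <- utils::modifyList(defaults, p)
  if (kind == "cutout") {
    if (p$n_patches < 1 || p$n_patches > 6)
      stop("cutout patch count must be in 1..6")
    if (p$area_frac < 0.05 || p$area_frac > 0.40)
      stop("cutout total area fraction must be in [0.05, 0.40]")
  }
  if (kind == "d4" && !(p$element %in% 0:7))
    stop("d4 element must be one of 0..7")
  if (kind %in% c("mean_blur", "median_blur") && p$ksize %% 2 != 1)
    stop("blur window must be odd")
  structure(list(kind = kind, params = p), class = "augment_op")
}

#' @export
print.augment_op <- function(x, ...) {
  cat(sprintf("augment_op(%s): %s\n", x$kind,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Sample a random augmentation operation
#'
#' Draws one of the seven kinds uniformly with parameters inside the suite's
#' printed ranges (1-6 CutOut patches totalling 5-40% of the image, one of
#' the 8 D4 group elements, small photometric jitters).
#'
#' @return an `augment_op`.
#' @export
random_augment_op <- function() {
  kind <- sample(c("hsv", "mean_blur", "gaussian_blur", "median_blur",
                   "cutout", "d4", "brightness"), 1L)
  switch(kind,
    hsv = augment_op("hsv", h = runif(1, 0.005, 0.03), s = runif(1, 0.2, 0.6),
                     v = runif(1, 0.1, 0.4)),
    mean_blur = augment_op("mean_blur", ksize = sample(c(3L, 5L), 1L)),
    gaussian_blur = augment_op("gaussian_blur", sigma = runif(1, 0.5, 2)),
    median_blur = augment_op("median_blur", ksize = 3L),
    cutout = augment_op("cutout", n_patches = sample(1:6, 1L),
                        area_frac = runif(1, 0.05, 0.40)),
    d4 = augment_op("d4", element = sample(0:7, 1L)),
    brightness = augment_op("brightness", gain = runif(1, 0.7, 1.3)))
}

# ---- D4 dihedral group -------------------------------------------------

# Element encoding: e = r + 4*f with r quarter-turns clockwise applied AFTER
# an optional horizontal mirror f. Elements with f = 1 are reflections and
# self-inverse; pure rotations invert to the complementary rotation.

rot90cw_mat <- function(m) {
  if (length(dim(m)) == 3L) {
    out <- array(0, c(dim(m)[2L], dim(m)[1L], dim(m)[3L]))
    for (c in seq_len(dim(m)[3L])) out[, , c] <- t(m[nrow(m):1, , c])
    out
  } else t(m[nrow(m):1, , drop = FALSE])
}

fliph_mat <- function(m) {
  if (length(dim(m)) == 3L) m[, dim(m)[2L]:1, , drop = FALSE]
  else m[, ncol(m):1, drop = FALSE]
}

d4_labels <- function(labels, element) {
  f <- element %/% 4L; r <- element %% 4L
  cx <- labels$cx; cy <- labels$cy; w <- labels$w; h <- labels$h
  if (f == 1L) cx <- 1 - cx
  if (r > 0) for (i in seq_len(r)) {
    tmp <- cx; cx <- 1 - cy; cy <- tmp
    tw <- w; w <- h; h <- tw
  }
  out <- labels
  out$cx <- cx; out$cy <- cy; out$w <- w; out$h <- h
  out
}

#' Apply a D4 symmetry to a square image and its labels
#'
#' @param image square matrix or H x W x C array.
#' @param labels normalized label frame.
#' @param element group element 0-7 (`r + 4*f`: `r` clockwise quarter-turns
#'   applied after `f` in 0/1 horizontal mirrors).
#' @return list with transformed `image` and `labels`.
#' @export
d4_apply <- function(image, labels, element) {
  stopifnot(element %in% 0:7)
  d <- dim(image)
  if (d[1L] != d[2L]) stop("D4 transforms require a square image")
  f <- element %/% 4L; r <- element %% 4L
  if (f == 1L) image <- fliph_mat(image)
  if (r > 0) for (i in seq_len(r)) image <- rot90cw_mat(image)
  list(image = image, labels = d4_labels(labels, element))
}

#' Inverse of a D4 group element
#' @param element group element 0-7.
#' @return the element whose application undoes `element`.
#' @export
d4_inverse <- function(element) {
  stopifnot(element %in% 0:7)
  f <- element %/% 4L; r <- element %% 4L
  if (f == 1L) element else (4L - r) %% 4L
}

# ---- photometric operations -------------------------------------------

pad_replicate <- function(m, p) {
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

conv2_same <- function(m, kernel) {
  k <- nrow(kernel); p <- (k - 1L) %/% 2L
  mp <- pad_replicate(m, p)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (kernel[i, j] == 0) next
    out <- out + kernel[i, j] * mp[(i - 1L) + seq_len(nrow(m)),
                                   (j - 1L) + seq_len(ncol(m)), drop = FALSE]
  }
  out
}

gaussian_kernel <- function(sigma) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  ax <- seq_len(k) - (k + 1L) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  ker <- outer(g, g)
  ker / sum(ker)
}

median_filter <- function(m, k) {
  p <- (k - 1L) %/% 2L
  mp <- pad_replicate(m, p)
  n <- nrow(m) * ncol(m)
  stack <- matrix(0, n, k * k)
  idx <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    stack[, idx] <- as.vector(mp[(i - 1L) + seq_len(nrow(m)),
                                 (j - 1L) + seq_len(ncol(m)), drop = FALSE])
    idx <- idx + 1L
  }
  # row-wise median of a small fixed-width matrix via partial sort
  med <- apply(stack, 1L, stats::median.default)
  matrix(med, nrow(m), ncol(m))
}

# Minimal HSV <-> RGB arithmetic (vectorized over pixels); h, s, v in [0, 1].
rgb_to_hsv_arr <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  im <- nz & mx == r
  h[im] <- ((g[im] - b[im]) / d[im]) %% 6
  im <- nz & mx == g & mx != r
  h[im] <- (b[im] - r[im]) / d[im] + 2
  im <- nz & mx == b & mx != r & mx != g
  h[im] <- (r[im] - g[im]) / d[im] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

hsv_to_rgb_arr <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# HSV jitter for single-channel Fv/Fm maps: render to a false-color ramp
# (blue = low Fv/Fm, red = high, the usual fluorescence display), jitter in
# HSV, convert back to gray via luminance.
hsv_perturb_gray <- function(m, dh, ds, dv) {
  g <- as.vector(m)
  hue <- (1 - g) * 2 / 3                 # 0 (red) .. 2/3 (blue)
  rgb <- hsv_to_rgb_arr(hue, rep(1, length(g)), pmax(g, 0.05))
  hsv <- rgb_to_hsv_arr(rgb$r, rgb$g, rgb$b)
  h2 <- (hsv$h + stats::runif(1, -dh, dh)) %% 1
  s2 <- pmin(pmax(hsv$s * (1 + stats::runif(1, -ds, ds)), 0), 1)
  v2 <- pmin(pmax(hsv$v * (1 + stats::runif(1, -dv, dv)), 0), 1)
  rgb2 <- hsv_to_rgb_arr(h2, s2, v2)
  lum <- 0.299 * rgb2$r + 0.587 * rgb2$g + 0.114 * rgb2$b
  matrix(pmin(pmax(lum, 0), 1), nrow(m), ncol(m))
}

# CutOut: n disjoint rectangular occluders whose total pixel count equals
# round(area_frac * H * W) exactly. Patches live in distinct cells of a
# ceiling(sqrt(n))^2 grid, which keeps them disjoint; each patch is an
# integer rectangle plus at most one partial column to hit its pixel budget.
cutout_mask <- function(side_h, side_w, n_patches, area_frac) {
  g <- as.integer(ceiling(sqrt(n_patches)))
  cells <- sample.int(g * g, n_patches)
  cell_h <- side_h %/% g; cell_w <- side_w %/% g
  total_px <- round(area_frac * side_h * side_w)
  mask <- matrix(FALSE, side_h, side_w)
  remaining <- total_px
  for (k in seq_len(n_patches)) {
    budget <- round(remaining / (n_patches - k + 1L))
    budget <- min(budget, cell_h * cell_w)
    c <- cells[k]
    crow <- (c - 1L) %/% g; ccol <- (c - 1L) %% g
    if (budget <= 0L) next
    aspect <- stats::runif(1, 0.5, 2)
    # tall enough that the patch never overflows its cell horizontally
    ph <- max(as.integer(ceiling(budget / cell_w)),
              max(1L, min(cell_h, as.integer(round(sqrt(budget / aspect))))))
    pw_full <- budget %/% ph
    part <- budget - ph * pw_full          # pixels in the partial column
    width <- pw_full + (part > 0L)
    y0 <- crow * cell_h + sample.int(cell_h - ph + 1L, 1L) - 1L
    x0 <- ccol * cell_w + sample.int(max(1L, cell_w - width + 1L), 1L) - 1L
    if (pw_full > 0L)
      mask[(y0 + 1L):(y0 + ph), (x0 + 1L):(x0 + pw_full)] <- TRUE
    if (part > 0L)
      mask[(y0 + 1L):(y0 + part), x0 + pw_full + 1L] <- TRUE
    remaining <- remaining - budget
  }
  mask
}

#' Apply an augmentation operation
#'
#' Photometric kinds return the labels byte-identical; `d4` remaps them via
#' [d4_apply()]. Randomized kinds (`hsv` jitter draw, `cutout` placement,
#' `brightness` when `gain` is missing) consume the current RNG stream, so
#' wrap calls in `set.seed()` for reproducibility.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param labels normalized label frame.
#' @param op an [augment_op()].
#' @return list with `image` and `labels`.
#' @export
augment <- function(image, labels, op) {
  stopifnot(inherits(op, "augment_op"))
  p <- op$params
  out_labels <- labels
  img <- switch(op$kind,
    hsv = hsv_perturb_gray(image, p$h, p$s, p$v),
    mean_blur = conv2_same(image, matrix(1 / p$ksize^2, p$ksize, p$ksize)),
    gaussian_blur = conv2_same(image, gaussian_kernel(p$sigma)),
    median_blur = median_filter(image, p$ksize),
    cutout = {
      m <- cutout_mask(nrow(image), ncol(image), p$n_patches, p$area_frac)
      image[m] <- 0
      image
    },
    d4 = {
      res <- d4_apply(image, labels, p$element)
      out_labels <- res$labels
      res$image
    },
    brightness = pmin(pmax(image * p$gain, 0), 1))
  list(image = img, labels = out_labels)
}
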