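#' Drought grading and synthetic Fv/Fm scene generation
#'
#' Stand-in data for drought-stress detection on chlorophyll-fluorescence
#' imagery: four-level drought grades defined by soil relative humidity
#' intervals, grayscale scenes of elliptical leaf blobs whose Fv/Fm-like
#' interior intensity declines with drought severity, the photometric and
#' geometric augmentation suite, and a split-then-augment dataset builder
#' with a lineage manifest.
#'
#' @name datagen
NULL

grade_table <- function() {
  data.frame(
    severity = c("No Drought", "Mild Drought", "Moderate Drought", "Severe Drought"),
    level = 1:4,
    w_low = c(60, 50, 40, 30),
    w_high = c(100, 60, 50, 40)
  )
}

#' Drought grade from soil relative humidity
#'
#' Interval lookup with closed lower bounds: `W >= 60` is level 1 (No
#' Drought), `50 <= W < 60` level 2 (Mild), `40 <= W < 50` level 3
#' (Moderate), `30 <= W < 40` level 4 (Severe). Humidity below 30% is outside
#' the grading scale and raises an error rather than being clamped to the
#' severest grade.
#'
#' @param W soil relative humidity in percent, in \[0, 100\] (vectorized).
#' @return data frame with `severity`, `level` (1-4) and `class_id`
#'   (`level - 1`, the label-file class).
#' @examples
#' grade_from_humidity(c(65, 55, 40))
#' @export
grade_from_humidity <- function(W) {
  if (any(!is.finite(W)) || any(W < 0) || any(W > 100))
    stop("soil relative humidity must lie in [0, 100] percent")
  if (any(W < 30))
    stop("out of scale: the grading is defined for W >= 30%")
  tab <- grade_table()
  level <- ifelse(W >= 60, 1L, ifelse(W >= 50, 2L, ifelse(W >= 40, 3L, 4L)))
  data.frame(severity = tab$severity[level], level = level,
             class_id = level - 1L)
}

#' Drought grade class names in class-id order
#' @return character vector of length 4 (class ids 0-3).
#' @export
grade_class_names <- function() {
  c("no_drought", "mild_drought", "moderate_drought", "severe_drought")
}

#' Synthetic scene specification
#'
#' Parameters of the scene generator. `grade_means` are the per-level mean
#' foreground Fv/Fm intensities (levels 1-4); healthy tissue sits near 0.8
#' and the means decrease strictly with severity.
#'
#' @param side image side in pixels (default 640).
#' @param n_leaves integer range (min, max) of leaf blobs per scene.
#' @param grade_means length-4 decreasing vector of mean Fv/Fm intensities.
#' @param grade_sd intensity spread around the grade mean.
#' @param background background level in \[0, 1\].
#' @param noise_sd additive pixel noise standard deviation.
#' @param leaf_axis_frac range of ellipse semi-axes as a fraction of `side`.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(side = 640L, n_leaves = c(3L, 8L),
                       grade_means = c(0.80, 0.68, 0.55, 0.40),
                       grade_sd = 0.04, background = 0.06, noise_sd = 0.015,
                       leaf_axis_frac = c(0.04, 0.12)) {
  stopifnot(side >= 32, length(grade_means) == 4L,
            all(diff(grade_means) < 0), all(grade_means > 0 & grade_means < 1))
  structure(list(side = as.integer(side), n_leaves = as.integer(n_leaves),
                 grade_means = grade_means, grade_sd = grade_sd,
                 background = background, noise_sd = noise_sd,
                 leaf_axis_frac = leaf_axis_frac),
            class = "scene_spec")
}

# Sample scene geometry (leaf ellipses + tight YOLO boxes) without rendering.
# Ellipses are kept fully inside the image so every label satisfies the
# normalized-label invariants.
sample_scene_geometry <- function(spec, level) {
  side <- spec$side
  n <- sample(spec$n_leaves[1L]:spec$n_leaves[2L], 1L)
  a <- runif(n, spec$leaf_axis_frac[1L], spec$leaf_axis_frac[2L]) * side
  b <- a * runif(n, 0.45, 0.9)   # leaves are elongated
  theta <- runif(n, 0, pi)
  # tight half-extents of a rotated ellipse
  dx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  dy <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  cx <- runif(n, dx + 1, side - dx - 1)
  cy <- runif(n, dy + 1, side - dy - 1)
  intensity <- pmin(pmax(rnorm(n, spec$grade_means[level], spec$grade_sd),
                         0.02), 0.98)
  leaves <- data.frame(cx = cx, cy = cy, a = a, b = b, theta = theta,
                       dx = dx, dy = dy, intensity = intensity)
  labels <- data.frame(class_id = rep(level - 1L, n),
                       cx = cx / side, cy = cy / side,
                       w = 2 * dx / side, h = 2 * dy / side)
  list(leaves = leaves, labels = labels)
}

render_scene <- function(spec, leaves) {
  side <- spec$side
  img <- matrix(spec$background, side, side)
  for (k in seq_len(nrow(leaves))) {
    lf <- leaves[k, ]
    rows <- max(1L, floor(lf$cy - lf$dy)):min(side, ceiling(lf$cy + lf$dy))
    cols <- max(1L, floor(lf$cx - lf$dx)):min(side, ceiling(lf$cx + lf$dx))
    # pixel centers at (col - 0.5, row - 0.5)
    px <- outer(rep(1, length(rows)), cols - 0.5) - lf$cx
    py <- outer(rows - 0.5, rep(1, length(cols))) - lf$cy
    u <- (px * cos(lf$theta) + py * sin(lf$theta)) / lf$a
    v <- (-px * sin(lf$theta) + py * cos(lf$theta)) / lf$b
    inside <- u^2 + v^2 <= 1
    patch <- img[rows, cols]
    # slight radial falloff mimics vein/edge attenuation in Fv/Fm maps
    shade <- lf$intensity * (1 - 0.15 * (u^2 + v^2))
    patch[inside] <- pmax(patch[inside], shade[inside])
    img[rows, cols] <- patch
  }
  img <- img + matrix(stats::rnorm(side^2, 0, spec$noise_sd), side, side)
  pmin(pmax(img, 0), 1)
}

#' Generate one synthetic Fv/Fm drought scene
#'
#' Draws a set of elliptical leaf blobs with interior intensity around the
#' grade's mean Fv/Fm value on a dark background, plus tight normalized boxes
#' labelled with the grade's class id. Fully reproducible per seed.
#'
#' @param spec a [scene_spec()].
#' @param level drought level 1-4 (or a data frame from
#'   [grade_from_humidity()]).
#' @param seed integer seed for this scene.
#' @return list with `image` (side x side matrix in \[0, 1\]) and `labels`
#'   (normalized label frame).
#' @export
generate_scene <- function(spec = scene_spec(), level = 1L, seed = 1L) {
  if (is.data.frame(level)) level <- level$level[1L]
  stopifnot(level %in% 1:4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  geom <- sample_scene_geometry(spec, level)
  img <- render_scene(spec, geom$leaves)
  list(image = img, labels = geom$labels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
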