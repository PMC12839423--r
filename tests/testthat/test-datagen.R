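test_that("drought grading follows the humidity intervals with closed lower bounds", {
  g <- grade_from_humidity(c(65, 55, 45, 35))
  expect_equal(g$level, 1:4)
  expect_equal(g$severity, c("No Drought", "Mild Drought",
                             "Moderate Drought", "Severe Drought"))
  expect_equal(g$class_id, 0:3)
  # boundaries are inclusive below
  expect_equal(grade_from_humidity(60)$level, 1L)
  expect_equal(grade_from_humidity(50)$level, 2L)
  expect_equal(grade_from_humidity(40)$level, 3L)
  expect_equal(grade_from_humidity(30)$level, 4L)
  expect_error(grade_from_humidity(25), "out of scale")
  expect_error(grade_from_humidity(105), "\\[0, 100\\]")
})

test_that("scene generation is seed-deterministic with valid labels", {
  spec <- scene_spec(side = 96)
  s1 <- generate_scene(spec, level = 2, seed = 99)
  s2 <- generate_scene(spec, level = 2, seed = 99)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  expect_equal(dim(s1$image), c(96, 96))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_silent(validate_labels(s1$labels))
  expect_true(all(s1$labels$class_id == 1L))
  s3 <- generate_scene(spec, level = 2, seed = 100)
  expect_false(identical(s1$image, s3$image))
})

test_that("foreground intensity decreases with drought level in expectation", {
  spec <- scene_spec(side = 64)
  mean_fg <- function(level) {
    vals <- vapply(1:100, function(s) {
      sc <- generate_scene(spec, level, seed = 1000 + s)
      mean(sc$image[sc$image > 2 * spec$background])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  m <- vapply(1:4, mean_fg, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("D4 transforms form a group: inverses round-trip image and labels", {
  set.seed(6)
  img <- matrix(runif(16 * 16), 16, 16)
  labs <- random_labels(4)
  for (el in 0:7) {
    fwd <- d4_apply(img, labs, el)
    back <- d4_apply(fwd$image, fwd$labels, d4_inverse(el))
    expect_identical(back$image, img)
    expect_equal(back$labels$cx, labs$cx, tolerance = 1e-12)
    expect_equal(back$labels$cy, labs$cy, tolerance = 1e-12)
    expect_equal(back$labels$w, labs$w, tolerance = 1e-12)
    # D4 is area preserving
    expect_equal(fwd$labels$w * fwd$labels$h, labs$w * labs$h,
                 tolerance = 1e-12)
  }
  # the half-turn is the double reflection: (cx, cy) -> (1-cx, 1-cy)
  rot180 <- d4_apply(img, labs, 2L)
  expect_equal(rot180$labels$cx, 1 - labs$cx)
  expect_equal(rot180$labels$cy, 1 - labs$cy)
  expect_equal(rot180$labels$w, labs$w)
})

test_that("photometric augmentations leave labels untouched", {
  set.seed(8)
  img <- matrix(runif(48 * 48), 48, 48)
  labs <- random_labels(3)
  for (kind in c("hsv", "mean_blur", "gaussian_blur", "median_blur",
                 "cutout", "brightness")) {
    out <- augment(img, labs, augment_op(kind))
    expect_identical(out$labels, labs)
    expect_equal(dim(out$image), dim(img))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("cutout occludes the requested area within the printed ranges", {
  set.seed(10)
  img <- matrix(1, 120, 120)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    frac <- runif(1, 0.05, 0.40)
    out <- augment(img, random_labels(1), augment_op("cutout", n_patches = n,
                                                     area_frac = frac))
    occluded <- mean(out$image == 0)
    expect_equal(occluded, frac, tolerance = 1e-3)
    expect_true(occluded >= 0.05 - 1e-3 && occluded <= 0.40 + 1e-3)
  }
  expect_error(augment_op("cutout", n_patches = 7), "1..6")
  expect_error(augment_op("cutout", area_frac = 0.45), "0.05")
})

test_that("blurs smooth the image without changing its scale", {
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  out <- augment(img, random_labels(1), augment_op("mean_blur", ksize = 3))$image
  expect_equal(out[11, 11], 1 / 9, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  g <- augment(img, random_labels(1), augment_op("gaussian_blur", sigma = 1))$image
  expect_equal(sum(g), 1, tolerance = 1e-6)
  expect_true(g[11, 11] > g[10, 11])
  med <- augment(img, random_labels(1), augment_op("median_blur"))$image
  expect_equal(max(med), 0)          # an isolated pixel is removed
})

test_that("build_dataset reproduces the published split-then-augment counts", {
  dir <- tempfile("ds")
  ds <- build_dataset(dir, n_originals = 324, val_frac = 0.2,
                      train_test_ratio = c(8, 2), per_image_variants = 12,
                      seed = 7, spec = scene_spec(side = 64))
  expect_equal(unname(ds$counts["train"]), 2691)
  expect_equal(unname(ds$counts["test"]), 676)
  expect_equal(unname(ds$counts["val"]), 845)
  expect_equal(unname(ds$counts["total"]), 4212)
  expect_silent(check_leakage_free(ds$manifest))
  # count law per split: (1 + variants) x raw split size
  raw <- table(ds$manifest$split[ds$manifest$variant == 0])
  expect_equal(unname(ds$counts[c("train", "test", "val")]),
               as.integer(13 * raw[c("train", "test", "val")]))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "dataset.yaml")))
  # every augmented file's source lies in its own split
  by_src <- split(ds$manifest$split, ds$manifest$source_id)
  expect_true(all(vapply(by_src, function(s) length(unique(s)) == 1,
                         logical(1))))
})

test_that("zero variants reduce to the raw split sizes 207/52/65", {
  ds <- build_dataset(tempfile("ds0"), n_originals = 324,
                      per_image_variants = 0, seed = 1,
                      spec = scene_spec(side = 64))
  expect_equal(unname(ds$counts[c("train", "test", "val")]), c(207, 52, 65))
})

test_that("a materialized dataset writes matching images and labels", {
  dir <- tempfile("dsm")
  ds <- build_dataset(dir, n_originals = 6, val_frac = 0.34,
                      per_image_variants = 1, seed = 3,
                      spec = scene_spec(side = 48), materialize = TRUE)
  imgs <- list.files(file.path(dir, "images"), recursive = TRUE)
  labs <- list.files(file.path(dir, "labels"), recursive = TRUE)
  expect_equal(length(imgs), nrow(ds$manifest))
  expect_equal(length(labs), nrow(ds$manifest))
  one <- file.path(dir, "images", ds$manifest$split[1], ds$manifest$file[1])
  img <- load_image(one)
  expect_equal(dim(img)[1:2], c(48, 48))
})
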