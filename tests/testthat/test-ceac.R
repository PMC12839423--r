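test_that("denormalize/normalize scale by canvas dims and round-trip", {
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  px <- denormalize_labels(lab, 1920, 1920)
  expect_equal(unlist(px[1, c("xc", "yc", "w", "h")], use.names = FALSE),
               c(960, 960, 960, 960))
  lab2 <- data.frame(class_id = 1L, cx = 0, cy = 0, w = 0.1, h = 0.1)
  px2 <- denormalize_labels(lab2, 100, 200)
  expect_equal(unlist(px2[1, c("xc", "yc", "w", "h")], use.names = FALSE),
               c(0, 0, 10, 20))
  expect_error(denormalize_labels(lab, -5, 100), "invalid geometry")
  # round trip over 1000 random draws
  set.seed(1)
  labs <- random_labels(1000)
  w <- 1713; h <- 941
  back <- normalize_labels(denormalize_labels(labs, w, h), w, h)
  expect_equal(back$cx, labs$cx, tolerance = 1e-9)
  expect_equal(back$cy, labs$cy, tolerance = 1e-9)
  expect_equal(back$w, labs$w, tolerance = 1e-9)
  expect_equal(back$h, labs$h, tolerance = 1e-9)
})

test_that("YOLO label txt files round-trip including confidence", {
  labs <- random_labels(5)
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(labs, f)
  back <- read_yolo_labels(f)
  expect_equal(back, labs, tolerance = 1e-10)
  labs$confidence <- runif(5)
  write_yolo_labels(labs, f)
  expect_equal(read_yolo_labels(f)$confidence, labs$confidence,
               tolerance = 1e-10)
  write_yolo_labels(labs[0, ], f)
  expect_equal(nrow(read_yolo_labels(f)), 0)
})

test_that("mosaic layout obeys the grid law and serializes", {
  for (x in 1:4) {
    ly <- mosaic_layout(x, 640)
    expect_equal(nrow(ly$origins), x^2)
    expect_equal(ly$canvas_w, x * 640)
    expect_equal(ly$origins$x0, ly$origins$col * 640)
    expect_equal(ly$origins$y0, ly$origins$row * 640)
  }
  f <- tempfile(fileext = ".yaml")
  write_mosaic_layout(mosaic_layout(3, 640, 480), f)
  ly2 <- read_mosaic_layout(f)
  expect_equal(ly2$x, 3L)
  expect_equal(ly2$tile_h, 480)
})

test_that("renormalize_to_tile matches the hand-worked substitution", {
  ly <- mosaic_layout(3, 640)           # canvas 1920
  box <- data.frame(class_id = 0L, xc = 960, yc = 960, w = 100, h = 100)
  out <- renormalize_to_tile(box, ly)
  expect_equal(out$tile_row, 1L)
  expect_equal(out$tile_col, 1L)
  expect_equal(out$cx, 0.5)
  expect_equal(out$cy, 0.5)
  expect_equal(out$w, 100 / 640)
  expect_equal(out$h, 100 / 640)
  # degenerate grid: x = 1 reduces to plain normalization
  ly1 <- mosaic_layout(1, 640)
  box2 <- data.frame(class_id = 0L, xc = 100, yc = 300, w = 50, h = 80)
  out1 <- renormalize_to_tile(box2, ly1)
  ref <- normalize_labels(box2, 640, 640)
  expect_equal(out1$cx, ref$cx)
  expect_equal(out1$w, ref$w)
})

test_that("seam centers go to the larger-index tile and clipping is bounded", {
  ly <- mosaic_layout(3, 100)
  # exhaustive sweep across both interior seams and the canvas edges
  for (seam in c(0, 100, 200, 300)) {
    tl <- tile_of(ly, xpix = seam, ypix = 50)
    expect_equal(tl$col, min(seam %/% 100, 2))
    tl <- tile_of(ly, xpix = 50, ypix = seam)
    expect_equal(tl$row, min(seam %/% 100, 2))
  }
  expect_error(tile_of(ly, 301, 50), "outside")
  # a straddling box is clipped into the unit square of its assigned tile
  box <- data.frame(class_id = 0L, xc = 100, yc = 50, w = 40, h = 20)
  out <- renormalize_to_tile(box, ly)
  expect_equal(out$tile_col, 1L)
  expect_true(out$cx - out$w / 2 >= -1e-12)
  expect_true(out$cx + out$w / 2 <= 1 + 1e-12)
  expect_true(out$w <= 1)
  expect_equal(out$retained, 0.5)     # half the box lies in the seam tile
})

test_that("compose_mosaic pastes row-major, conserves labels, errors on bad input", {
  set.seed(2)
  items <- lapply(1:9, function(i) tiny_item(32))
  mos <- compose_mosaic(items, 3)
  expect_equal(dim(mos$image), c(96, 96))
  expect_equal(nrow(mos$labels), sum(vapply(items, function(it)
    nrow(it$labels), integer(1))))
  # tile (1, 2) holds item 1*3+2+1 = 6 (row-major)
  expect_equal(mos$image[33:64, 65:96], items[[6]]$image)
  # x = 1 identity
  one <- compose_mosaic(items[1], 1)
  expect_equal(one$image, items[[1]]$image)
  expect_equal(one$labels$cx, items[[1]]$labels$cx)
  expect_error(compose_mosaic(items[1:5], 3), "x\\^2")
  # mismatched dims get resized to the tile size, not an error
  items2 <- items
  items2[[2]]$image <- matrix(runif(64 * 64), 64, 64)
  mos2 <- compose_mosaic(items2, 3)
  expect_equal(dim(mos2$image), c(96, 96))
})

test_that("compose -> split recovers every input label exactly (1000 scenes)", {
  set.seed(33)
  x <- 3
  n_mosaics <- 112                    # 112 * 9 = 1008 scenes
  for (rep in seq_len(n_mosaics)) {
    items <- lapply(seq_len(x^2), function(i) tiny_item(48, n_labels = 2))
    mos <- compose_mosaic(items, x)
    dets <- denormalize_labels(mos$labels, mos$layout$canvas_w,
                               mos$layout$canvas_h)
    dets$confidence <- 1
    split <- split_detections(dets, mos$layout)
    for (i in 0:(x - 1)) for (j in 0:(x - 1)) {
      got <- split[[i * x + j + 1L]]
      want <- items[[i * x + j + 1L]]$labels
      expect_equal(nrow(got), nrow(want))
      ord_g <- order(got$cx, got$cy); ord_w <- order(want$cx, want$cy)
      expect_equal(got$cx[ord_g], want$cx[ord_w], tolerance = 1e-9)
      expect_equal(got$cy[ord_g], want$cy[ord_w], tolerance = 1e-9)
      expect_equal(got$w[ord_g], want$w[ord_w], tolerance = 1e-9)
      expect_equal(got$h[ord_g], want$h[ord_w], tolerance = 1e-9)
      expect_true(all(got$cx >= 0 & got$cx <= 1 & got$cy >= 0 & got$cy <= 1))
    }
  }
})

test_that("split_detections drops sub-retention fragments and handles empties", {
  ly <- mosaic_layout(2, 100)
  empty <- split_detections(data.frame(), ly)
  expect_length(empty, 4)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0))
  # center just right of the vertical seam: 34/60 of the width survives
  det <- data.frame(class_id = 0L, confidence = 0.9,
                    xc = 104, yc = 50, w = 60, h = 20)
  tight <- split_detections(det, ly, retention = 0.6)
  expect_true(all(vapply(tight, nrow, integer(1)) == 0))  # 0.567 < 0.6
  loose <- split_detections(det, ly, retention = 0.5)
  expect_equal(nrow(loose[[2]]), 1)                       # tile (0, 1)
  frac <- (104 + 30 - 100) / 60
  expect_equal(loose[[2]]$w, frac * 60 / 100, tolerance = 1e-12)
})

test_that("training wrapper composes x^2 randomly sampled items", {
  set.seed(4)
  pool <- lapply(1:5, function(i) tiny_item(24))
  mos <- ceac_sample_batch(pool, 3)
  expect_equal(dim(mos$image), c(72, 72))
  expect_equal(mos$layout$x, 3L)
})
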