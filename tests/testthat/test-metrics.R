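make_dets <- function(gts, jitter = 0, conf = NULL) {
  d <- gts
  d$confidence <- if (is.null(conf)) runif(nrow(gts), 0.5, 1) else conf
  d$xc <- d$xc + jitter
  d
}

test_that("matching handles perfect, empty and constructed detection sets", {
  set.seed(1)
  gts <- data.frame(class_id = c(0, 0, 1, 2, 3), xc = c(10, 40, 80, 20, 60),
                    yc = c(10, 40, 80, 70, 30), w = 8, h = 8)
  m <- match_detections(make_dets(gts), gts)
  expect_equal(sum(m$counts$fp), 0)
  expect_equal(sum(m$counts$fn), 0)
  expect_equal(sum(m$counts$tp), 5)
  # no detections at all
  empty <- make_dets(gts[0, ])
  m0 <- match_detections(empty, gts)
  expect_equal(sum(m0$counts$tp), 0)
  expect_equal(sum(m0$counts$fn), nrow(gts))
  # TP + FN equals the ground-truth count per class
  dets <- rbind(make_dets(gts), make_dets(gts, jitter = 50))
  m2 <- match_detections(dets, gts)
  agg <- merge(m2$counts,
               as.data.frame(table(class_id = gts$class_id)), by = "class_id")
  expect_equal(agg$tp + agg$fn, as.integer(as.character(agg$Freq)))
})

test_that("greedy matching agrees with an exhaustive assignment oracle", {
  # 5 detections, 3 gts of one class, constructed so the confidence-greedy
  # matching attains the best achievable TP count; the oracle enumerates all
  # one-to-one assignments of detections to ground truths.
  gts <- data.frame(class_id = 0, xc = c(10, 30, 50), yc = 10, w = 8, h = 8)
  dets <- data.frame(class_id = 0,
                     confidence = c(0.9, 0.8, 0.7, 0.6, 0.5),
                     xc = c(10.5, 30.5, 50.5, 11, 90), yc = 10, w = 8, h = 8)
  m <- match_detections(dets, gts, iou_threshold = 0.5)
  best_tp <- 0
  perm_idx <- utils::combn(seq_len(nrow(dets)), nrow(gts), simplify = FALSE)
  for (sel in perm_idx) {
    for (ord in list(sel, rev(sel))) {
      tp <- sum(vapply(seq_along(ord), function(i)
        box_iou(as.numeric(dets[ord[i], c("xc", "yc", "w", "h")]),
                as.numeric(gts[i, c("xc", "yc", "w", "h")])) >= 0.5,
        logical(1)))
      best_tp <- max(best_tp, tp)
    }
  }
  expect_equal(sum(m$counts$tp), best_tp)
  expect_equal(sum(m$counts$fp), nrow(dets) - best_tp)
})

test_that("precision/recall/F1 arithmetic reproduces the published values", {
  # printed comparison rows: P/R in percent
  expect_equal(round(f1_score(93.03, 95.01), 2), 94.01)
  expect_equal(round(f1_score(88.39, 88.08), 2), 88.23)
  # harmonic-mean fixed point
  expect_equal(f1_score(0.7, 0.7), 0.7)
  # from raw counts
  prf <- precision_recall_f1(tp = 8, fp = 2, fn = 4)
  expect_equal(prf$precision, 0.8)
  expect_equal(prf$recall, 8 / 12)
  expect_equal(prf$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  expect_warning(precision_recall_f1(tp = 0, fp = 0, fn = 3), "zero")
})

test_that("F1 satisfies its algebraic bounds", {
  set.seed(5)
  p <- runif(200); r <- runif(200)
  f1 <- f1_score(p, r)
  expect_true(all(f1 <= (p + r) / 2 + 1e-12))
  expect_true(all(f1 <= 2 * pmin(p, r) + 1e-12))
  expect_true(all(pmin(p, r) >= f1 / 2 - 1e-12))
})

test_that("average precision handles degenerate detectors and hand cases", {
  # perfect detector: every detection a TP
  expect_equal(average_precision(pr_curve(rep(TRUE, 4), n_gt = 4)), 1)
  # a single wrong detection
  expect_equal(average_precision(pr_curve(FALSE, n_gt = 2)), 0)
  expect_error(pr_curve(TRUE, n_gt = 0), "undefined")
  # 4-detection hand case: TP, FP, TP, FP with 3 gts
  curve <- pr_curve(c(TRUE, FALSE, TRUE, FALSE), n_gt = 3)
  # recalls 1/3, 1/3, 2/3, 2/3; interpolated precision at 2/3 recall is 2/3
  expect_equal(average_precision(curve), 1 / 3 * 1 + 1 / 3 * 2 / 3)
})

test_that("average precision agrees with a Riemann-sum oracle", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    tp <- runif(n) < 0.6
    n_gt <- sum(tp) + sample(0:3, 1)
    if (n_gt == 0) n_gt <- 1
    curve <- pr_curve(tp, n_gt)
    expect_equal(average_precision(curve), riemann_ap(curve),
                 tolerance = 1e-3)
  }
})

test_that("AP is permutation invariant at equal confidence", {
  gts <- data.frame(class_id = 0, xc = c(10, 30, 50), yc = 10, w = 8, h = 8)
  dets <- data.frame(class_id = 0, confidence = 0.8,
                     xc = c(10, 30, 90), yc = 10, w = 8, h = 8)
  e1 <- evaluate_detections(dets, gts)$map
  e2 <- evaluate_detections(dets[c(3, 1, 2), ], gts)$map
  expect_equal(e1, e2)
})

test_that("mAP averages classes and the IoU sweep is non-increasing", {
  expect_equal(mean_ap(c(1, 0)), 0.5)
  expect_equal(mean_ap(0.7), 0.7)
  expect_warning(m <- mean_ap(c(0.5, NA)), "excluding")
  expect_equal(m, 0.5)
  set.seed(21)
  gts <- data.frame(class_id = rep(0:3, each = 3),
                    xc = runif(12, 20, 100), yc = runif(12, 20, 100),
                    w = 10, h = 10)
  dets <- make_dets(gts, jitter = runif(12, 0, 3))
  sweep <- map_50_95(dets, gts)
  expect_true(all(diff(sweep$per_threshold$map) <= 1e-9))
  expect_equal(sweep$map_50_95, mean(sweep$per_threshold$map))
})
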