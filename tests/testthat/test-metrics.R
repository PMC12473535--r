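# Error metrics, pixel-wise segmentation scores, and COCO-style mask AP.

test_that("mae/rmse match direct formula evaluation and their invariants", {
  expect_equal(mae_rmse(c(1, 2, 3), c(1, 2, 3)), list(mae = 0, rmse = 0))
  r <- mae_rmse(c(10, 20), c(12, 19))
  expect_equal(r$mae, 1.5)
  expect_equal(r$rmse, sqrt(2.5))
  s <- mae_rmse(5, 9)
  expect_equal(s$mae, s$rmse)
  expect_error(mae_rmse(numeric(0), numeric(0)), "empty")
  expect_error(mae_rmse(1:3, 1:2), "mismatch")
})

test_that("rmse >= mae on random inputs, equality iff equal absolute errors", {
  set.seed(99)
  for (k in 1:1000) {
    n <- sample(1:30, 1)
    a <- rnorm(n, 100, 20); b <- rnorm(n, 100, 20)
    r <- mae_rmse(a, b)
    expect_gte(r$rmse, r$mae - 1e-12)
  }
  r <- mae_rmse(c(10, 20, 30), c(12, 18, 32))  # all |e| = 2
  expect_equal(r$rmse, r$mae)
})

test_that("centerline scores count pixels correctly", {
  y <- matrix(0L, 3, 3); y[1, 1] <- 1L; y[2, 2] <- 1L; y[3, 3] <- 1L
  p <- matrix(0, 3, 3); p[1, 1] <- 1; p[2, 2] <- 1; p[1, 3] <- 1
  s <- centerline_scores(p, y, 0.5)   # 2 TP, 1 FP, 1 FN
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 / 3)
  expect_equal(s$iou_fg, 0.5)
  expect_equal(s$miou, mean(c(0.5, 5 / 7)))   # tn = 5
  # perfect prediction
  sp <- centerline_scores(y * 1.0, y)
  expect_equal(unlist(sp[c("precision", "recall", "f1", "miou")]),
               c(precision = 1, recall = 1, f1 = 1, miou = 1))
  # empty prediction convention
  se <- centerline_scores(matrix(0, 3, 3), y)
  expect_equal(se$precision, 0)
  expect_equal(se$recall, 0)
  expect_equal(se$f1, 0)
})

test_that("f1 equals the harmonic mean of precision and recall", {
  set.seed(7)
  for (k in 1:50) {
    p <- matrix(runif(100), 10, 10)
    y <- matrix(rbinom(100, 1, 0.3), 10, 10)
    s <- centerline_scores(p, y, 0.5)
    hm <- if (s$precision + s$recall == 0) 0 else
      2 * s$precision * s$recall / (s$precision + s$recall)
    expect_equal(s$f1, hm, tolerance = 1e-12)
  }
})

test_that("perfect detections give AP 1 and empty predictions give AP 0", {
  cfg <- scene_config(image_height = 90, image_width = 120, n_instances = 3,
                      seed = 2)
  sc <- generate_scene(cfg)
  truth <- lapply(sc$instances, `[[`, "mask")
  det <- shrimpline:::new_detection_result(truth, rep(1, 3))
  ap <- mask_ap(list(det), list(truth))
  expect_equal(unname(ap$ap), rep(1, 10))
  empty <- shrimpline:::new_detection_result(list(), numeric(0))
  ap0 <- mask_ap(list(empty), list(truth))
  expect_equal(ap0$ap50, 0)
})

test_that("AP matches a hand-built PR construction on a toy case", {
  # 1 image, 2 truths, 3 scored predictions with IoUs straddling 0.5
  t1 <- matrix(0L, 20, 20); t1[2:9, 2:9] <- 1L
  t2 <- matrix(0L, 20, 20); t2[12:19, 12:19] <- 1L
  p1 <- matrix(0L, 20, 20); p1[2:9, 2:9] <- 1L          # IoU 1 with t1
  p2 <- matrix(0L, 20, 20); p2[12:19, 11:18] <- 1L      # high IoU with t2
  p3 <- matrix(0L, 20, 20); p3[5:12, 5:12] <- 1L        # low IoU with both
  det <- shrimpline:::new_detection_result(list(p3, p1, p2), c(0.9, 0.8, 0.7))
  ap <- mask_ap(list(det), list(list(t1, t2)), iou_thresholds = 0.5)
  expect_equal(unname(ap$ap50),
               bruteforce_ap(list(p3, p1, p2), c(0.9, 0.8, 0.7),
                             list(t1, t2), 0.5))
  # hand PR: order p3 (FP), p1 (TP), p2 (TP) -> precision envelope 2/3
  expect_equal(unname(ap$ap50), 2 / 3, tolerance = 1e-9)
})

test_that("AP agrees with the brute-force matcher on random small cases", {
  set.seed(123)
  for (k in 1:40) {
    nt <- sample(0:4, 1); np <- sample(0:4, 1)
    truths <- lapply(seq_len(nt), function(i) {
      m <- matrix(0L, 30, 30)
      r <- sample(1:22, 1); cc <- sample(1:22, 1)
      m[r:(r + 7), cc:(cc + 7)] <- 1L
      m
    })
    preds <- lapply(seq_len(np), function(i) {
      m <- matrix(0L, 30, 30)
      r <- sample(1:22, 1); cc <- sample(1:22, 1)
      m[r:(r + 7), cc:(cc + 7)] <- 1L
      m
    })
    if (nt == 0) next
    scores <- round(runif(np), 3)
    det <- shrimpline:::new_detection_result(preds, scores)
    for (thr in c(0.5, 0.75)) {
      mine <- mask_ap(list(det), list(truths), iou_thresholds = thr)$ap[[1]]
      ref <- bruteforce_ap(preds, scores, truths, thr)
      expect_equal(unname(mine), ref, tolerance = 1e-12,
                   label = sprintf("case %d thr %.2f", k, thr))
    }
  }
})

test_that("ap50_95 averages the per-threshold APs and requires scores", {
  t1 <- matrix(0L, 10, 10); t1[2:8, 2:8] <- 1L
  det <- shrimpline:::new_detection_result(list(t1), 1)
  ap <- mask_ap(list(det), list(list(t1)))
  expect_equal(ap$ap50_95, mean(ap$ap))
  det$scores <- NULL
  expect_error(mask_ap(list(det), list(list(t1))), "scores")
})
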