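make_dets <- function(boxes, scores) {
  data.frame(do.call(rbind, lapply(boxes, function(b)
    setNames(as.numeric(b), c("x0", "y0", "x1", "y1")))), score = scores)
}

test_that("greedy matching labels exact hits TP and everything else FP", {
  gts <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  dets <- make_dets(list(c(0, 0, 10, 10), c(20, 20, 30, 30)), c(0.9, 0.8))
  m <- match_detections(dets, gts)
  expect_true(all(m$tp))

  none <- match_detections(dets, matrix(numeric(), ncol = 4))
  expect_false(any(none$tp))

  # a duplicate of an already-matched ground truth is a false positive
  dup <- make_dets(list(c(0, 0, 10, 10), c(0, 0, 10, 10)), c(0.9, 0.8))
  m2 <- match_detections(dup, gts)
  expect_equal(m2$tp, c(TRUE, FALSE))
})

test_that("matching follows greedy score order on a crafted 3x2 instance", {
  # det A (score .9) overlaps gt1 at IoU ~0.53; det B (.8) overlaps gt1
  # better (1.0) but greedy order gives gt1 to A; B cannot re-match it.
  gts <- rbind(c(0, 0, 10, 10), c(50, 50, 60, 60))
  dets <- make_dets(list(c(0, 3, 10, 13), c(0, 0, 10, 10), c(50, 50, 60, 60)),
                    c(0.9, 0.8, 0.7))
  m <- match_detections(dets, gts, iou_threshold = 0.5)
  expect_equal(m$tp, c(TRUE, FALSE, TRUE))
})

test_that("average precision hits the stated boundary cases", {
  # perfect ranking, all ground truths found, no false positives
  expect_equal(average_precision(pr_curve(c(TRUE, TRUE, TRUE), 3)), 1)
  # a single false-positive detection against one ground truth
  expect_equal(average_precision(pr_curve(FALSE, 1)), 0)
  # zero ground truths: flagged NA, never silently 0
  expect_warning(ap <- average_precision(pr_curve(logical(), 0)), "undefined")
  expect_true(is.na(ap))
  expect_true(attr(ap, "undefined"))
})

test_that("average precision equals the threshold-enumeration oracle", {
  withr::local_seed(41)
  for (i in 1:300) {
    n_gt <- sample(1:5, 1)
    n_det <- sample(1:10, 1)
    tp <- rep(FALSE, n_det)
    hits <- sample(0:min(n_gt, n_det), 1)
    if (hits > 0) tp[sample(n_det, hits)] <- TRUE
    scores <- sort(runif(n_det), decreasing = TRUE)  # distinct a.s.
    got <- average_precision(pr_curve(tp, n_gt))
    expect_equal(got, oracle_ap(scores, tp, n_gt))
  }
})

test_that("adding a correct detection at the top never decreases AP", {
  withr::local_seed(43)
  for (i in 1:100) {
    n_gt <- sample(2:6, 1)
    n_det <- sample(1:8, 1)
    tp <- runif(n_det) < 0.5
    tp[cumsum(tp) > n_gt - 1] <- FALSE  # leave at least one gt unmatched
    ap0 <- average_precision(pr_curve(tp, n_gt))
    ap1 <- average_precision(pr_curve(c(TRUE, tp), n_gt))
    expect_gte(ap1, ap0)
  }
})

test_that("mAP is the order-invariant arithmetic mean of per-class APs", {
  expect_equal(mean_average_precision(c(88.78, 91.64)), 90.21)
  expect_equal(mean_average_precision(c(67.4, 78.48)), 72.94)
  expect_equal(mean_average_precision(91.64), 91.64)
  withr::local_seed(44)
  aps <- runif(5)
  expect_equal(mean_average_precision(aps),
               mean_average_precision(sample(aps)))
  expect_error(mean_average_precision(numeric()), "at least one class")
})

test_that("end-to-end evaluation on a fixture scene behaves as expected", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(scene_config(width = 96, height = 96, n_psyllid = 2,
                                      n_fly = 1, seed = 55),
                         n_images = 4, dir = dir)
  # the ground truth itself, scored 1.0, is a perfect detector
  perfect <- do.call(rbind, lapply(ds$records, function(r) {
    a <- r$annotations
    if (nrow(a) == 0) return(NULL)
    data.frame(image_id = r$id, class_id = a$class_id, x0 = a$x0, y0 = a$y0,
               x1 = a$x1, y1 = a$y1, score = 1.0)
  }))
  s <- evaluate(ds, perfect)
  expect_equal(unname(s$per_class_ap), c(1, 1))
  expect_equal(s$map, 1)

  # no detections at all: AP 0 for every class with ground truth
  empty <- perfect[0, ]
  s0 <- evaluate(ds, empty)
  expect_equal(unname(s0$per_class_ap), c(0, 0))

  # unknown category ids are rejected by name
  bad <- perfect
  bad$class_id[1] <- 7L
  expect_error(evaluate(ds, bad), "unknown category id 7")
})

test_that("a planted TP/FP pattern reproduces the hand-enumerated summary", {
  ds <- detection_dataset(list(list(
    id = 1L, file_name = "a.png", width = 100L, height = 100L,
    annotations = annotations(c(10, 40, 70), c(10, 40, 70),
                              c(20, 50, 80), c(20, 50, 80), c(0L, 0L, 0L)))))
  dets <- data.frame(
    image_id = 1L, class_id = 0L,
    x0 = c(10, 40, 0, 70), y0 = c(10, 40, 0, 70),
    x1 = c(20, 50, 5, 80), y1 = c(20, 50, 5, 80),
    score = c(0.9, 0.7, 0.8, 0.3))
  # ranked: TP, FP, TP, TP -> oracle AP over the 3 ground truths
  suppressWarnings(s <- evaluate(ds, dets))
  expect_equal(s$per_class_ap[["psyllid"]],
               oracle_ap(c(0.9, 0.8, 0.7, 0.3),
                         c(TRUE, FALSE, TRUE, TRUE), 3))
})
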