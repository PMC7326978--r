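test_that("matching pairs predictions and ground truth greedily by score then IoU", {
  gt <- list(square_inst(10, 10, 10, image = "i"))
  # identical prediction
  p1 <- list(square_inst(10, 10, 10, score = 0.9, image = "i"))
  m <- match_instances(p1, gt, 0.5, height = 64, width = 64)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(length(m$fp), 0L)
  expect_equal(length(m$fn), 0L)
  # IoU 0.4 below threshold 0.5: FP + FN
  p2 <- list(square_inst(10, 16, 10, score = 0.9, image = "i"))  # overlap 4/10 rows
  iou <- 40 / 160
  p3 <- list(square_inst(10, 13, 10, score = 0.9, image = "i"))  # 70/130
  m3 <- match_instances(p3, gt, 0.6, height = 64, width = 64)
  expect_equal(nrow(m3$pairs), 0L)
  expect_equal(m3$fp, 1L)
  expect_equal(m3$fn, 1L)
  # two predictions over one GT: the higher-scored wins, the other is FP
  p4 <- list(square_inst(10, 11, 10, score = 0.7, image = "i"),   # IoU 9/11
             square_inst(10, 12, 10, score = 0.9, image = "i"))   # IoU 8/12
  m4 <- match_instances(p4, gt, 0.5, height = 64, width = 64)
  expect_equal(m4$pairs$pred, 2L)
  expect_equal(m4$fp, 1L)
  expect_error(match_instances(p4, gt, 1.2, height = 64, width = 64), "0, 1")
  expect_error(match_instances(list(square_inst(1, 1, 4, image = "i")), gt, 0.5,
                               height = 64, width = 64), "scores")
})

test_that("class-aware matching refuses cross-class pairs", {
  gt <- list(square_inst(10, 10, 10, label = "immature", image = "i"))
  p <- list(square_inst(10, 10, 10, label = "mature", score = 1, image = "i"))
  m <- match_instances(p, gt, 0.5, class_aware = TRUE, height = 64, width = 64)
  expect_equal(nrow(m$pairs), 0L)
  m2 <- match_instances(p, gt, 0.5, class_aware = FALSE, height = 64, width = 64)
  expect_equal(nrow(m2$pairs), 1L)
})

test_that("average precision reproduces the hand-enumerated PR curve", {
  # 2 GT; score order: TP, FP, TP -> monotonized AP = 0.5 + 0.5 * 2/3
  gts <- list(square_inst(0, 0, 10, image = "i"),
              square_inst(30, 30, 10, image = "i"))
  preds <- list(square_inst(0, 0, 10, score = 0.9, image = "i"),
                square_inst(45, 0, 10, score = 0.8, image = "i"),
                square_inst(30, 30, 10, score = 0.7, image = "i"))
  a <- average_precision(preds, gts, "mature", 0.5, 64, 64)
  expect_equal(a$ap, 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_equal(a$curve$recall, c(0.5, 0.5, 1.0))
  expect_equal(a$curve$precision, c(1.0, 0.5, 2 / 3))
  # recall non-decreasing along the curve
  expect_true(all(diff(a$curve$recall) >= 0))
  # single TP only
  a1 <- average_precision(preds[1], gts[1], "mature", 0.5, 64, 64)
  expect_equal(a1$ap, 1.0)
  # all FP
  a0 <- average_precision(preds[2], gts, "mature", 0.5, 64, 64)
  expect_equal(a0$ap, 0.0)
  expect_error(average_precision(preds, gts, "immature", 0.5, 64, 64),
               "no ground truth")
})

test_that("AP equals the exhaustive prefix-enumeration oracle on small scenes", {
  set.seed(23)
  for (rep in 1:8) {
    n_gt <- sample(2:4, 1)
    gts <- lapply(seq_len(n_gt), function(j)
      disk_inst(20 + 28 * ((j - 1) %% 3), 20 + 28 * ((j - 1) %/% 3),
                runif(1, 7, 11), label = sample(c("mature", "immature"), 1),
                image = "i", height = 96, width = 96))
    # up to 6 detections: some near a GT, some spurious
    preds <- lapply(seq_len(sample(3:6, 1)), function(k) {
      if (k <= n_gt) {
        g <- gts[[k]]
        m <- instance_mask(g, 96, 96)
        idx <- which(m, arr.ind = TRUE)
        disk_inst(mean(idx[, 2]) + runif(1, -6, 6),
                  mean(idx[, 1]) + runif(1, -6, 6), runif(1, 6, 11),
                  label = sample(c("mature", "immature"), 1),
                  score = runif(1), image = "i", height = 96, width = 96)
      } else {
        disk_inst(runif(1, 60, 88), runif(1, 60, 88), runif(1, 5, 8),
                  label = sample(c("mature", "immature"), 1),
                  score = runif(1), image = "i", height = 96, width = 96)
      }
    })
    for (cl in unique(vapply(gts, function(g) g$label, character(1)))) {
      for (t in c(0.5, 0.75)) {
        a <- average_precision(preds, gts, cl, t, 96, 96)
        expect_equal(a$ap, oracle_ap(preds, gts, cl, t, 96, 96),
                     tolerance = 1e-12,
                     info = sprintf("rep %d class %s t %.2f", rep, cl, t))
      }
    }
  }
})

test_that("match counts partition predictions and ground truth at every threshold", {
  set.seed(31)
  gts <- lapply(1:5, function(j)
    disk_inst(24 * j - 10, 50, 9, label = c("mature", "immature")[1 + j %% 2],
              image = "i", height = 128, width = 128))
  preds <- lapply(1:6, function(k)
    disk_inst(24 * k - 10 + runif(1, -5, 5), 50 + runif(1, -5, 5),
              9, label = c("mature", "immature")[1 + k %% 2],
              score = runif(1), image = "i", height = 128, width = 128))
  for (t in seq(0.5, 0.95, by = 0.05)) {
    m <- match_instances(preds, gts, t, height = 128, width = 128)
    expect_equal(nrow(m$pairs) + length(m$fn), length(gts))
    expect_equal(nrow(m$pairs) + length(m$fp), length(preds))
    expect_true(all(m$pairs$iou >= t))
    expect_true(!anyDuplicated(m$pairs$gt) && !anyDuplicated(m$pairs$pred))
  }
})

test_that("metrics are invariant to prediction input order", {
  set.seed(13)
  gts <- lapply(1:4, function(j)
    disk_inst(28 * j - 12, 40, 9, image = "i", height = 128, width = 128))
  preds <- lapply(1:5, function(k)
    disk_inst(28 * k - 12 + runif(1, -4, 4), 40, 9,
              score = runif(1), image = "i", height = 128, width = 128))
  base <- mean_average_precision(preds, gts, height = 128, width = 128,
                                 classes = "mature")
  for (rep in 1:3) {
    shuf <- mean_average_precision(preds[sample(5)], gts, height = 128,
                                   width = 128, classes = "mature")
    expect_equal(shuf$table$mAP, base$table$mAP, tolerance = 1e-12)
  }
})

test_that("mAP is 1 for perfect predictions and non-increasing in the threshold", {
  gts <- list(square_inst(5, 5, 12, label = "mature", image = "i"),
              square_inst(30, 30, 12, label = "immature", image = "i"))
  preds <- lapply(gts, function(g) { g$score <- 1; g })
  r <- mean_average_precision(preds, gts, height = 64, width = 64)
  expect_true(all(r$table$mAP == 1))
  # shrunken masks with exact IoU 0.7 flip from 1 to 0 across 0.7
  gts2 <- list(square_inst(5, 5, 20, label = "mature", image = "i"),
               square_inst(35, 35, 20, label = "immature", image = "i"))
  preds2 <- list(square_inst(5, 5 + 3, 20, 14, label = "mature", score = 1,
                             image = "i"),
                 square_inst(35, 35 + 3, 20, 14, label = "immature", score = 1,
                             image = "i"))
  r2 <- mean_average_precision(preds2, gts2, height = 64, width = 64)
  expect_true(all(r2$table$mAP[r2$table$iou_threshold <= 0.65] == 1))
  expect_true(all(r2$table$mAP[r2$table$iou_threshold >= 0.75] == 0))
  expect_true(all(diff(r2$table$mAP) <= 1e-12))
})

test_that("a class absent from ground truth is excluded with a warning", {
  gts <- list(square_inst(5, 5, 12, label = "mature", image = "i"))
  preds <- list(square_inst(5, 5, 12, label = "mature", score = 1, image = "i"),
                square_inst(30, 30, 8, label = "immature", score = 0.8,
                            image = "i"))
  expect_warning(r <- mean_average_precision(preds, gts, height = 64, width = 64),
                 "absent")
  expect_equal(r$classes, "mature")
  expect_true(all(r$table$mAP == 1))
})

test_that("mean IoU averages true-positive pair IoUs only", {
  gts <- list(square_inst(0, 0, 10, image = "i"),
              square_inst(30, 30, 10, image = "i"))
  preds <- list(square_inst(0, 1, 10, score = 0.9, image = "i"),   # IoU 9/11
                square_inst(30, 32, 10, score = 0.8, image = "i")) # IoU 8/12
  m <- match_instances(preds, gts, 0.5, height = 64, width = 64)
  expect_equal(mean_iou(m), mean(c(9 / 11, 8 / 12)))
  expect_equal(mean_iou(match_instances(preds[1], gts[1], 0.5,
                                        height = 64, width = 64)), 9 / 11)
  none <- match_instances(list(), gts, 0.5, height = 64, width = 64)
  expect_error(mean_iou(none), "undefined")
  # 100 constructed pairs: mean equals direct recomputation
  set.seed(3)
  offs <- sample(0:5, 100, replace = TRUE)
  gl <- lapply(1:100, function(i)
    square_inst(2, 2, 10, image = paste0("i", i), height = 20, width = 20))
  pl <- lapply(1:100, function(i)
    square_inst(2, 2 + offs[i], 10, score = 1, image = paste0("i", i),
                height = 20, width = 20))
  ms <- lapply(1:100, function(i)
    match_instances(pl[i], gl[i], 0.1, height = 20, width = 20))
  expect_equal(mean_iou(ms), mean((10 - offs) / (10 + offs)))
})

test_that("error taxonomy identifies each constructed failure mode", {
  # perfect predictions: all tallies zero
  gts <- list(disk_inst(30, 30, 10, image = "i"),
              disk_inst(70, 70, 10, image = "i"))
  perfect <- lapply(gts, function(g) { g$score <- 1; g })
  t0 <- classify_errors(perfect, gts, height = 128, width = 128)
  expect_equal(unlist(t0), c(one_as_two = 0L, missed = 0L, two_as_one = 0L,
                             partial = 0L))
  # missed: a GT with no overlapping prediction
  t1 <- classify_errors(perfect[1], gts, height = 128, width = 128)
  expect_equal(t1$missed, 1L)
  # two-as-one: one blob covering two GT disks at IoU < 0.5 each
  blob <- detection_instance("i", instance_mask(gts[[1]], 128, 128) |
                                    instance_mask(gts[[2]], 128, 128) |
                                    square_mask(28, 28, 45, height = 128, width = 128),
                             "mature", 0.9)
  t2 <- classify_errors(list(blob), gts, height = 128, width = 128)
  expect_equal(t2$two_as_one, 1L)
  expect_equal(t2$missed + t2$partial + t2$one_as_two, 0L)
  # one-as-two: two halves of one GT
  gm <- instance_mask(gts[[1]], 128, 128)
  left <- gm; left[, 29:128] <- FALSE    # gap keeps each piece below IoU 0.5
  right <- gm; right[, 1:32] <- FALSE
  halves <- list(detection_instance("i", left, "mature", 0.8),
                 detection_instance("i", right, "mature", 0.7),
                 perfect[[2]])
  t3 <- classify_errors(halves, gts, height = 128, width = 128)
  expect_equal(t3$one_as_two, 1L)
  # partial: one overlapping prediction in [floor, primary)
  sliver <- gm; sliver[, 27:128] <- FALSE   # small left sliver of GT 1
  t4 <- classify_errors(list(detection_instance("i", sliver, "mature", 0.8),
                             perfect[[2]]),
                        gts, height = 128, width = 128)
  expect_equal(t4$partial, 1L)
  expect_error(classify_errors(perfect, gts, primary_threshold = 0.5,
                               floor_threshold = 0.6,
                               height = 128, width = 128), "below")
})

test_that("evaluation report serializes, validates, and plots", {
  gts <- list(square_inst(5, 5, 12, label = "mature", image = "i"),
              square_inst(30, 30, 12, label = "immature", image = "i"))
  preds <- lapply(gts, function(g) { g$score <- 0.95; g })
  rep_ <- evaluate_detections(preds, gts, 64, 64)
  expect_equal(rep_$miou, 1)
  expect_true(all(rep_$map$table$mAP == 1))
  f <- tempfile(fileext = ".json")
  write_report(rep_, f)
  expect_true(validate_report(f))
  p <- plot_pr_curves(rep_)
  expect_s3_class(p, "ggplot")
})
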