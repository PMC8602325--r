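test_that("confusion counts match constructed fixtures", {
  ones <- matrix(1, 5, 5)
  cc <- confusion_counts(ones, ones)
  expect_equal(unlist(cc[c("n_tp", "n_fp", "n_tn", "n_fn")]),
               c(n_tp = 25, n_fp = 0, n_tn = 0, n_fn = 0))

  gt <- random_mask(6, 6)
  cc2 <- confusion_counts(1 - gt, gt)
  expect_equal(cc2$n_tp, 0)
  expect_equal(cc2$n_tn, 0)

  pred <- matrix(0, 10, 10)
  gtm <- matrix(0, 10, 10)
  pred[1:3] <- 1           # 2 TP + 1 FP
  gtm[c(1, 2, 4)] <- 1     # 1 FN at position 4
  cc3 <- confusion_counts(pred, gtm)
  expect_equal(unlist(cc3[c("n_tp", "n_fp", "n_tn", "n_fn")]),
               c(n_tp = 2, n_fp = 1, n_tn = 96, n_fn = 1))
  sc <- segmentation_scores(cc3)
  expect_equal(sc, c(dice = 2 / 3, acc = 0.98, jac = 0.5), tolerance = 1e-12)

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "waveseg_shape_error")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               class = "waveseg_validation_error")
})

test_that("Dice-Jaccard identity and pixel-loop equivalence hold on random masks", {
  set.seed(77)
  for (i in 1:50) {
    pred <- random_mask(32, 32, runif(1, 0.1, 0.9))
    gt <- random_mask(32, 32, runif(1, 0.1, 0.9))
    sc <- segmentation_scores(confusion_counts(pred, gt))
    expect_equal(sc[["dice"]], 2 * sc[["jac"]] / (1 + sc[["jac"]]),
                 tolerance = 1e-12)
    expect_lte(sc[["jac"]], sc[["dice"]])
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(sc, scores_pixel_loop(pred, gt), tolerance = 1e-12)
  }
})

test_that("empty-positive slides score by the perfect-empty convention", {
  z <- matrix(0, 4, 4)
  sc <- segmentation_scores(confusion_counts(z, z))
  expect_equal(sc, c(dice = 1, acc = 1, jac = 1))
  sc0 <- segmentation_scores(confusion_counts(z, z), empty_value = 0)
  expect_equal(sc0[["dice"]], 0)
})

test_that("threshold sweeps binarize with >= and are monotone in positives", {
  gt <- random_mask(16, 16)
  sw <- threshold_sweep(gt * 1.0, gt)
  expect_equal(nrow(sw), 9L)
  expect_true(all(sw$dice == 1))

  half <- matrix(0, 16, 16)
  half[, 1:8] <- 1
  sw2 <- threshold_sweep(matrix(0.5, 16, 16), half, thresholds = c(0.3, 0.5, 0.7))
  # t <= 0.5: everything predicted positive -> dice 2*(n/2)/(n + n/2) = 2/3
  expect_equal(sw2$dice[sw2$threshold == 0.3], 2 / 3, tolerance = 1e-12)
  expect_equal(sw2$dice[sw2$threshold == 0.5], 2 / 3, tolerance = 1e-12)  # >= is non-strict
  expect_equal(sw2$dice[sw2$threshold == 0.7], 0)

  set.seed(3)
  m <- matrix(runif(256), 16, 16)
  pos <- vapply(seq(0.1, 0.9, 0.1), function(t) sum(m >= t), 0)
  expect_true(all(diff(pos) <= 0))

  expect_error(threshold_sweep(m, random_mask(16, 16), thresholds = numeric(0)),
               class = "waveseg_validation_error")
  expect_error(threshold_sweep(m, random_mask(16, 16), thresholds = c(0, 0.5)),
               class = "waveseg_validation_error")
})

test_that("aggregation reports per-class and overall mean/sd", {
  rec <- function(id, cl, dice) {
    data.frame(slide_id = id, class_label = cl, method = "m", threshold = 0.5,
               dice = dice, acc = dice, jac = dice)
  }
  one <- aggregate_by_class(rec("a", "TAH", 0.8))
  expect_equal(one$dice_mean, c(0.8, 0.8))
  expect_equal(one$dice_sd, c(0, 0))

  two <- aggregate_by_class(rbind(rec("a", "TAH", 0.6), rec("b", "TAH", 0.8)))
  overall <- two[two$class_label == "ALL", ]
  expect_equal(overall$dice_mean, 0.7, tolerance = 1e-12)
  expect_equal(overall$dice_sd, sqrt(0.02), tolerance = 1e-12)
  expect_equal(format_pm(overall$dice_mean, overall$dice_sd), "0.700 ± 0.141")

  five <- do.call(rbind, Map(rec, letters[1:5],
                             c("ADENOCA", "TAH", "TAL", "CARCINOID", "HYPERP"),
                             seq(0.5, 0.9, 0.1)))
  agg <- aggregate_by_class(five)
  expect_equal(nrow(agg), 6L)  # 5 classes + ALL
  expect_error(aggregate_by_class(five[0, ]), class = "waveseg_validation_error")
})

test_that("k-fold splits are balanced, seeded, and by slide", {
  ids <- sprintf("s%02d", 1:23)
  f1 <- kfold_split(ids, k = 5, seed = 3)
  f2 <- kfold_split(ids, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1$fold)), 1:5)
  expect_true(all(abs(table(f1$fold) - 23 / 5) <= 1))
  expect_false(any(duplicated(f1$slide_id)))
  expect_error(kfold_split(ids, k = 1), class = "waveseg_size_error")
})

test_that("geometry accounting follows quadratic tile-side scaling", {
  expect_equal(scaled_roi_area(1024), 6.25e-2)
  expect_equal(scaled_roi_area(512), 6.25e-2 / 4)
  expect_equal(scaled_roi_area(256), 6.25e-2 / 16)
  expect_equal(input_size_reduction_pct(), 100 / 12)
  expect_equal(tile_area_ratio(1024, 512), 4)
})
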