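# Confusion-count segmentation metrics, threshold sweeps, and per-class
# aggregation. The positive class is tumor (= 1) throughout.

#' Pixel confusion counts between a binary prediction and ground truth
#'
#' @param pred,gt Binary arrays of equal shape.
#' @return An object of class `"confusion_counts"`: list with `n_tp`, `n_fp`,
#'   `n_tn`, `n_fn` (they always sum to the pixel count).
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt)) {
    stop_waveseg("pred and gt shapes differ", class = "waveseg_shape_error")
  }
  if (!is_binary(pred) || !is_binary(gt)) {
    stop_waveseg("pred and gt must be binary", class = "waveseg_validation_error")
  }
  n_tp <- sum(pred * gt)
  n_fp <- sum(pred) - n_tp
  n_fn <- sum(gt) - n_tp
  n_tn <- length(pred) - n_tp - n_fp - n_fn
  structure(list(n_tp = n_tp, n_fp = n_fp, n_tn = n_tn, n_fn = n_fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, TN %d, FN %d\n",
              x$n_tp, x$n_fp, x$n_tn, x$n_fn))
  invisible(x)
}

#' Dice, pixel accuracy and Jaccard from confusion counts
#'
#' `dice = 2*TP / (2*TP + FP + FN)`, `acc = (TP + TN) / total`,
#' `jac = TP / (TP + FP + FN)`. When neither mask contains any positive pixel
#' the Dice/Jaccard denominators vanish; by the perfect-empty convention such
#' scores default to `empty_value = 1` (configurable).
#'
#' @param counts A `"confusion_counts"` object.
#' @param empty_value Score assigned when `TP + FP + FN == 0`.
#' @return Named numeric vector `c(dice, acc, jac)`.
#' @export
segmentation_scores <- function(counts, empty_value = 1) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$n_tp + counts$n_fp + counts$n_tn + counts$n_fn
  if (total <= 0) {
    stop_waveseg("empty confusion counts", class = "waveseg_validation_error")
  }
  den <- counts$n_tp + counts$n_fp + counts$n_fn
  if (den == 0) {
    dice <- empty_value
    jac <- empty_value
  } else {
    dice <- 2 * counts$n_tp / (2 * counts$n_tp + counts$n_fp + counts$n_fn)
    jac <- counts$n_tp / den
  }
  c(dice = dice, acc = (counts$n_tp + counts$n_tn) / total, jac = jac)
}

#' Score a probability map against ground truth across thresholds
#'
#' The map is binarized as `map >= t` at each threshold and scored with
#' [segmentation_scores()].
#'
#' @param map Probability matrix in \[0, 1\].
#' @param gt Binary ground-truth matrix of the same shape.
#' @param thresholds Thresholds in (0, 1); default `0.1, 0.2, ..., 0.9`.
#' @param slide_id,class_label,method Metadata copied into each record.
#' @return Data frame with one row per threshold: slide_id, class_label,
#'   method, threshold, dice, acc, jac.
#' @export
threshold_sweep <- function(map, gt, thresholds = seq(0.1, 0.9, by = 0.1),
                            slide_id = "slide", class_label = NA_character_,
                            method = "method") {
  if (length(thresholds) == 0L) {
    stop_waveseg("empty threshold list", class = "waveseg_validation_error")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_waveseg("thresholds must lie in (0, 1)", class = "waveseg_validation_error")
  }
  rows <- lapply(thresholds, function(t) {
    sc <- segmentation_scores(confusion_counts((map >= t) * 1, gt))
    data.frame(slide_id = slide_id, class_label = class_label, method = method,
               threshold = t, dice = sc[["dice"]], acc = sc[["acc"]],
               jac = sc[["jac"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate evaluation records by method and class
#'
#' For each (method, class) pair and for each method overall (class `"ALL"`),
#' reports the mean and sample standard deviation (n - 1 denominator; 0 for a
#' single record) of dice, acc and jac.
#'
#' @param records Non-empty data frame of evaluation records.
#' @return Data frame with columns method, class_label, n, and
#'   `<metric>_mean` / `<metric>_sd` for the three metrics. Use [format_pm()]
#'   to render the conventional "mean ± sd" strings.
#' @export
aggregate_by_class <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_waveseg("records must be a non-empty data frame", class = "waveseg_validation_error")
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  summarize <- function(df, method, class_label) {
    data.frame(method = method, class_label = class_label, n = nrow(df),
               dice_mean = mean(df$dice), dice_sd = sd0(df$dice),
               acc_mean = mean(df$acc), acc_sd = sd0(df$acc),
               jac_mean = mean(df$jac), jac_sd = sd0(df$jac),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in unique(records$method)) {
    dm <- records[records$method == m, , drop = FALSE]
    for (cl in unique(dm$class_label)) {
      out[[length(out) + 1L]] <-
        summarize(dm[dm$class_label %in% cl, , drop = FALSE], m, cl)
    }
    out[[length(out) + 1L]] <- summarize(dm, m, "ALL")
  }
  do.call(rbind, out)
}

#' Seeded k-fold split by slide
#'
#' Fold assignment is by slide (never by tile) so tiles from one slide cannot
#' leak across folds.
#'
#' @param ids Vector of slide identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Data frame with columns `slide_id` and `fold`.
#' @export
kfold_split <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (k < 2L || k > n) {
    stop_waveseg("k must lie in [2, number of slides]", class = "waveseg_size_error")
  }
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  data.frame(slide_id = ids, fold = fold, stringsAsFactors = FALSE)
}

#' Region-of-interest area under quadratic tile-side scaling
#'
#' Physical tile (ROI) area scales with the square of the tile side at fixed
#' magnification: a configuration with side `tile_side` covers
#' `ref_area * (tile_side / ref_side)^2`.
#'
#' @param tile_side Tile side in pixels.
#' @param ref_side Reference tile side (default 1024).
#' @param ref_area Physical area covered by the reference tile, default
#'   6.25e-2 (square micrometres for a 1024-pixel tile at 20x).
#' @return Scaled area in the units of `ref_area`.
#' @export
scaled_roi_area <- function(tile_side, ref_side = 1024, ref_area = 6.25e-2) {
  ref_area * (tile_side / ref_side)^2
}

#' Input-size reduction of one sub-band relative to the RGB tile
#'
#' A single-level DWT sub-band of a compressed tile has half the side and one
#' channel, so a model sees `(side/2)^2 * 1` values instead of
#' `side^2 * channels`.
#'
#' @param tile_side RGB tile side (default 1024).
#' @param channels RGB channel count (default 3).
#' @return Percentage of the original input size.
#' @export
input_size_reduction_pct <- function(tile_side = 1024, channels = 3) {
  100 * (tile_side / 2)^2 / (tile_side^2 * channels)
}

#' Pixel-area ratio between two square tile sizes
#'
#' @param large,small Tile sides in pixels.
#' @return `large^2 / small^2`.
#' @export
tile_area_ratio <- function(large = 1024, small = 512) {
  (large / small)^2
}
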