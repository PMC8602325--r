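# Probability-map fusion: the wavelet-weighted ensemble (per-pixel weights
# from the DWT of the tissue mask, fused through the inverse DWT), the scalar
# weighted-average comparator, and the exhaustive grid search for the four
# band weights.

#' Ensemble weights for sub-band fusion
#'
#' Scalar weights for the LL, LH, HL and HH bands plus the offset `epsilon`
#' added to the mask-derived wavelet weights to remove zero terms. Defaults
#' are the grid-search optimum of the reference configuration: `w1 = 2.1`,
#' `w2 = 1.8`, `w3 = 1.8`, `w4 = 3.0`, `epsilon = 0.1`.
#'
#' @param w1,w2,w3,w4 Positive band weights (LL, LH, HL, HH).
#' @param epsilon Nonnegative offset.
#' @return An object of class `"ensemble_weights"`.
#' @export
ensemble_weights <- function(w1 = 2.1, w2 = 1.8, w3 = 1.8, w4 = 3.0,
                             epsilon = 0.1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4)
  if (any(w <= 0)) {
    stop_waveseg("band weights must be positive", class = "waveseg_validation_error")
  }
  if (epsilon < 0) {
    stop_waveseg("epsilon must be >= 0", class = "waveseg_validation_error")
  }
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, epsilon = epsilon),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("ensemble weights: W1=%.2f (LL), W2=%.2f (LH), W3=%.2f (HL), W4=%.2f (HH), epsilon=%.2f\n",
              x$w1, x$w2, x$w3, x$w4, x$epsilon))
  invisible(x)
}

#' Per-pixel wavelet weight maps from a tissue mask
#'
#' Takes the single-level Haar DWT of the binary tissue mask
#' `Y = (Y_LL, Y_LH, Y_HL, Y_HH)` and returns `m_band = W_band * (Y_band +
#' epsilon)` with the LL/LH/HL/HH bands weighted by `w1/w2/w3/w4`. Under the
#' mean-normalized convention `Y_LL` is 1 inside tissue and 0 in background
#' while the detail bands are nonzero only along tissue boundaries, so the
#' maps concentrate ensemble mass on tissue and discount detail-band output
#' away from edges.
#'
#' @param mask Binary tissue mask matrix (even dimensions), or a
#'   `"tissue_mask"` object.
#' @param weights An [ensemble_weights()] object.
#' @param convention DWT normalization, see [dwt2_haar()].
#' @return An object of class `"wavelet_weight_maps"`: list of half-resolution
#'   matrices `ll`, `lh`, `hl`, `hh`.
#' @export
wavelet_weight_maps <- function(mask, weights = ensemble_weights(),
                                convention = c("mean", "orthonormal")) {
  convention <- match.arg(convention)
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  if (!is_binary(mask)) {
    stop_waveseg("tissue mask must be binary", class = "waveseg_validation_error")
  }
  check_even_dims(mask, "tissue mask")
  y <- dwt2_haar(mask * 1.0, convention)
  e <- weights$epsilon
  structure(list(ll = weights$w1 * (y$ll + e),
                 lh = weights$w2 * (y$lh + e),
                 hl = weights$w3 * (y$hl + e),
                 hh = weights$w4 * (y$hh + e),
                 convention = convention),
            class = "wavelet_weight_maps")
}

#' Wavelet-weighted ensemble fusion of four sub-band probability maps
#'
#' Multiplies each half-resolution sub-band probability map elementwise by its
#' wavelet weight map and applies the inverse Haar DWT, yielding a
#' full-resolution map. The raw reconstruction can exceed \[0, 1\] (inside
#' tissue the LL weight is `w1 * (1 + epsilon)`), so the output is clipped by
#' default; `clip = FALSE` retains the raw values for exact-math work.
#'
#' @param r_ll,r_lh,r_hl,r_hh Half-resolution probability maps, equal shape.
#' @param maps A [wavelet_weight_maps()] object of the same shape.
#' @param clip Clip the output to \[0, 1\] (default TRUE).
#' @return Full-resolution probability matrix.
#' @export
wwe_fuse <- function(r_ll, r_lh, r_hl, r_hh, maps, clip = TRUE) {
  d <- dim(r_ll)
  for (x in list(r_lh, r_hl, r_hh, maps$ll)) {
    if (!identical(dim(x), d)) {
      stop_waveseg("sub-band maps and weight maps must share one shape",
                   class = "waveseg_shape_error")
    }
  }
  out <- idwt2_haar(subband_set(maps$ll * r_ll, maps$lh * r_lh,
                                maps$hl * r_hl, maps$hh * r_hh,
                                convention = maps$convention %||% "mean"))
  if (clip) out <- clamp01(out)
  out
}

#' Weighted-average ensemble of four sub-band probability maps
#'
#' The scalar comparator: a single weighted mean of the four maps,
#' `(w1*LL + w2*LH + w3*HL + w4*HH) / (w1+w2+w3+w4)`, computed at half
#' resolution and (by default) upsampled 2x by pixel replication so it can be
#' scored against the full-resolution annotation.
#'
#' @inheritParams wwe_fuse
#' @param weights An [ensemble_weights()] object (`epsilon` unused here).
#' @param upsample Replicate to full resolution (default TRUE).
#' @return Probability matrix (full- or half-resolution).
#' @export
wae_fuse <- function(r_ll, r_lh, r_hl, r_hh, weights = ensemble_weights(),
                     upsample = TRUE) {
  d <- dim(r_ll)
  for (x in list(r_lh, r_hl, r_hh)) {
    if (!identical(dim(x), d)) {
      stop_waveseg("sub-band maps must share one shape", class = "waveseg_shape_error")
    }
  }
  out <- (weights$w1 * r_ll + weights$w2 * r_lh +
            weights$w3 * r_hl + weights$w4 * r_hh) /
    (weights$w1 + weights$w2 + weights$w3 + weights$w4)
  if (upsample) out <- upsample2(out)
  out
}

# Per-slide full-resolution fusion contributions: the WWE output is linear in
# each band weight, R(w) = sum_b w_b * C_b with
# C_b = idwt(placing (Y_b + eps) * r_b in band b, zeros elsewhere).
# Precomputing C_b makes the grid search O(1) transforms per candidate.
wwe_contributions <- function(slide_maps, epsilon, convention = "mean") {
  y <- dwt2_haar(as_binary_mask(slide_maps$tissue) * 1.0, convention)
  z <- matrix(0, nrow(y$ll), ncol(y$ll))
  bands <- c("ll", "lh", "hl", "hh")
  rmaps <- list(slide_maps$r_ll, slide_maps$r_lh, slide_maps$r_hl, slide_maps$r_hh)
  lapply(seq_along(bands), function(b) {
    parts <- list(z, z, z, z)
    parts[[b]] <- (y[[bands[b]]] + epsilon) * rmaps[[b]]
    idwt2_haar(subband_set(parts[[1L]], parts[[2L]], parts[[3L]], parts[[4L]],
                           convention = convention))
  })
}

as_binary_mask <- function(x) {
  if (inherits(x, "tissue_mask")) x <- x$mask
  x
}

#' Mean Dice of the wavelet-weighted ensemble at given weights
#'
#' Fuses each evaluation slide with [wavelet_weight_maps()] and [wwe_fuse()],
#' binarizes at `threshold`, and averages the per-slide Dice. This is the
#' direct route through the fusion stack; [optimize_weights()] reaches the
#' same number through precomputed linear contributions, and the two must
#' agree.
#'
#' @param eval_set List of slides, each a list with half-resolution maps
#'   `r_ll`, `r_lh`, `r_hl`, `r_hh`, the full-resolution binary `tissue`
#'   mask, and the full-resolution binary ground truth `gt`.
#' @param weights An [ensemble_weights()] object.
#' @param threshold Binarization threshold (default 0.5).
#' @param convention DWT normalization.
#' @return Mean Dice over the evaluation slides.
#' @export
evaluate_weights <- function(eval_set, weights, threshold = 0.5,
                             convention = c("mean", "orthonormal")) {
  convention <- match.arg(convention)
  dice <- vapply(eval_set, function(s) {
    maps <- wavelet_weight_maps(as_binary_mask(s$tissue), weights, convention)
    fused <- wwe_fuse(s$r_ll, s$r_lh, s$r_hl, s$r_hh, maps)
    segmentation_scores(confusion_counts((fused >= threshold) * 1, s$gt))[["dice"]]
  }, 0)
  mean(dice)
}

#' Exhaustive grid search for the ensemble band weights
#'
#' Evaluates every combination `(w1, w2, w3, w4)` from `grid^4`, scoring each
#' by the mean Dice of the thresholded WWE output over the evaluation set,
#' and returns the argmax. Ties go to the lexicographically smallest
#' `(w1, w2, w3, w4)`. The default grid is `0.3, 0.6, ..., 3.0` (10 values,
#' 10^4 candidates).
#'
#' Internally the WWE output is decomposed into four precomputed per-band
#' contribution images (it is linear in each band weight), so each candidate
#' costs four scaled additions rather than a wavelet transform; clipping does
#' not change the thresholded mask for thresholds in (0, 1) and is skipped.
#'
#' @inheritParams evaluate_weights
#' @param grid Positive weight values to try on each band.
#' @param epsilon Offset for the weight maps.
#' @return An object of class `"weight_search"`: list with the best
#'   `weights`, its `score`, the full `table` (one row per candidate:
#'   w1..w4, mean_dice), `threshold` and `epsilon`.
#' @export
optimize_weights <- function(eval_set, grid = seq(0.3, 3.0, by = 0.3),
                             epsilon = 0.1, threshold = 0.5,
                             convention = c("mean", "orthonormal")) {
  convention <- match.arg(convention)
  if (length(eval_set) == 0L) {
    stop_waveseg("empty evaluation set", class = "waveseg_validation_error")
  }
  if (length(grid) == 0L || any(grid <= 0)) {
    stop_waveseg("grid must be non-empty and positive", class = "waveseg_validation_error")
  }
  grid <- sort(unique(grid))

  ns <- length(eval_set)
  contribs <- lapply(eval_set, wwe_contributions, epsilon = epsilon,
                     convention = convention)
  npix <- vapply(eval_set, function(s) length(s$gt), 0L)
  c1 <- unlist(lapply(contribs, `[[`, 1L), use.names = FALSE)
  c2 <- unlist(lapply(contribs, `[[`, 2L), use.names = FALSE)
  c3 <- unlist(lapply(contribs, `[[`, 3L), use.names = FALSE)
  c4 <- unlist(lapply(contribs, `[[`, 4L), use.names = FALSE)
  offsets <- cumsum(c(0L, npix))[seq_len(ns)]
  gt_idx <- lapply(seq_len(ns), function(s) offsets[s] + which(eval_set[[s]]$gt == 1))
  npos <- vapply(gt_idx, length, 0L)
  ranges <- lapply(seq_len(ns), function(s) offsets[s] + seq_len(npix[s]))

  g <- length(grid)
  ncand <- g^4
  score <- numeric(ncand)
  best <- -Inf
  best_w <- NULL
  i <- 0L
  for (w1 in grid) {
    p1 <- w1 * c1
    for (w2 in grid) {
      p12 <- p1 + w2 * c2
      for (w3 in grid) {
        p123 <- p12 + w3 * c3
        for (w4 in grid) {
          pred <- (p123 + w4 * c4) >= threshold
          dice <- vapply(seq_len(ns), function(s) {
            tp <- sum(pred[gt_idx[[s]]])
            pp <- sum(pred[ranges[[s]]])
            den <- pp + npos[s]
            if (den == 0) 1 else 2 * tp / den
          }, 0)
          i <- i + 1L
          score[i] <- mean(dice)
          if (score[i] > best) {
            best <- score[i]
            best_w <- c(w1, w2, w3, w4)
          }
        }
      }
    }
  }
  tab <- data.frame(w1 = rep(grid, each = g^3),
                    w2 = rep(rep(grid, each = g^2), times = g),
                    w3 = rep(rep(grid, each = g), times = g^2),
                    w4 = rep(grid, times = g^3),
                    mean_dice = score)
  structure(list(weights = ensemble_weights(best_w[1L], best_w[2L],
                                            best_w[3L], best_w[4L], epsilon),
                 score = best, table = tab,
                 threshold = threshold, epsilon = epsilon,
                 convention = convention, n_slides = ns),
            class = "weight_search")
}

#' @export
print.weight_search <- function(x, ...) {
  cat(sprintf("weight grid search over %d candidates on %d slides\n",
              nrow(x$table), x$n_slides))
  print(x$weights)
  cat(sprintf("mean Dice at threshold %.2f: %.4f\n", x$threshold, x$score))
  invisible(x)
}
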