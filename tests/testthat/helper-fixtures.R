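# Shared fixtures, all built in code. Small slides are cached per test run
# because several files exercise the same geometry.

.fixture_env <- new.env(parent = emptyenv())

small_params <- function(canvas = 256L, class_label = "ADENOCA", ...) {
  slide_params(width = canvas, height = canvas, class_label = class_label, ...)
}

small_slide <- function(canvas = 256L, seed = 3L, class_label = "ADENOCA") {
  key <- paste0("slide_", canvas, "_", seed, "_", class_label)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_slide(small_params(canvas, class_label), seed)
  }
  .fixture_env[[key]]
}

# A hand-built slide around a given mask: uniform mid-gray tissue everywhere,
# so the spatial oracle sees exactly `mask` as context.
manual_slide <- function(mask, class_label = "ADENOCA") {
  h <- nrow(mask)
  w <- ncol(mask)
  img <- array(0L, c(h, w, 3L))
  img[, , 1L] <- 180L
  img[, , 2L] <- 140L
  img[, , 3L] <- 170L
  structure(list(image = img, mask = mask, tissue = matrix(1L, h, w),
                 class_label = class_label, seed = 0L,
                 params = slide_params(width = w, height = h)),
            class = "waveseg_slide")
}

# Reference per-block Haar transform: explicit loop over 2x2 blocks,
# independent of the vectorized implementation.
haar_loop <- function(x) {
  h2 <- nrow(x) / 2
  w2 <- ncol(x) / 2
  out <- list(ll = matrix(0, h2, w2), lh = matrix(0, h2, w2),
              hl = matrix(0, h2, w2), hh = matrix(0, h2, w2))
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      a <- x[2 * i - 1, 2 * j - 1]
      b <- x[2 * i - 1, 2 * j]
      cc <- x[2 * i, 2 * j - 1]
      d <- x[2 * i, 2 * j]
      out$ll[i, j] <- (a + b + cc + d) / 4
      out$lh[i, j] <- (a - b + cc - d) / 4
      out$hl[i, j] <- (a + b - cc - d) / 4
      out$hh[i, j] <- (a - b - cc + d) / 4
    }
  }
  out
}

# Literal per-pixel scorer used as the independent metrics oracle.
scores_pixel_loop <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    acc = (tp + tn) / length(pred),
    jac = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn))
}

# Axis-aligned ellipse indicator, independent of the generator's internals.
ellipse_ref <- function(h, w, cy, cx, ry, rx) {
  yy <- ((seq_len(h) - cy) / ry)^2
  xx <- ((seq_len(w) - cx) / rx)^2
  outer(yy, xx, "+") <= 1
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
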