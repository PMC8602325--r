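# Brute-force Otsu: evaluate the between-class variance of every candidate
# split explicitly from first principles.
otsu_bruteforce <- function(values) {
  bins <- pmin(floor(values), 255)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    lo <- values[bins <= t]
    hi <- values[bins > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(bins[bins <= t]) - mean(bins[bins > t]))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

test_that("Otsu separates a bimodal sample and matches the exhaustive argmax", {
  thr <- otsu_threshold(c(rep(10, 50), rep(200, 50)))
  expect_gt(thr, 10)
  expect_lt(thr, 200)

  set.seed(21)
  for (i in 1:5) {
    x <- c(rnorm(400, 80, 12), rnorm(600, 190, 9))
    x <- pmin(pmax(x, 0), 255)
    expect_equal(floor(otsu_threshold(x)), otsu_bruteforce(x))
  }
})

test_that("constant samples are rejected as degenerate", {
  expect_error(otsu_threshold(rep(128, 100)), class = "waveseg_degenerate_error")
  expect_error(otsu_threshold(numeric(0)), class = "waveseg_degenerate_error")
})

test_that("tissue_mask recovers a dark disk on white and rejects flat images", {
  img <- array(255L, c(64, 64, 3))
  disk <- ellipse_ref(64, 64, 32, 32, 12, 12)
  for (k in 1:3) {
    ch <- img[, , k]
    ch[disk] <- 120L
    img[, , k] <- ch
  }
  tm <- tissue_mask(img)
  expect_equal(tm$mask, disk * 1)

  expect_error(tissue_mask(array(255L, c(16, 16, 3))),
               class = "waveseg_degenerate_error")
})

test_that("tissue_mask tracks the generator's painted tissue fraction", {
  s <- small_slide(256, seed = 3)
  tm <- tissue_mask(s$image)
  painted <- mean(s$tissue)
  expect_lt(abs(mean(tm$mask) - painted) / painted, 0.10)
})

test_that("two-point PCA maps the blue-dominant pixel to 1 and the red one to 0", {
  rgb <- array(0L, c(2, 2, 3))
  rgb[, , 1] <- matrix(c(200L, 200L, 100L, 100L), 2, 2)  # R
  rgb[, , 3] <- matrix(c(100L, 100L, 200L, 200L), 2, 2)  # B
  mask <- matrix(1, 2, 2)
  ct <- pca_compress(rgb, mask)
  expect_false(ct$degenerate)
  expect_equal(abs(ct$rotation), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_gte(sum(ct$rotation * c(-1, 1)), 0)
  expect_equal(ct$values, matrix(c(0, 0, 1, 1), 2, 2))
})

test_that("identical tissue pixels give a degenerate all-zero projection", {
  rgb <- array(150L, c(4, 4, 3))
  ct <- pca_compress(rgb, matrix(1, 4, 4))
  expect_true(ct$degenerate)
  expect_true(all(ct$values == 0))
  expect_error(pca_compress(rgb, matrix(0, 4, 4)), class = "waveseg_degenerate_error")
})

test_that("the projection variance equals the top eigenvalue of the sample covariance", {
  set.seed(8)
  n <- 1024
  r <- round(pmin(pmax(150 + rnorm(n, sd = 25) , 0), 255))
  b <- round(pmin(pmax(120 + 0.7 * (r - 150) + rnorm(n, sd = 12), 0), 255))
  rgb <- array(0L, c(32, 32, 3))
  rgb[, , 1] <- matrix(as.integer(r), 32, 32)
  rgb[, , 3] <- matrix(as.integer(b), 32, 32)
  ct <- pca_compress(rgb, matrix(1, 32, 32))

  # independent eigen-decomposition of the brute-force covariance
  cv <- stats::cov(cbind(r, b))
  top <- max(eigen(cv, symmetric = TRUE)$values)
  proj <- as.vector(ct$values)

  # the stored projections are min-max rescaled; recompute the raw ones from
  # the fitted center/rotation and compare both routes
  raw <- (r - ct$center[1]) * ct$rotation[1] + (b - ct$center[2]) * ct$rotation[2]
  expect_equal(stats::var(raw), top, tolerance = 1e-9)
  expect_equal((raw - min(raw)) / diff(range(raw)), proj, tolerance = 1e-12)

  # maximal-variance property against the axes
  expect_gte(stats::var(raw) + 1e-9, stats::var(r))
  expect_gte(stats::var(raw) + 1e-9, stats::var(b))
})

test_that("PCA is invariant to a constant (R,B) shift and exact on collinear data", {
  set.seed(14)
  r <- sample(60:130, 64, replace = TRUE)
  b <- sample(60:180, 64, replace = TRUE)
  mk <- function(r, b) {
    a <- array(0L, c(8, 8, 3))
    a[, , 1] <- matrix(as.integer(r), 8, 8)
    a[, , 3] <- matrix(as.integer(b), 8, 8)
    a
  }
  m <- matrix(1, 8, 8)
  c1 <- pca_compress(mk(r, b), m)
  c2 <- pca_compress(mk(r + 40, b + 40), m)
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
  expect_equal(c1$rotation, c2$rotation, tolerance = 1e-12)

  # points exactly on a line in (R,B): rank-1 covariance, zero residual
  b_lin <- 2 * r - 30
  cl <- pca_compress(mk(r, b_lin), m)
  raw <- (r - cl$center[1]) * cl$rotation[1] + (b_lin - cl$center[2]) * cl$rotation[2]
  recon_r <- cl$center[1] + raw * cl$rotation[1]
  recon_b <- cl$center[2] + raw * cl$rotation[2]
  expect_equal(recon_r, as.numeric(r), tolerance = 1e-9)
  expect_equal(recon_b, as.numeric(b_lin), tolerance = 1e-9)
})

test_that("grayscale conversion applies BT.601 weights rescaled to [0,1]", {
  mk1 <- function(r, g, b) {
    a <- array(0L, c(2, 2, 3))
    a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
    a
  }
  expect_equal(grayscale_convert(mk1(255L, 255L, 255L))$values, matrix(1, 2, 2))
  expect_equal(grayscale_convert(mk1(0L, 0L, 0L))$values, matrix(0, 2, 2))
  ct <- grayscale_convert(mk1(100L, 150L, 200L))
  expect_equal(ct$values[1, 1], (0.299 * 100 + 0.587 * 150 + 0.114 * 200) / 255,
               tolerance = 1e-12)
  expect_equal(ct$values[1, 1], 0.5519608, tolerance = 1e-6)
  expect_identical(ct$method, "gray")
})
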