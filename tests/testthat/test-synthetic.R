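test_that("slide generation is a pure function of (params, seed)", {
  p <- small_params(128)
  s1 <- generate_slide(p, seed = 7)
  s2 <- generate_slide(p, seed = 7)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_slide(p, seed = 8)
  expect_false(identical(s1$image, s3$image))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_slide(small_params(128), seed = 1))
  expect_identical(runif(1), before)
})

test_that("geometry invariants hold: even dims, registration, zero-region case", {
  s <- small_slide(256, seed = 1)
  expect_equal(dim(s$image)[1:2], dim(s$mask))
  expect_true(all(s$mask %in% c(0L, 1L)))
  expect_true(all(dim(s$mask) %% 2 == 0))
  # tumor is only ever drawn inside painted tissue
  expect_true(all(s$tissue[s$mask == 1] == 1))

  s0 <- generate_slide(small_params(128, n_tumor = 0), seed = 1)
  expect_true(all(s0$mask == 0))

  expect_error(slide_params(width = 255, height = 256), class = "waveseg_size_error")
})

test_that("tumor-pixel fraction lands in the configured range", {
  for (seed in c(3, 17)) {
    p <- small_params(256, tumor_frac = c(0.05, 0.25))
    s <- generate_slide(p, seed)
    frac <- sum(s$mask) / length(s$mask)
    expect_gte(frac, 0.05)
    expect_lte(frac, 0.25)
  }
})

test_that("color structure matches H&E: backgrounds, stroma, nuclei, R-B coupling", {
  s <- small_slide(256, seed = 3)
  bg <- s$tissue == 0
  for (k in 1:3) expect_true(all(s$image[, , k][bg] >= 230))

  r <- s$image[, , 1][s$tissue == 1]
  g <- s$image[, , 2][s$tissue == 1]
  b <- s$image[, , 3][s$tissue == 1]
  expect_gt(stats::cor(r, b), stats::cor(r, g))

  # split tissue by luminance: bright pixels are stroma, dark ones nuclei
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  stroma <- lum > stats::quantile(lum, 0.7)
  nuclei <- lum < stats::quantile(lum, 0.2)
  expect_gt(mean(r[stroma]), mean(g[stroma]))  # pink
  expect_gt(mean(b[stroma]), mean(g[stroma]))
  expect_gt(mean(b[nuclei]), mean(r[nuclei]))  # blue-purple
  expect_gt(mean(r[nuclei]), mean(g[nuclei]))
})

test_that("tumor texture frequency content differs across classes", {
  hf_energy <- function(cl) {
    s <- generate_slide(small_params(256, class_label = cl,
                                     tumor_frac = c(0.15, 0.3)), seed = 5)
    gray <- grayscale_convert(s$image)$values
    sb <- dwt2_haar(gray)
    half_tumor <- waveseg:::downsample_majority(s$mask) == 1
    mean(sb$hh[half_tumor]^2)
  }
  # speckle (TAH) carries far more diagonal-detail energy than smooth blobs
  expect_gt(hf_energy("TAH"), 2 * hf_energy("HYPERP"))
})

test_that("cohorts cycle classes, respect proportions, and are reproducible", {
  co <- generate_cohort(5, small_params(128), seed = 0)
  expect_length(co$slides, 5L)
  expect_setequal(co$index$class_label,
                  c("ADENOCA", "TAH", "TAL", "CARCINOID", "HYPERP"))
  co2 <- generate_cohort(5, small_params(128), seed = 0)
  expect_identical(co$slides[[3]]$image, co2$slides[[3]]$image)

  co39 <- generate_cohort(39, small_params(64, n_tumor = 1), seed = 1)
  counts <- table(co39$index$class_label)
  expect_true(all(abs(counts - 39 / 5) <= 1))

  cop <- generate_cohort(10, small_params(64, n_tumor = 1), seed = 1,
                         proportions = c(ADENOCA = 0.5, TAH = 0.3, HYPERP = 0.2))
  tp <- table(cop$index$class_label)
  expect_equal(as.integer(tp[c("ADENOCA", "TAH", "HYPERP")]), c(5L, 3L, 2L))

  expect_error(generate_cohort(0), class = "waveseg_size_error")
})

test_that("cohorts round-trip through disk with an index CSV", {
  co <- generate_cohort(2, small_params(64, n_tumor = 1), seed = 4)
  dir <- withr::local_tempdir()
  idx <- write_cohort(co, dir)
  expect_true(all(file.exists(idx$image_path, idx$mask_path)))
  expect_identical(read_image(idx$image_path[1]), co$slides[[1]]$image)
  expect_identical(read_mask(idx$mask_path[2]), co$slides[[2]]$mask)
  tab <- utils::read.csv(file.path(dir, "index.csv"))
  expect_equal(nrow(tab), 2L)
})

test_that("probability fixtures: exact at zero noise, clamped-Gaussian mean otherwise", {
  m <- random_mask(32, 32, 0.4)
  expect_identical(make_probability_fixture(m, 0, seed = 9), m * 1.0)

  ones <- matrix(1, 64, 64)
  f <- make_probability_fixture(ones, 0.1, seed = 2)
  expect_true(all(f >= 0 & f <= 1))

  # mean over a ones-region of clamp(1 + N(0, s)) is 1 - s/sqrt(2*pi)
  # (the upper clamp removes the positive half of the noise), with
  # sd sqrt(s^2 * (1/2 - 1/(2*pi))) per pixel
  half <- matrix(0, 64, 64)
  half[, 1:32] <- 1
  f2 <- make_probability_fixture(half, 0.1, seed = 2)
  n1 <- sum(half == 1)
  expected <- 1 - 0.1 / sqrt(2 * pi)
  se <- sqrt(0.1^2 * (0.5 - 1 / (2 * pi))) / sqrt(n1)
  expect_lt(abs(mean(f2[half == 1]) - expected), 4 * se)

  expect_error(make_probability_fixture(matrix(0.5, 2, 2), 0),
               class = "waveseg_format_error")
  expect_error(make_probability_fixture(random_mask(4, 4), -1),
               class = "waveseg_size_error")
})
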