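test_that("weight maps on constant masks follow the (Y + eps) * W arithmetic", {
  w <- ensemble_weights()  # 2.1, 1.8, 1.8, 3.0, eps 0.1
  ones <- wavelet_weight_maps(matrix(1, 8, 8), w)
  expect_true(all(abs(ones$ll - 2.31) < 1e-12))
  expect_true(all(abs(ones$lh - 0.18) < 1e-12))
  expect_true(all(abs(ones$hl - 0.18) < 1e-12))
  expect_true(all(abs(ones$hh - 0.30) < 1e-12))

  zeros <- wavelet_weight_maps(matrix(0, 8, 8), w)
  expect_true(all(abs(zeros$ll - 0.21) < 1e-12))
  expect_true(all(abs(zeros$lh - 0.18) < 1e-12))
  expect_true(all(abs(zeros$hh - 0.30) < 1e-12))
})

test_that("half-plane masks move weight only at the tissue boundary", {
  m <- matrix(0, 8, 8)
  m[, 1:3] <- 1  # boundary inside blocks covering columns 3:4
  maps <- wavelet_weight_maps(m, ensemble_weights())
  expect_true(all(abs(maps$ll[, 1] - 2.31) < 1e-12))
  expect_true(all(abs(maps$ll[, 3:4] - 0.21) < 1e-12))
  expect_true(all(abs(maps$lh[, c(1, 3, 4)] - 0.18) < 1e-12))
  expect_true(all(abs(maps$lh[, 2] - 1.8 * 0.6) < 1e-12))  # (0.5 + 0.1) * 1.8

  expect_error(wavelet_weight_maps(matrix(0.5, 8, 8), ensemble_weights()),
               class = "waveseg_validation_error")
  expect_error(ensemble_weights(w1 = 0), class = "waveseg_validation_error")
  expect_error(ensemble_weights(epsilon = -0.1), class = "waveseg_validation_error")
})

test_that("unit weight maps make WWE o DWT the identity on any [0,1] image", {
  # zero mask, eps = 1, all W = 1 forces every weight map to 1
  unit <- wavelet_weight_maps(matrix(0, 16, 16), ensemble_weights(1, 1, 1, 1, 1))
  expect_true(all(unit$ll == 1) && all(unit$hh == 1))
  set.seed(4)
  g <- matrix(runif(256), 16, 16)
  sb <- dwt2_haar(g)
  out <- wwe_fuse(sb$ll, sb$lh, sb$hl, sb$hh, unit)
  expect_lt(max(abs(out - g)), 1e-9)
})

test_that("constant-field WWE arithmetic and clipping behave as specified", {
  maps <- wavelet_weight_maps(matrix(1, 8, 8), ensemble_weights())
  z <- matrix(0, 4, 4)
  raw <- wwe_fuse(matrix(0.4, 4, 4), z, z, z, maps, clip = FALSE)
  expect_true(all(abs(raw - 0.924) < 1e-12))

  over <- wwe_fuse(matrix(0.9, 4, 4), z, z, z, maps)  # 2.31 * 0.9 > 1
  expect_true(all(over == 1))
  expect_true(all(wwe_fuse(z, z, z, z, maps) == 0))

  expect_error(wwe_fuse(matrix(0, 4, 4), z, z, matrix(0, 2, 2), maps),
               class = "waveseg_shape_error")
})

test_that("WWE and WAE outputs always lie in [0,1]", {
  set.seed(6)
  for (i in 1:5) {
    mask <- random_mask(16, 16, 0.6)
    maps <- wavelet_weight_maps(mask, ensemble_weights())
    r <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
    fw <- wwe_fuse(r[[1]], r[[2]], r[[3]], r[[4]], maps)
    fa <- wae_fuse(r[[1]], r[[2]], r[[3]], r[[4]])
    expect_true(all(fw >= 0 & fw <= 1))
    expect_true(all(fa >= 0 & fa <= 1))
    expect_equal(dim(fw), c(16L, 16L))
    expect_equal(dim(fa), c(16L, 16L))
  }
})

test_that("WAE matches its closed form and is monotone in each input", {
  p <- matrix(0.42, 4, 4)
  expect_equal(wae_fuse(p, p, p, p, ensemble_weights(0.9, 1.7, 2.2, 0.4)),
               matrix(0.42, 8, 8), tolerance = 1e-12)

  mk <- function(v) matrix(v, 4, 4)
  out <- wae_fuse(mk(0.8), mk(0.4), mk(0.2), mk(0.6), ensemble_weights())
  expect_equal(out[1, 1], (2.1 * 0.8 + 1.8 * 0.4 + 1.8 * 0.2 + 3.0 * 0.6) / 8.7,
               tolerance = 1e-12)
  expect_equal(out[1, 1], 0.5241379, tolerance = 1e-7)

  eq <- wae_fuse(mk(0.1), mk(0.3), mk(0.5), mk(0.7), ensemble_weights(1, 1, 1, 1))
  expect_equal(eq[1, 1], 0.4, tolerance = 1e-12)

  base <- wae_fuse(mk(0.3), mk(0.3), mk(0.3), mk(0.3))
  bump <- wae_fuse(mk(0.5), mk(0.3), mk(0.3), mk(0.3))
  expect_true(all(bump >= base))
})

# Small controlled evaluation set: noisy sub-band fixtures over slides whose
# masks and tissue we control exactly.
tiny_eval_set <- function(n = 2, side = 32, noise = 0.15, seed = 1) {
  lapply(seq_len(n), function(i) {
    gt <- matrix(0L, side, side)
    gt[waveseg:::upsample2(ellipse_ref(side / 2, side / 2, side / 4, side / 4,
                                       side / 6, side / 8))] <- 1L
    half <- waveseg:::downsample_majority(gt) * 1.0
    list(r_ll = make_probability_fixture(half, 0, seed),
         r_lh = make_probability_fixture(half, noise, seed + 10 * i),
         r_hl = make_probability_fixture(half, noise, seed + 20 * i),
         r_hh = make_probability_fixture(half, noise, seed + 30 * i),
         tissue = matrix(1L, side, side), gt = gt)
  })
}

test_that("the grid search returns the single candidate on a degenerate grid", {
  es <- tiny_eval_set()
  sr <- optimize_weights(es, grid = 1.0)
  expect_equal(unlist(sr$weights[c("w1", "w2", "w3", "w4")]),
               c(w1 = 1, w2 = 1, w3 = 1, w4 = 1))
  expect_equal(nrow(sr$table), 1L)
  expect_equal(sr$score, evaluate_weights(es, sr$weights), tolerance = 1e-12)
})

test_that("a candidate achieving Dice 1 by construction is selected", {
  # noise-free fixtures: large enough w1 reconstructs the mask exactly
  es <- tiny_eval_set(noise = 0)
  sr <- optimize_weights(es, grid = c(0.3, 2.1))
  expect_equal(sr$score, 1.0)
  expect_equal(evaluate_weights(es, sr$weights), 1.0)
})

test_that("every grid combination is scored and both evaluation routes agree", {
  es <- tiny_eval_set(noise = 0.25)
  grid <- c(0.5, 1.0, 2.0)
  sr <- optimize_weights(es, grid = grid)
  expect_equal(nrow(sr$table), length(grid)^4)
  expect_false(any(duplicated(sr$table[, 1:4])))

  # the table itself must match the direct fusion route, row by row
  set.seed(33)
  for (i in sample(nrow(sr$table), 6)) {
    w <- ensemble_weights(sr$table$w1[i], sr$table$w2[i],
                          sr$table$w3[i], sr$table$w4[i], sr$epsilon)
    expect_equal(sr$table$mean_dice[i], evaluate_weights(es, w),
                 tolerance = 1e-12)
  }
  expect_equal(max(sr$table$mean_dice), sr$score, tolerance = 1e-15)
})

test_that("the search is invariant to evaluation-set order and breaks ties low", {
  es <- tiny_eval_set(n = 3, noise = 0.2)
  sr1 <- optimize_weights(es, grid = c(0.6, 1.2))
  sr2 <- optimize_weights(rev(es), grid = c(0.6, 1.2))
  expect_equal(sr1$weights, sr2$weights)
  expect_equal(sr1$score, sr2$score, tolerance = 1e-15)

  # all-equal scores (flat search): lexicographically smallest candidate wins
  flat <- tiny_eval_set(n = 1, noise = 0)
  srf <- optimize_weights(flat, grid = c(2.0, 3.0))
  expect_equal(unlist(srf$weights[c("w1", "w2", "w3", "w4")]),
               c(w1 = 2, w2 = 2, w3 = 2, w4 = 2))

  expect_error(optimize_weights(list(), grid = 1), class = "waveseg_validation_error")
  expect_error(optimize_weights(es, grid = numeric(0)),
               class = "waveseg_validation_error")
})
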