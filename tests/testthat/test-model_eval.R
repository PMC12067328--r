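test_that("relative error identities and worked example", {
  v <- seeded_volume(c(8, 8, 8), seed = 1)
  expect_equal(relative_error(v, v), 0)
  # RE(k*real, real) = |k - 1|
  half <- volume3d(v$data / 2)
  expect_equal(relative_error(half, v), 0.5, tolerance = 1e-12)
  dbl <- volume3d(pmin(v$data * 2, 255))
  v_small <- volume3d(array(100, c(4, 4, 4)))
  expect_equal(relative_error(volume3d(v_small$data * 2), v_small), 1)
  # 4-voxel worked example: |1-2|+|2-2|+|3-2|+|4-2| over 8
  gen <- array(c(1, 2, 3, 4), c(1, 2, 2))
  real <- array(2, c(1, 2, 2))
  expect_equal(relative_error(gen, real), 0.5)
  expect_error(relative_error(gen, array(0, c(1, 2, 2))),
               class = "airgap3d_undefined_normalization")
})

test_that("psnr closed forms, infinity sentinel and monotonicity", {
  v <- seeded_volume(c(8, 8, 8), seed = 2)
  expect_identical(psnr(v, v), Inf)
  z <- volume3d(array(0, c(4, 4, 4)))
  m <- volume3d(array(255, c(4, 4, 4)))
  expect_equal(psnr(z, m), 0)
  one_off <- volume3d(v$data + 1)          # uniform difference of 1
  expect_equal(psnr(one_off, v), 10 * log10(255^2), tolerance = 1e-9)
  # decreases with noise amplitude
  set.seed(4)
  noise <- array(rnorm(8^3), c(8, 8, 8))
  vals <- vapply(c(1, 4, 16), function(a)
    psnr(volume3d(pmin(pmax(v$data + a * noise, 0), 255)), v), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("ssim identities, symmetry and the constant-pair closed form", {
  v <- seeded_volume(c(8, 8, 8), seed = 3)
  expect_equal(ssim(v, v), 1)
  w <- seeded_volume(c(8, 8, 8), seed = 4)
  expect_equal(ssim(v, w), ssim(w, v), tolerance = 1e-12)
  expect_lt(ssim(v, w), 1)
  expect_gte(ssim(v, w), -1)
  # constant volumes 100 vs 200: variance terms cancel, luminance remains
  a <- volume3d(array(100, c(4, 4, 4)))
  b <- volume3d(array(200, c(4, 4, 4)))
  c1 <- (0.01 * 255)^2
  expect_equal(ssim(a, b), (2 * 100 * 200 + c1) / (100^2 + 200^2 + c1),
               tolerance = 1e-12)
})

test_that("checkpoint evaluation ranks and selects by rank sum", {
  # fabricate three checkpoints via stub generator models is heavy; instead
  # exercise the ranking on a constructed table through the public path:
  # three trivial one-layer models cannot be faked, so rank the table rule
  # directly on synthetic metric outcomes using evaluate_checkpoints on
  # real (tiny) models is covered in the training test; here check the
  # dominance property with two identical models differing only in epoch.
  pairs <- phantom_pairs(2, edge = 16L, seed0 = 300L)
  gs <- tiny_gen_spec(16L)
  m1 <- build_generator(gs, init_seed = 1)
  m1$meta$epoch <- 0L
  m2 <- build_generator(gs, init_seed = 1)
  m2$meta$epoch <- 10L
  ev <- evaluate_checkpoints(list(m1, m2), pairs)
  # identical weights -> identical metrics -> tie broken toward later epoch
  expect_equal(ev$table$re_mean[1], ev$table$re_mean[2])
  expect_equal(ev$selected, 10)
  expect_error(evaluate_checkpoints(list(), pairs),
               class = "airgap3d_parameter_error")
  expect_error(evaluate_checkpoints(list(m1), list()),
               class = "airgap3d_parameter_error")
})

test_that("rank-sum winner matches hand computation on a known table", {
  # hand-rankable metric table, checked through the internal ranking rule:
  # re:   0.10 0.05 0.07  -> ranks 3 1 2
  # psnr: 20   25   24    -> ranks 3 1 2
  # ssim: 0.80 0.90 0.85  -> ranks 3 1 2
  tab <- data.frame(re_mean = c(0.10, 0.05, 0.07),
                    psnr_mean_db = c(20, 25, 24),
                    ssim_mean = c(0.80, 0.90, 0.85))
  rank_sum <- rank(tab$re_mean) + rank(-tab$psnr_mean_db) + rank(-tab$ssim_mean)
  expect_equal(which.min(rank_sum), 2)
  expect_equal(rank_sum, c(9, 3, 6))
})
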