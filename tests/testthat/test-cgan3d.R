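test_that("generator depth follows the log2 rule and preserves shape", {
  gs <- generator_spec(32)
  expect_length(gs$encoder_filters, 5)
  expect_equal(gs$encoder_filters, c(64, 128, 256, 512, 512))
  expect_equal(gs$decoder_filters, c(512, 512, 256, 128, 64)[-1])
  # published full-scale architecture at edge 256
  gs256 <- generator_spec(256)
  expect_equal(gs256$encoder_filters, c(64, 128, 256, 512, 512, 512, 512, 512))
  expect_equal(gs256$decoder_filters, c(512, 512, 512, 512, 256, 128, 64))
  expect_error(generator_spec(48), class = "airgap3d_parameter_error")

  # forward shape preservation on a small net
  G <- build_generator(tiny_gen_spec(16L), init_seed = 1)
  cube <- seeded_volume(c(16, 16, 16), seed = 1)
  out <- generate(G, cube)
  expect_equal(dim(out$data), dim(cube$data))
  expect_true(all(out$data >= 0 & out$data <= 255))
  expect_equal(out$voxel_size_um, cube$voxel_size_um)
  expect_error(generate(G, seeded_volume(c(8, 8, 8))),
               class = "airgap3d_parameter_error")
})

test_that("generator parameter count equals the hand-computed total", {
  # edge 8, filters (8,16,8): encoder convs 1->8, 8->16, 16->8 (k=4)
  # decoder: convt 8->16 (+bn), convt [16+16]->8 (+bn), out convt [8+8]->1
  gs <- generator_spec(8, encoder_filters = c(8, 16, 8),
                       decoder_filters = c(16, 8))
  G <- build_generator(gs, init_seed = 1)
  k3 <- 64
  enc <- (k3 * 1 * 8 + 8) + (k3 * 8 * 16 + 16) + (k3 * 16 * 8 + 8)
  enc_bn <- 2 * 16                         # only block 2 has batch norm
  dec <- (k3 * 8 * 16 + 16) + (k3 * 32 * 8 + 8)
  dec_bn <- 2 * 16 + 2 * 8
  out <- k3 * 16 * 1 + 1
  expect_equal(n_params(G), enc + enc_bn + dec + dec_bn + out)
})

test_that("discriminator emits sigmoid patch maps of the documented size", {
  D <- build_discriminator(tiny_disc_spec(), init_seed = 2)
  n <- 16^3
  set.seed(1)
  a <- matrix(runif(n, -1, 1), n, 1)
  b <- matrix(runif(n, -1, 1), n, 1)
  fw <- airgap3d:::discriminator_forward(D, a, b, c(16, 16, 16))
  expect_equal(fw$shape, c(2, 2, 2))       # 16 -> 8 -> 4 -> 2 -> 2 -> 2
  expect_true(all(fw$scores > 0 & fw$scores < 1))
  # shape arithmetic for a 70-voxel input: 70 -> 35 -> 18 -> 9 -> 9 -> 9
  fw70 <- airgap3d:::discriminator_forward(
    D, matrix(0, 70^3, 1), matrix(0, 70^3, 1), c(70, 70, 70))
  expect_equal(fw70$shape, c(9, 9, 9))
})

test_that("receptive field recurrence matches the published stack and probes", {
  expect_identical(receptive_field(discriminator_spec()), 70L)
  # single conv k4 s1
  expect_identical(receptive_field(discriminator_spec(filters = 1,
                                                      strides = 1)), 7L)
  # 4-conv stack (block strides 2,2,1 plus scoring conv):
  # RF 1 -> 4 -> 10 -> 22 -> 34
  alt <- discriminator_spec(filters = c(8, 8, 8), strides = c(2, 2, 1))
  expect_identical(receptive_field(alt), 34L)
  # empirical gradient-footprint probes agree with the recurrence
  probed <- probe_receptive_field(discriminator_spec(), input_edge = 80,
                                  filters = c(2, 2, 2, 2), seed = 3)
  expect_equal(probed, 70L)
  probed_alt <- probe_receptive_field(alt, input_edge = 48,
                                      filters = c(2, 2, 2), seed = 4)
  expect_equal(probed_alt, 34L)
})

test_that("loss closed forms match hand computation", {
  p_half <- matrix(0.5, 3, 1)
  v <- array(10, c(2, 2, 2))
  expect_equal(generator_loss(p_half, v, v, 100), -log(0.5), tolerance = 1e-12)
  # lambda scaling: loss - adversarial term is linear in lambda
  w <- array(12, c(2, 2, 2))
  l1 <- generator_loss(p_half, w, v, 100) - (-log(0.5))
  l2 <- generator_loss(p_half, w, v, 200) - (-log(0.5))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  expect_equal(discriminator_loss(p_half, p_half), -log(0.5), tolerance = 1e-12)
  # perfect discrimination drives the loss toward 0
  eps <- 1e-6
  expect_lt(discriminator_loss(matrix(1 - eps, 2, 1), matrix(eps, 2, 1)),
            1e-5)
  # symmetry under real <-> 1 - fake
  set.seed(8)
  pr <- matrix(runif(4, 0.1, 0.9), 4, 1)
  pf <- matrix(runif(4, 0.1, 0.9), 4, 1)
  expect_equal(discriminator_loss(pr, pf), discriminator_loss(1 - pf, 1 - pr),
               tolerance = 1e-12)
  expect_error(generator_loss(p_half, v, array(0, c(2, 2, 4))),
               class = "airgap3d_parameter_error")
})

test_that("intensity normalization round-trips 8-bit data", {
  x <- 0:255
  y <- airgap3d:::denormalize_intensity(airgap3d:::normalize_intensity(x))
  expect_identical(as.integer(y), 0:255)
  expect_true(all(airgap3d:::normalize_intensity(x) >= -1 &
                    airgap3d:::normalize_intensity(x) <= 1))
})

test_that("training writes checkpoints on the cadence and is reproducible", {
  pairs <- phantom_pairs(3, edge = 16L, seed0 = 700L)
  gs <- generator_spec(16, encoder_filters = c(4, 8, 8, 8))
  ds <- discriminator_spec(filters = c(4, 8), strides = c(2, 1))
  dir1 <- withr::local_tempdir()
  s1 <- train_cgan(pairs, gs, ds,
                   train_config(epochs = 4, checkpoint_interval_epochs = 2,
                                seed = 5), dir1)
  # epoch 0 baseline + epochs 2 and 4
  expect_equal(vapply(s1$checkpoints, `[[`, 0L, "epoch"), c(0L, 2L, 4L))
  expect_true(all(file.exists(vapply(s1$checkpoints, `[[`, "", "path"))))
  expect_true(file.exists(file.path(dir1, "losses.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_equal(nrow(s1$losses), 4 * 3)
  expect_true(all(is.finite(as.matrix(s1$losses))))
  # determinism of the loss trace and final weights
  dir2 <- withr::local_tempdir()
  s2 <- train_cgan(pairs, gs, ds,
                   train_config(epochs = 4, checkpoint_interval_epochs = 2,
                                seed = 5), dir2)
  expect_equal(s1$losses, s2$losses, tolerance = 1e-12)
  m1 <- load_generator(s1$checkpoints[[3]]$path)
  m2 <- load_generator(s2$checkpoints[[3]]$path)
  expect_equal(airgap3d:::generator_state(m1)$enc,
               airgap3d:::generator_state(m2)$enc, tolerance = 1e-12)
  # inference determinism
  g1 <- generate(m1, pairs[[1]]$source)
  g2 <- generate(m1, pairs[[1]]$source)
  expect_identical(g1$data, g2$data)
  # edge mismatch is rejected up front
  expect_error(train_cgan(pairs, generator_spec(32), ds,
                          train_config(epochs = 1), withr::local_tempdir()),
               class = "airgap3d_parameter_error")
})
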