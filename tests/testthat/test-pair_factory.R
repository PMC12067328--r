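test_that("cube extraction enumerates the stride lattice", {
  vol <- seeded_volume(c(64, 64, 64), seed = 1)
  cubes <- extract_cubes(vol, 32, 16)
  expect_length(cubes, 27)                 # origins 0,16,32 per axis
  origins <- t(vapply(cubes, function(cb) cb$origin, integer(3)))
  expect_equal(nrow(unique(origins)), 27)
  expect_true(all(origins %% 16 == 0))
  expect_true(all(origins <= 32))
  # non-overlapping tiling
  cubes2 <- extract_cubes(vol, 32, 32)
  expect_length(cubes2, 8)
  # single partial-fit cube
  vol3 <- seeded_volume(c(40, 40, 40), seed = 2)
  expect_length(extract_cubes(vol3, 32, 32), 1)
  expect_error(extract_cubes(vol3, 48), class = "airgap3d_parameter_error")
  # extracted content matches the parent volume
  cb <- cubes[[14]]
  o <- cb$origin - vol$origin
  expect_identical(cb$data, vol$data[o[1] + 1:32, o[2] + 1:32, o[3] + 1:32])
})

test_that("artifact-cube classification ignores sub-threshold salt noise", {
  x <- array(128, c(32, 32, 32))
  x[cbind(c(4, 16, 28), c(4, 16, 28), c(4, 16, 28))] <- 255  # 3 isolated voxels
  cl <- classify_artifact_cube(volume3d(x), mask_params(min_component_vox = 50))
  expect_false(cl$is_artifact)
  expect_equal(cl$score, 0)
  # clean phantom scores exactly zero
  ph <- generate_lung_phantom(phantom_spec(shape = c(32, 32, 32), seed = 4))
  cl2 <- classify_artifact_cube(ph)
  expect_false(cl2$is_artifact)
  expect_equal(cl2$score, 0)
  # an injected bubble above the component threshold flips the decision
  inj <- inject_air_artifacts(ph, artifact_spec(n_bubbles = 1,
                                                radius_range_vox = c(4, 4),
                                                shape_irregularity = 0,
                                                seed = 1))
  cl3 <- classify_artifact_cube(inj$volume)
  expect_true(cl3$is_artifact)
  expect_gt(cl3$score, 0)
})

test_that("air mask recovers ground-truth voids with high recall", {
  ph <- generate_lung_phantom(phantom_spec(shape = c(48, 48, 48), seed = 21))
  inj <- inject_air_artifacts(ph, artifact_spec(n_bubbles = 2,
                                                rim_thickness_vox = 2,
                                                seed = 9))
  m <- make_air_mask(inj$volume, mask_params(opening_radius_vox = 1,
                                             dilation_radius_vox = 2))
  recall <- sum(m & inj$void) / sum(inj$void)
  expect_gte(recall, 0.95)
})

test_that("mask of an extreme block equals its ball dilation", {
  x <- array(128, c(32, 32, 32))
  x[14:18, 14:18, 14:18] <- 0              # 5^3 void block
  m <- make_air_mask(volume3d(x), mask_params(opening_radius_vox = 1,
                                              dilation_radius_vox = 2,
                                              min_component_vox = 50))
  # independent morphology: open(1) keeps the eroded-dilated 5-block
  # (it contains a ball of radius 1), then dilate by a 2-ball
  ref <- array(FALSE, c(32, 32, 32))
  ref[14:18, 14:18, 14:18] <- TRUE
  ref_d <- binary_dilate(binary_open(ref, 1), 2)
  expect_identical(m, ref_d)
  # brute-force size of the 2-ball dilation of the opened block
  blk <- arrayInd(which(binary_open(ref, 1)), dim(ref))
  cnt <- 0
  for (i in seq_len(length(ref))) {
    p <- arrayInd(i, dim(ref))
    if (min(rowSums(sweep(blk, 2, p)^2)) <= 4) cnt <- cnt + 1
  }
  expect_equal(sum(m), cnt)
  # no extremes -> empty mask
  expect_false(any(make_air_mask(volume3d(array(128, c(16, 16, 16))))))
})

test_that("mask grows monotonically with the dilation radius", {
  ph <- generate_lung_phantom(phantom_spec(shape = c(32, 32, 32), seed = 5))
  inj <- inject_air_artifacts(ph, artifact_spec(n_bubbles = 1, seed = 2))
  prev <- make_air_mask(inj$volume, mask_params(dilation_radius_vox = 1))
  for (r in 2:3) {
    cur <- make_air_mask(inj$volume, mask_params(dilation_radius_vox = r))
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("transplant conservation holds voxel-wise on random fixtures", {
  set.seed(77)
  for (i in 1:100) {
    donor <- seeded_volume(c(16, 16, 16), seed = i)
    recipient <- seeded_volume(c(16, 16, 16), seed = i + 500)
    mask <- array(runif(16^3) < runif(1, 0.05, 0.5), c(16, 16, 16))
    pair <- transplant_artifacts(donor, recipient, mask)
    expect_identical(pair$source$data[mask], donor$data[mask])
    expect_identical(pair$source$data[!mask], recipient$data[!mask])
    expect_identical(pair$target$data, recipient$data)
  }
})

test_that("transplant handles empty and full masks", {
  donor <- seeded_volume(c(8, 8, 8), seed = 1)
  recipient <- seeded_volume(c(8, 8, 8), seed = 2)
  none <- transplant_artifacts(donor, recipient, array(FALSE, c(8, 8, 8)))
  expect_identical(none$source$data, none$target$data)
  all_m <- transplant_artifacts(donor, recipient, array(TRUE, c(8, 8, 8)))
  expect_identical(all_m$source$data, donor$data)
  expect_error(transplant_artifacts(donor, seeded_volume(c(4, 4, 4)),
                                    array(TRUE, c(8, 8, 8))),
               class = "airgap3d_parameter_error")
})

test_that("training-set factory is seeded, self-consistent and well-formed", {
  cleans <- lapply(1:3, function(i) generate_lung_phantom(
    phantom_spec(shape = c(24, 24, 24), pore_correlation_length_vox = 3,
                 seed = i)))
  arts <- lapply(1:3, function(i) {
    inj <- inject_air_artifacts(cleans[[i]],
                                artifact_spec(n_bubbles = 1,
                                              radius_range_vox = c(3, 4),
                                              rim_thickness_vox = 1,
                                              shape_irregularity = 0,
                                              seed = i + 10))
    inj$volume
  })
  set1 <- build_training_set(cleans, arts, n_pairs = 9, pairing_seed = 3)
  set2 <- build_training_set(cleans, arts, n_pairs = 9, pairing_seed = 3)
  expect_length(set1, 9)
  prov <- vapply(set1, function(p)
    paste(p$provenance$donor, p$provenance$recipient), "")
  expect_identical(prov, vapply(set2, function(p)
    paste(p$provenance$donor, p$provenance$recipient), ""))
  for (p in set1) {
    expect_identical(dim(p$source$data), dim(p$target$data))
    expect_identical(p$source$data[!p$mask], p$target$data[!p$mask])
    # factory self-consistency: every source classifies as artifact cube
    expect_true(classify_artifact_cube(p$source)$is_artifact)
  }
  expect_error(build_training_set(list(), arts),
               class = "airgap3d_parameter_error")
})
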