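test_that("two disjoint spheres segment into two pores of analytic volume", {
  x <- array(200, c(64, 64, 64))
  x <- fill_sphere(x, c(20, 32, 32), 5, 80)
  x <- fill_sphere(x, c(50, 32, 32), 7, 80)
  seg <- segment_pores(volume3d(x),
                       seg_params(pore_threshold = 128,
                                  closing_radius_vox = 0,
                                  min_distance_vox = 4))
  expect_equal(max(seg$labels), 2)
  sizes <- sort(tabulate(seg$labels[seg$labels > 0]))
  brute <- sort(c(sphere_voxel_count(5), sphere_voxel_count(7)))
  expect_identical(sizes, brute)
  expect_lt(abs(sizes[1] - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.15)
  expect_lt(abs(sizes[2] - 4 / 3 * pi * 7^3) / (4 / 3 * pi * 7^3), 0.15)
  # exact partition of the pore mask
  expect_equal(sum(sizes), sum(seg$mask))
})

test_that("constant tissue volume yields an empty segmentation", {
  seg <- segment_pores(volume3d(array(200, c(16, 16, 16))))
  expect_equal(max(seg$labels), 0)
  expect_equal(nrow(pore_properties(seg)), 0)
  expect_equal(porosity(seg), 0)
})

test_that("watershed splits a dumbbell at the analytic neck", {
  x <- array(200, c(48, 48, 48))
  x <- fill_sphere(x, c(18, 24, 24), 8, 80)
  x <- fill_sphere(x, c(30, 24, 24), 8, 80)
  seg <- segment_pores(volume3d(x),
                       seg_params(closing_radius_vox = 0,
                                  min_distance_vox = 6))
  expect_equal(max(seg$labels), 2)
  # split plane within 2 voxels of the symmetry plane z = 24
  z1 <- max(arrayInd(which(seg$labels == seg$labels[18, 24, 24]),
                     dim(seg$labels))[, 1])
  z2 <- min(arrayInd(which(seg$labels == seg$labels[30, 24, 24]),
                     dim(seg$labels))[, 1])
  expect_lte(abs(z1 - 24), 2)
  expect_lte(abs(z2 - 24), 2)
})

test_that("pore properties: filled cuboid and voxelized ball identities", {
  x <- array(200, c(64, 64, 64))
  x[20:29, 20:29, 20:29] <- 80             # filled 10-cube
  seg <- segment_pores(volume3d(x), seg_params(closing_radius_vox = 0))
  p <- pore_properties(seg)
  expect_equal(nrow(p), 1)
  expect_equal(p$extent, 1)
  expect_equal(p$solidity, 1)
  expect_equal(p$volume_vox, 1000)
  # ball of continuous diameter 21 voxels
  xb <- array(200, c(64, 64, 64))
  xb <- fill_sphere(xb, c(32, 32, 32), 10.5, 80)
  segb <- segment_pores(volume3d(xb), seg_params(closing_radius_vox = 0,
                                                 min_distance_vox = 8))
  pb <- pore_properties(segb)
  expect_equal(nrow(pb), 1)
  expect_lt(abs(pb$extent - pi / 6), 0.03)
  expect_gte(pb$solidity, 0.95)
})

test_that("concave regions have solidity below one", {
  x <- array(200, c(40, 40, 40))
  g <- expand.grid(z = 1:40, y = 1:40, x = 1:40)
  rad <- sqrt((g$y - 20)^2 + (g$x - 20)^2)
  cshape <- rad >= 8 & rad <= 14 & g$z >= 15 & g$z <= 25 & g$y <= 20
  x[cbind(g$z, g$y, g$x)[cshape, , drop = FALSE]] <- 80
  seg <- segment_pores(volume3d(x), seg_params(closing_radius_vox = 0,
                                               min_distance_vox = 30))
  p <- pore_properties(seg)
  expect_equal(nrow(p), 1)
  expect_lt(p$solidity, 1)
})

test_that("physical volumes scale with the voxel size cubed", {
  x <- array(200, c(32, 32, 32))
  x[10:14, 10:14, 10:14] <- 80
  v <- volume3d(x, voxel_size_um = 2)
  p <- pore_properties(segment_pores(v, seg_params(closing_radius_vox = 0)))
  expect_equal(p$volume_um3, p$volume_vox * 8)
})

test_that("porosity identities and monotonicity in the threshold", {
  expect_equal(porosity(volume3d(array(200, c(8, 8, 8)))), 0)
  expect_equal(porosity(volume3d(array(80, c(8, 8, 8)))), 1)
  ph <- generate_lung_phantom(phantom_spec(shape = c(48, 48, 48),
                                           target_porosity = 0.4, seed = 31))
  por <- porosity(ph, seg_params(pore_threshold = 125,
                                 closing_radius_vox = 1))
  expect_lt(abs(por - 0.4), 0.05)
  vals <- vapply(c(100, 125, 150, 180), function(thr)
    porosity(ph, seg_params(pore_threshold = thr, closing_radius_vox = 0)), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("fixed-value masking touches exactly the masked voxels", {
  set.seed(123)
  for (i in 1:100) {
    vol <- seeded_volume(c(16, 16, 16), seed = i, lo = 30, hi = 220)
    mask <- array(runif(16^3) < 0.2, c(16, 16, 16))
    out <- mask_artifacts_fixed_value(vol, mask, fill_value = 128)
    expect_identical(out$data[!mask], vol$data[!mask])
    expect_true(all(out$data[mask] == 128))
  }
  vol <- seeded_volume(c(8, 8, 8), seed = 1)
  ident <- mask_artifacts_fixed_value(vol, array(FALSE, c(8, 8, 8)), 128)
  expect_identical(ident$data, vol$data)
  full <- mask_artifacts_fixed_value(vol, array(TRUE, c(8, 8, 8)), 128)
  expect_true(all(full$data == 128))
  expect_error(mask_artifacts_fixed_value(vol, array(TRUE, c(4, 4, 4)), 1),
               class = "airgap3d_parameter_error")
})

test_that("default fill value estimates the background mode", {
  x <- array(90, c(16, 16, 16))             # paraffin-like background
  x[5:8, 5:8, 5:8] <- 160
  mask <- array(FALSE, c(16, 16, 16)); mask[10:12, 10:12, 10:12] <- TRUE
  out <- mask_artifacts_fixed_value(volume3d(x), mask)
  expect_true(all(out$data[mask] == 90))
})

test_that("structural comparison reproduces the artifact-inflation ordering", {
  # two clean pores bridged by an artifact void: ignoring the artifact
  # merges alveolar regions and inflates the mean pore volume
  clean <- array(200, c(48, 48, 48))
  clean <- fill_sphere(clean, c(16, 24, 24), 6, 80)
  clean <- fill_sphere(clean, c(34, 24, 24), 6, 80)
  art <- clean
  art <- fill_sphere(art, c(25, 24, 24), 7, 0)      # bridging void
  rim <- binary_dilate(art == 0, 2) & !(art == 0)
  art[rim] <- 255
  mask <- art == 0 | rim
  masked <- mask_artifacts_fixed_value(volume3d(art), mask, fill_value = 80)
  params <- seg_params(pore_threshold = 128, closing_radius_vox = 1,
                       min_distance_vox = 10)
  tab <- compare_structural_metrics(volume3d(art), masked, volume3d(clean),
                                    params)
  mpv <- function(variant) tab$value[tab$metric == "mean_pore_volume_vox" &
                                       tab$variant == variant]
  expect_gt(mpv("original"), mpv("generated"))
  # masked fill below the pore threshold joins the pore phase
  por <- function(variant) tab$value[tab$metric == "porosity" &
                                       tab$variant == variant]
  expect_gte(por("masked"), por("generated"))
  # no-artifact degenerate case: all relative differences vanish
  tab0 <- compare_structural_metrics(volume3d(clean), volume3d(clean),
                                     volume3d(clean), params)
  expect_true(all(abs(tab0$diff_vs_generated) < 1e-12))
})

test_that("rois are validated and evaluated independently", {
  clean <- array(200, c(32, 32, 32))
  clean[4:9, 4:9, 4:9] <- 80
  v <- volume3d(clean)
  rois <- list(list(origin = c(0, 0, 0), size = c(16, 16, 16)),
               list(origin = c(16, 16, 16), size = c(16, 16, 16)))
  tab <- compare_structural_metrics(v, v, v, seg_params(closing_radius_vox = 0),
                                    rois)
  expect_equal(sort(unique(tab$roi)), c(1, 2))
  # pore only in roi 1
  expect_gt(tab$value[tab$roi == 1 & tab$metric == "porosity" &
                        tab$variant == "original"], 0)
  expect_equal(tab$value[tab$roi == 2 & tab$metric == "porosity" &
                           tab$variant == "original"], 0)
  expect_error(compare_structural_metrics(
    v, v, v, roi_list = list(list(origin = c(20, 0, 0), size = c(16, 16, 16)))),
    class = "airgap3d_parameter_error")
})
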