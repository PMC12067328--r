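# Shared fixture builders; everything is generated in code, seeded.

seeded_volume <- function(shape = c(16, 16, 16), seed = 1, lo = 20, hi = 235) {
  set.seed(seed)
  volume3d(array(sample(lo:hi, prod(shape), replace = TRUE), shape))
}

# voxelized sphere: value assigned where voxel center within radius r
fill_sphere <- function(arr, center, r, value) {
  d <- dim(arr)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  inside <- (g$z - center[1])^2 + (g$y - center[2])^2 +
    (g$x - center[3])^2 <= r^2
  arr[cbind(g$z, g$y, g$x)[inside, , drop = FALSE]] <- value
  arr
}

sphere_voxel_count <- function(r) {
  n <- ceiling(r)
  g <- expand.grid(-n:n, -n:n, -n:n)
  sum(rowSums(g^2) <= r^2)
}

# small phantom training pairs built through the transplant factory
phantom_pairs <- function(n, edge = 16L, seed0 = 100L,
                          n_bubbles = 2L, radius = c(2.5, 3.5), rim = 1L) {
  lapply(seq_len(n), function(i) {
    recipient <- generate_lung_phantom(phantom_spec(
      shape = rep(edge, 3), pore_correlation_length_vox = 3,
      seed = seed0 + i))
    donor_clean <- generate_lung_phantom(phantom_spec(
      shape = rep(edge, 3), pore_correlation_length_vox = 3,
      seed = seed0 + 1000L + i))
    inj <- inject_air_artifacts(donor_clean, artifact_spec(
      n_bubbles = n_bubbles, radius_range_vox = radius,
      rim_thickness_vox = rim, shape_irregularity = 0,
      seed = seed0 + 2000L + i))
    transplant_artifacts(inj$volume, recipient, inj$mask)
  })
}

tiny_gen_spec <- function(edge = 16L)
  generator_spec(edge,
                 encoder_filters = c(16, 32, 64, 64, 64, 64)[seq_len(log2(edge))])

tiny_disc_spec <- function()
  discriminator_spec(filters = c(16, 32, 64, 64), strides = c(2, 2, 2, 1))
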