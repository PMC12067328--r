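# Synthetic FFPE-lung phantoms.  The generator emulates the appearance
# of paraffin-embedded lung tissue in phase-contrast micro-CT after
# 8-bit conversion: a two-phase medium of connected airways (filled
# with darker paraffin) inside brighter tissue, mid-gray throughout,
# with no saturated voxels.  Air-bubble artifacts are injected
# separately as near-0 voids wrapped in near-255 rims, which is the
# histogram signature such artifacts show in real scans.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur along one axis via banded matrix multiply;
# kernel renormalized at the edges (truncated support)
blur_axis <- function(x, axis, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  n <- d[axis]
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- k[j - i + r + 1L]
    K[i, j] <- w / sum(w)
  }
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- K %*% matrix(xp, n)
  aperm(array(y, dp), order(perm))
}

gaussian_blur3 <- function(x, sigma) {
  for (ax in 1:3) x <- blur_axis(x, ax, sigma)
  x
}

#' Specification of a synthetic lung phantom
#'
#' Defaults describe a desk-scale stand-in for FFPE lung tissue: pore
#' (airway) fraction 0.4, alveolar-scale features of ~4 voxel
#' correlation length, paraffin darker than tissue (90 vs 160 on the
#' 8-bit scale), mild detector-like noise and a slight blur.  Clean
#' phantoms are clipped to the band `[5, 250]`, so they never contain
#' the extreme intensities 0 or 255 that characterize air artifacts.
#'
#' @param shape integer 3-vector of voxels (z, y, x).
#' @param target_porosity pore-phase fraction in (0, 1).
#' @param pore_correlation_length_vox Gaussian smoothing length of the
#'   random field; controls airway/alveolus size.
#' @param tissue_mean,paraffin_mean phase intensities, with
#'   `paraffin_mean < tissue_mean`, both inside (0, 255).
#' @param noise_sd additive Gaussian noise sd (gray levels).
#' @param blur_sigma_vox final blur sigma in voxels.
#' @param seed integer seed; the phantom is deterministic given it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), target_porosity = 0.4,
                         pore_correlation_length_vox = 4,
                         tissue_mean = 160, paraffin_mean = 90,
                         noise_sd = 6, blur_sigma_vox = 0.8, seed = 1L) {
  if (!(target_porosity > 0 && target_porosity < 1))
    abort_param("target_porosity must lie in (0, 1)")
  if (!(paraffin_mean > 0 && paraffin_mean < tissue_mean && tissue_mean < 255))
    abort_param("need 0 < paraffin_mean < tissue_mean < 255")
  if (noise_sd < 0 || blur_sigma_vox < 0)
    abort_param("noise_sd and blur_sigma_vox must be >= 0")
  if (pore_correlation_length_vox <= 0)
    abort_param("pore_correlation_length_vox must be positive")
  structure(list(shape = as.integer(shape), target_porosity = target_porosity,
                 pore_correlation_length_vox = pore_correlation_length_vox,
                 tissue_mean = tissue_mean, paraffin_mean = paraffin_mean,
                 noise_sd = noise_sd, blur_sigma_vox = blur_sigma_vox,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of injected air-bubble artifacts
#'
#' Bubbles are spheres with an optional smooth random radial
#' perturbation (`shape_irregularity`); at irregularity 0 they are
#' exact spheres, which keeps voxel counts analytically checkable.
#' The void interior is set to `void_value` (default 0) and a rim of
#' `rim_thickness_vox` voxels around the void — defined by Euclidean
#' distance from the void surface — to `rim_value` (default 255),
#' reproducing the dark-void/bright-band phenotype of phase-contrast
#' edge artifacts at trapped air.
#'
#' @param n_bubbles number of bubbles (>= 0).
#' @param radius_range_vox numeric `(min, max)` bubble radius.
#' @param rim_thickness_vox rim band thickness in voxels (>= 1).
#' @param void_value,rim_value intensities written into void and rim.
#' @param shape_irregularity amplitude of the radial perturbation
#'   (fraction of the radius, >= 0).
#' @param seed integer seed for centers, radii and perturbations.
#' @return an `artifact_spec` list.
#' @export
artifact_spec <- function(n_bubbles = 3L, radius_range_vox = c(4, 8),
                          rim_thickness_vox = 2L, void_value = 0,
                          rim_value = 255, shape_irregularity = 0.3,
                          seed = 1L) {
  if (n_bubbles < 0) abort_param("n_bubbles must be >= 0")
  if (radius_range_vox[1] > radius_range_vox[2])
    abort_param("radius range must satisfy min <= max")
  if (rim_thickness_vox < 1) abort_param("rim_thickness_vox must be >= 1")
  if (shape_irregularity < 0) abort_param("shape_irregularity must be >= 0")
  structure(list(n_bubbles = as.integer(n_bubbles),
                 radius_range_vox = as.numeric(radius_range_vox),
                 rim_thickness_vox = as.integer(rim_thickness_vox),
                 void_value = void_value, rim_value = rim_value,
                 shape_irregularity = shape_irregularity,
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Generate a synthetic FFPE-lung phantom
#'
#' A seeded white-noise field is smoothed with a Gaussian kernel of
#' width `pore_correlation_length_vox` and thresholded at the empirical
#' quantile that yields `target_porosity`, giving a connected two-phase
#' medium; the pore phase receives `paraffin_mean`, tissue
#' `tissue_mean`; noise and blur are added and the result clipped to
#' `[5, 250]` and rounded to 8-bit.  The phase mask before noise is
#' attached as attribute `"pore_mask"` (ground truth for tests).
#'
#' @param spec a [phantom_spec()].
#' @return a `volume3d` (8-bit), deterministic given `spec$seed`.
#' @export
generate_lung_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$shape < 4 * spec$pore_correlation_length_vox))
    abort_param("shape too small: every axis must be >= 4x the correlation length")
  vol <- with_seed(spec$seed, {
    field <- array(rnorm(prod(spec$shape)), spec$shape)
    field <- gaussian_blur3(field, spec$pore_correlation_length_vox)
    thr <- stats::quantile(field, spec$target_porosity, names = FALSE)
    pore <- field <= thr
    x <- array(spec$tissue_mean, spec$shape)
    x[pore] <- spec$paraffin_mean
    if (spec$noise_sd > 0) x <- x + array(rnorm(length(x), 0, spec$noise_sd), spec$shape)
    if (spec$blur_sigma_vox > 0) x <- gaussian_blur3(x, spec$blur_sigma_vox)
    x <- pmin(pmax(round_half_away(x), 5), 250)
    v <- volume3d(array(x, spec$shape))
    attr(v, "pore_mask") <- pore
    v
  })
  vol
}

#' Inject air-bubble artifacts into a volume
#'
#' Bubble centers are sampled with a margin of `max(radius) * (1 +
#' irregularity) + rim_thickness` from the faces so that every bubble
#' (and its rim) fits inside the volume.  Only masked voxels change:
#' the returned mask is exactly the union of void and rim voxels.
#'
#' @param vol a `volume3d`.
#' @param spec an [artifact_spec()].
#' @return a list with elements `volume` (`volume3d`), `mask` (logical
#'   array, void + rim) and `void` (logical array, void only).
#' @export
inject_air_artifacts <- function(vol, spec) {
  vol <- as_volume3d(vol)
  stopifnot(inherits(spec, "artifact_spec"))
  d <- dim(vol$data)
  if (spec$n_bubbles == 0L) {
    return(list(volume = vol, mask = array(FALSE, d), void = array(FALSE, d)))
  }
  rmax <- spec$radius_range_vox[2] * (1 + spec$shape_irregularity)
  margin <- ceiling(rmax) + spec$rim_thickness_vox
  if (any(d < 2 * margin + 1))
    abort_param(sprintf(
      "volume too small for bubbles: need every axis >= %d voxels", 2 * margin + 1))
  void <- array(FALSE, d)
  with_seed(spec$seed, {
    for (b in seq_len(spec$n_bubbles)) {
      ctr <- vapply(d, function(n) runif(1, margin + 1, n - margin), 0)
      r <- runif(1, spec$radius_range_vox[1], spec$radius_range_vox[2])
      # smooth even perturbation of the radius over directions
      vdirs <- matrix(rnorm(9), 3)
      vdirs <- sweep(vdirs, 2, sqrt(colSums(vdirs^2)), "/")
      coefs <- runif(3, -1, 1)
      ext <- ceiling(r * (1 + spec$shape_irregularity))
      rng <- lapply(1:3, function(a)
        max(1, floor(ctr[a] - ext)):min(d[a], ceiling(ctr[a] + ext)))
      g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
      rel <- cbind(g$z - ctr[1], g$y - ctr[2], g$x - ctr[3])
      dist <- sqrt(rowSums(rel^2))
      if (spec$shape_irregularity > 0) {
        u <- rel / pmax(dist, 1e-9)
        pert <- (u %*% vdirs)^2 %*% coefs
        pert <- pert - mean(pert)
        r_eff <- r * (1 + spec$shape_irregularity * as.vector(pert))
      } else {
        r_eff <- r
      }
      inside <- dist <= r_eff
      idx <- cbind(g$z, g$y, g$x)[inside, , drop = FALSE]
      void[idx] <- TRUE
    }
  })
  rim <- binary_dilate(void, spec$rim_thickness_vox) & !void
  x <- vol$data
  x[void] <- spec$void_value
  x[rim] <- spec$rim_value
  out <- volume3d(x, vol$voxel_size_um, vol$origin)
  list(volume = out, mask = void | rim, void = void)
}
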