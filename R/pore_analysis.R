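# Pore-structure quantification: threshold -> fill-holes/closing ->
# Euclidean distance transform -> marker-based watershed -> per-pore
# volume, extent and solidity, plus volume-level porosity.  Lung
# airspaces are strongly connected rather than enclosed pores, which
# is why the watershed split of the thresholded airway phase is needed
# before per-pore morphometrics mean anything.

#' Pore segmentation parameters
#'
#' The pore (airway/paraffin) phase is everything at or below
#' `pore_threshold` — the darker phase of the two-phase medium; 128
#' (the 8-bit midpoint) separates the default phantom phases and is
#' meant to be tuned per scan.  `min_distance_vox` controls watershed
#' marker separation and should be about the expected pore radius.
#'
#' @param pore_threshold intensity; pore phase is `I <= threshold`.
#' @param closing_radius_vox binary closing radius (>= 0).
#' @param min_distance_vox minimum marker (peak) separation (>= 1).
#' @param connectivity `"face"` (default) or `"full"`.
#' @param min_pore_vox labels smaller than this are merged into the
#'   background (0 keeps everything).
#' @return a `seg_params` list.
#' @export
seg_params <- function(pore_threshold = 128, closing_radius_vox = 1L,
                       min_distance_vox = 5L,
                       connectivity = c("face", "full"),
                       min_pore_vox = 0L) {
  connectivity <- match.arg(connectivity)
  if (min_distance_vox < 1) abort_param("min_distance_vox must be >= 1")
  if (closing_radius_vox < 0) abort_param("closing_radius_vox must be >= 0")
  structure(list(pore_threshold = pore_threshold,
                 closing_radius_vox = as.integer(closing_radius_vox),
                 min_distance_vox = as.integer(min_distance_vox),
                 connectivity = connectivity,
                 min_pore_vox = as.integer(min_pore_vox)),
            class = "seg_params")
}

#' Watershed segmentation of the pore phase
#'
#' Binary pore mask = fill-holes of the closed threshold mask; markers
#' are plateau-merged local maxima of the Euclidean distance
#' transform, thinned to `min_distance_vox` separation; labels come
#' from priority-flooding the distance transform from the markers
#' (equivalently, a watershed of the negated distance map restricted
#' to the mask), so the labels partition the mask exactly.  An empty
#' pore mask yields a valid segmentation with zero labels.
#'
#' @param vol an 8-bit `volume3d`.
#' @param params a [seg_params()].
#' @return a `pore_segmentation`: list with `labels` (integer array,
#'   0 = tissue, 1..K = pores), `mask` (logical array after
#'   morphology), `params`, `voxel_size_um`.
#' @export
segment_pores <- function(vol, params = seg_params()) {
  vol <- as_volume3d(vol)
  x <- vol$data
  mask <- x <= params$pore_threshold
  mask <- binary_close(mask, params$closing_radius_vox)
  mask <- fill_holes(mask)
  if (!any(mask)) {
    return(structure(list(labels = array(0L, dim(x)), mask = mask,
                          params = params,
                          voxel_size_um = vol$voxel_size_um),
                     class = "pore_segmentation"))
  }
  dt <- distance_transform(mask)
  markers <- peak_markers(dt, mask, params$min_distance_vox)
  labels <- watershed3d(dt, markers, mask, params$connectivity)
  if (params$min_pore_vox > 0L && max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < params$min_pore_vox)
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  # relabel contiguously, preserving flood order
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  structure(list(labels = labels, mask = mask, params = params,
                 voxel_size_um = vol$voxel_size_um),
            class = "pore_segmentation")
}

#' Per-pore morphometrics
#'
#' For every label: voxel volume (and physical volume), extent =
#' volume / bounding-box volume, and solidity = volume / voxelized
#' convex-hull volume (hull of the voxel centers).  Extent measures
#' how a pore fills its bounding cuboid; solidity is 1 for filled
#' convex bodies and < 1 for concave or hollow regions.  Where a 3D
#' hull is degenerate (a pore thinner than one voxel in some
#' direction), solidity is computed on the region dilated by one voxel
#' and the record flagged.
#'
#' @param seg a `pore_segmentation`.
#' @param voxel_size_um voxel size (defaults to the segmentation's).
#' @return data frame with one row per pore: `label`, `volume_vox`,
#'   `volume_um3`, `extent`, `solidity`, `bbox_z`, `bbox_y`, `bbox_x`,
#'   `hull_degenerate`.
#' @export
pore_properties <- function(seg, voxel_size_um = seg$voxel_size_um) {
  stopifnot(inherits(seg, "pore_segmentation"))
  labels <- seg$labels
  k <- max(labels)
  if (k == 0L) {
    return(data.frame(label = integer(0), volume_vox = integer(0),
                      volume_um3 = numeric(0), extent = numeric(0),
                      solidity = numeric(0), bbox_z = integer(0),
                      bbox_y = integer(0), bbox_x = integer(0),
                      hull_degenerate = logical(0)))
  }
  idx <- which(labels > 0L)
  coords <- arrayInd(idx, dim(labels))
  labs <- labels[idx]
  rows <- lapply(seq_len(k), function(l) {
    cc <- coords[labs == l, , drop = FALSE]
    nv <- nrow(cc)
    ext_axes <- apply(cc, 2, function(v) diff(range(v)) + 1L)
    hv <- hull_voxel_volume(cc)
    degenerate <- isTRUE(hv$degenerate)
    if (degenerate) {
      # dilate-by-one fallback for flat regions
      m <- array(FALSE, dim(labels))
      m[cc] <- TRUE
      md <- binary_dilate(m, 1)
      cc2 <- arrayInd(which(md), dim(labels))
      hv2 <- hull_voxel_volume(cc2)
      sol <- if (isTRUE(hv2$degenerate)) 1 else
        min(sum(md) / hv2$volume_vox, 1)
    } else {
      sol <- min(nv / hv$volume_vox, 1)
    }
    data.frame(label = l, volume_vox = nv,
               volume_um3 = nv * voxel_size_um^3,
               extent = nv / prod(ext_axes),
               solidity = sol,
               bbox_z = ext_axes[1], bbox_y = ext_axes[2],
               bbox_x = ext_axes[3],
               hull_degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Porosity of a volume or segmentation
#'
#' Fraction of pore-phase voxels (the post-morphology binary mask)
#' over all voxels.
#'
#' @param x a `pore_segmentation`, or an 8-bit `volume3d` (segmented
#'   with `params` first).
#' @param params a [seg_params()] (used when `x` is a volume).
#' @return fraction in `[0, 1]`.
#' @export
porosity <- function(x, params = seg_params()) {
  if (inherits(x, "pore_segmentation")) return(mean(x$mask))
  mean(segment_pores(as_volume3d(x), params)$mask)
}

#' Replace artifact voxels by a fixed value
#'
#' The masking baseline: all voxels of the (void + rim) artifact mask
#' are overwritten with one fixed intensity; everything else is
#' bit-identical.  The default fill is the histogram mode of the
#' unmasked voxels, which in paraffin-embedded tissue estimates the
#' paraffin background.
#'
#' @param vol an 8-bit `volume3d`.
#' @param mask logical artifact mask of the same shape.
#' @param fill_value intensity written into the mask (default:
#'   histogram mode of the voxels outside the mask).
#' @return a `volume3d`.
#' @export
mask_artifacts_fixed_value <- function(vol, mask, fill_value = NULL) {
  vol <- as_volume3d(vol)
  if (!all(dim(mask) == dim(vol$data)))
    abort_param("mask and volume must share one shape")
  if (is.null(fill_value)) {
    vals <- round_half_away(vol$data[!mask])
    tb <- tabulate(vals + 1L, nbins = 256L)
    fill_value <- which.max(tb) - 1L
  }
  x <- vol$data
  x[mask] <- fill_value
  volume3d(x, vol$voxel_size_um, vol$origin)
}

crop_roi <- function(vol, origin, size) {
  d <- dim(vol$data)
  if (any(origin < 0) || any(origin + size > d))
    abort_param(sprintf("ROI origin (%s) + size (%s) outside volume (%s)",
                        paste(origin, collapse = ","),
                        paste(size, collapse = ","),
                        paste(d, collapse = "x")))
  volume3d(vol$data[origin[1] + 1:size[1], origin[2] + 1:size[2],
                    origin[3] + 1:size[3], drop = FALSE],
           vol$voxel_size_um, vol$origin + as.integer(origin))
}

roi_metrics <- function(vol, params) {
  seg <- segment_pores(vol, params)
  props <- pore_properties(seg)
  c(porosity = porosity(seg),
    mean_pore_volume_vox = if (nrow(props)) mean(props$volume_vox) else 0,
    mean_extent = if (nrow(props)) mean(props$extent) else NA_real_,
    mean_solidity = if (nrow(props)) mean(props$solidity) else NA_real_)
}

#' Compare pore structure across original, masked and generated data
#'
#' For every region of interest, porosity, mean pore volume, mean
#' extent and mean solidity are computed on the original
#' (artifact-bearing) volume, on the fixed-value-masked volume and on
#' the generated (artifact-suppressed) volume; differences are
#' reported relative to the generated variant as reference.
#'
#' @param original,masked,generated `volume3d` objects of one shape.
#' @param params a [seg_params()].
#' @param roi_list list of ROIs, each `list(origin = c(z, y, x)
#'   0-based, size = c(nz, ny, nx))`; `NULL` means one ROI covering
#'   the full volume.
#' @return data frame keyed by (`roi`, `metric`, `variant`) with the
#'   value and the difference relative to the generated reference.
#' @export
compare_structural_metrics <- function(original, masked, generated,
                                       params = seg_params(),
                                       roi_list = NULL) {
  original <- as_volume3d(original); masked <- as_volume3d(masked)
  generated <- as_volume3d(generated)
  if (!all(dim(original$data) == dim(masked$data)) ||
      !all(dim(original$data) == dim(generated$data)))
    abort_param("the three volumes must share one shape")
  if (is.null(roi_list)) {
    roi_list <- list(list(origin = c(0L, 0L, 0L), size = dim(original$data)))
  }
  if (!length(roi_list)) abort_param("need at least one ROI")
  vols <- list(original = original, masked = masked, generated = generated)
  rows <- list()
  for (ri in seq_along(roi_list)) {
    roi <- roi_list[[ri]]
    ms <- lapply(vols, function(v)
      roi_metrics(crop_roi(v, roi$origin, roi$size), params))
    for (metric in names(ms$generated)) {
      ref <- ms$generated[[metric]]
      for (variant in names(vols)) {
        val <- ms[[variant]][[metric]]
        rows[[length(rows) + 1L]] <- data.frame(
          roi = ri, metric = metric, variant = variant, value = val,
          diff_vs_generated = val - ref,
          rel_diff_vs_generated = if (!is.na(ref) && ref != 0)
            (val - ref) / ref else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
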