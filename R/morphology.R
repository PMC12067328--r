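# True-3D binary morphology built on a Euclidean distance transform.
# Structuring elements are Euclidean balls of integer radius, so all
# operations are isotropic in voxel units.

#' Euclidean distance transform of a 3D binary mask
#'
#' Distance (in voxels) from every foreground voxel to the nearest
#' background voxel; 0 on the background.  Exact separable algorithm.
#'
#' @param mask logical 3D array.
#' @return numeric 3D array of distances.
#' @export
distance_transform <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d2 <- .edt_sq_cpp(as.logical(mask), dim(mask))
  array(sqrt(d2), dim(mask))
}

#' Binary morphology with a Euclidean ball structuring element
#'
#' Dilation, erosion, opening and closing of 3D masks.  Radius 0 is the
#' identity.  Implemented through the distance transform, which for a
#' ball element is exact and isotropic.
#'
#' @param mask logical 3D array.
#' @param radius non-negative structuring-element radius in voxels.
#' @return logical 3D array.
#' @export
binary_dilate <- function(mask, radius) {
  stopifnot(radius >= 0)
  if (radius == 0) return(mask & TRUE)
  d2 <- .edt_sq_cpp(!mask, dim(mask))
  array(d2 <= radius^2, dim(mask))
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius) {
  stopifnot(radius >= 0)
  if (radius == 0) return(mask & TRUE)
  d2 <- .edt_sq_cpp(as.logical(mask), dim(mask))
  array(d2 > radius^2, dim(mask))
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, radius) binary_dilate(binary_erode(mask, radius), radius)

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, radius) binary_erode(binary_dilate(mask, radius), radius)

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity `"face"` (6-neighborhood, default) or `"full"`
#'   (26-neighborhood).
#' @return integer 3D array; 0 = background, components numbered 1..K
#'   in deterministic scan order.
#' @export
label_components <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  array(.label3d_cpp(as.logical(mask), dim(mask), connectivity == "full"),
        dim(mask))
}

#' Remove connected components smaller than a voxel count
#'
#' @param mask logical 3D array.
#' @param min_vox minimum component size kept (components with fewer
#'   voxels are cleared).
#' @param connectivity passed to [label_components()].
#' @return logical 3D array.
#' @export
remove_small_components <- function(mask, min_vox,
                                    connectivity = c("face", "full")) {
  if (min_vox <= 1 || !any(mask)) return(mask & TRUE)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_vox)
  array(lab %in% keep, dim(mask))
}

#' Fill holes enclosed in a 3D mask
#'
#' A hole is a background component not connected (face connectivity)
#' to the array border.
#'
#' @param mask logical 3D array.
#' @return logical 3D array with enclosed background filled.
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, "face")
  d <- dim(mask)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  holes <- bg & !(lab %in% border_labels)
  mask | holes
}

# Greedy peak markers for watershed: plateau-merged local maxima of a
# distance map, thinned so accepted peaks are >= min_distance apart
# (stronger peaks win).  Returns an integer marker array labeled 1..K.
peak_markers <- function(dist, mask, min_distance) {
  d <- dim(dist)
  dmask <- dist
  dmask[!mask] <- -Inf
  # 26-neighborhood maximum via shifted pmax
  nb_max <- array(-Inf, d)
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    src1 <- max(1, 1 - a):min(d[1], d[1] - a)
    src2 <- max(1, 1 - b):min(d[2], d[2] - b)
    src3 <- max(1, 1 - c):min(d[3], d[3] - c)
    shifted <- array(-Inf, d)
    shifted[src1, src2, src3] <- dmask[src1 + a, src2 + b, src3 + c]
    nb_max <- pmax(nb_max, shifted)
  }
  is_peak <- mask & (dmask >= nb_max)
  if (!any(is_peak)) return(array(0L, d))
  plat <- label_components(is_peak, "full")
  k <- max(plat)
  # one representative voxel per plateau: the centroid-nearest member
  reps <- integer(k)
  vals <- numeric(k)
  idx_all <- which(plat > 0L)
  coords <- arrayInd(idx_all, d)
  labs <- plat[idx_all]
  for (i in seq_len(k)) {
    sel <- labs == i
    cc <- coords[sel, , drop = FALSE]
    ctr <- colMeans(cc)
    j <- which.min(rowSums((cc - matrix(ctr, nrow(cc), 3, byrow = TRUE))^2))
    reps[i] <- idx_all[sel][j]
    vals[i] <- dist[reps[i]]
  }
  ord <- order(-vals, reps)
  rc <- arrayInd(reps, d)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted)) {
      dd <- rowSums((rc[accepted, , drop = FALSE] -
                       matrix(rc[i, ], length(accepted), 3, byrow = TRUE))^2)
      if (any(dd < min_distance^2)) next
    }
    accepted <- c(accepted, i)
  }
  markers <- array(0L, d)
  markers[reps[accepted]] <- seq_along(accepted)
  markers
}

#' Marker-based watershed of a 3D priority map
#'
#' Floods `mask` from the marker voxels in order of decreasing
#' `priority` (priority flooding), assigning every mask voxel to the
#' basin that reaches it first; equivalently a watershed of the negated
#' priority map.  Deterministic: ties are broken by insertion order.
#'
#' @param priority numeric 3D array (e.g. a distance transform).
#' @param markers integer 3D array of seed labels (> 0 at seeds).
#' @param mask logical 3D array restricting the flood.
#' @param connectivity `"face"` or `"full"`.
#' @return integer 3D array of basin labels covering all of `mask`.
#' @export
watershed3d <- function(priority, markers, mask,
                        connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  stopifnot(all(dim(priority) == dim(mask)), all(dim(markers) == dim(mask)))
  array(.watershed3d_cpp(as.numeric(priority), as.integer(markers),
                         as.logical(mask), dim(mask),
                         connectivity == "full"),
        dim(mask))
}
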