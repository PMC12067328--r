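# Training-pair factory: cube extraction, artifact-cube detection,
# air-mask creation by two-sided thresholding plus binary morphology,
# and transplantation of masked artifact voxels into clean cubes to
# form source ("Real A") / target ("Real B") pairs.

#' Parameters of the air-artifact mask pipeline
#'
#' Air artifacts appear as near-0 voids with near-255 rims, so the mask
#' starts from a two-sided extreme-intensity threshold (`I <= low_thr`
#' or `I >= high_thr`), is cleaned by a morphological opening, purged
#' of components smaller than `min_component_vox` (this replaces human
#' judgment in classifying cubes: isolated noise voxels at the
#' extremes are not artifacts), and finally dilated to capture the
#' full artifact edge.  Structuring elements are Euclidean balls.
#'
#' @param low_thr void threshold (default 10).
#' @param high_thr rim threshold (default 245), `low_thr < high_thr`.
#' @param opening_radius_vox opening radius (>= 0, default 1).
#' @param dilation_radius_vox final dilation radius (>= 1, default 2).
#' @param min_component_vox minimum surviving component size (default 50).
#' @return a `mask_params` list.
#' @export
mask_params <- function(low_thr = 10, high_thr = 245, opening_radius_vox = 1L,
                        dilation_radius_vox = 2L, min_component_vox = 50L) {
  if (!(low_thr < high_thr)) abort_param("low_thr must be < high_thr")
  if (opening_radius_vox < 0) abort_param("opening_radius_vox must be >= 0")
  if (dilation_radius_vox < 1) abort_param("dilation_radius_vox must be >= 1")
  structure(list(low_thr = low_thr, high_thr = high_thr,
                 opening_radius_vox = as.integer(opening_radius_vox),
                 dilation_radius_vox = as.integer(dilation_radius_vox),
                 min_component_vox = as.integer(min_component_vox)),
            class = "mask_params")
}

#' Extract cubes from a volume on a stride lattice
#'
#' Origins run over `0, stride, 2*stride, ...` per axis, keeping only
#' cubes fully inside the volume.  With `stride == edge` the cubes are
#' non-overlapping and tile the largest covered sub-volume.
#'
#' @param vol a `volume3d`.
#' @param edge cube edge length in voxels.
#' @param stride lattice stride (>= 1).
#' @return list of `volume3d` cubes; each carries its 0-based `origin`.
#' @export
extract_cubes <- function(vol, edge, stride = edge) {
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  if (edge > min(d))
    abort_param(sprintf("edge (%d) exceeds a volume dimension (%s)",
                        edge, paste(d, collapse = "x")))
  if (stride < 1) abort_param("stride must be >= 1")
  origins <- expand.grid(z = seq(0L, d[1] - edge, by = stride),
                         y = seq(0L, d[2] - edge, by = stride),
                         x = seq(0L, d[3] - edge, by = stride))
  lapply(seq_len(nrow(origins)), function(i) {
    o <- as.integer(origins[i, ])
    volume3d(vol$data[o[1] + 1:edge, o[2] + 1:edge, o[3] + 1:edge,
                      drop = FALSE],
             vol$voxel_size_um, vol$origin + o)
  })
}

extreme_mask <- function(x, params) x <= params$low_thr | x >= params$high_thr

#' Classify a cube as containing air artifacts
#'
#' The score is the fraction of voxels at extreme intensities
#' (`<= low_thr` or `>= high_thr`) after removing connected components
#' smaller than `min_component_vox`; a cube is called an artifact cube
#' when the score reaches `min_extreme_fraction`.
#'
#' @param cube an 8-bit `volume3d`.
#' @param params a [mask_params()].
#' @param min_extreme_fraction decision threshold on the score.
#' @return list with `is_artifact` (logical) and `score` (fraction).
#' @export
classify_artifact_cube <- function(cube, params = mask_params(),
                                   min_extreme_fraction = 0.001) {
  cube <- as_volume3d(cube)
  m <- extreme_mask(cube$data, params)
  m <- remove_small_components(m, params$min_component_vox)
  score <- mean(m)
  list(is_artifact = score >= min_extreme_fraction, score = score)
}

#' Build a binary air-artifact mask for a cube
#'
#' Pipeline: two-sided extreme threshold -> opening
#' (`opening_radius_vox`) -> removal of components smaller than
#' `min_component_vox` -> dilation (`dilation_radius_vox`).  The
#' dilation captures the transition zone at the artifact edge beyond
#' the saturated rim itself.
#'
#' @param cube an 8-bit `volume3d`.
#' @param params a [mask_params()].
#' @return logical 3D array, same shape as the cube.
#' @export
make_air_mask <- function(cube, params = mask_params()) {
  cube <- as_volume3d(cube)
  m <- extreme_mask(cube$data, params)
  m <- binary_open(m, params$opening_radius_vox)
  m <- remove_small_components(m, params$min_component_vox)
  binary_dilate(m, params$dilation_radius_vox)
}

#' Transplant artifact voxels from a donor into a clean recipient
#'
#' The source of the returned pair is the recipient with the masked
#' voxels replaced by the donor's; the target is the untouched
#' recipient.  Outside the mask, source and target are bit-identical.
#'
#' @param donor `volume3d` cube containing artifacts.
#' @param recipient clean `volume3d` cube of the same shape.
#' @param mask logical array of the transplanted voxels.
#' @param provenance optional list of identifiers carried on the pair.
#' @return a `training_pair`: list with `source`, `target` (both
#'   `volume3d`), `mask`, `provenance`.
#' @export
transplant_artifacts <- function(donor, recipient, mask, provenance = NULL) {
  donor <- as_volume3d(donor); recipient <- as_volume3d(recipient)
  if (!all(dim(donor$data) == dim(recipient$data)) ||
      !all(dim(mask) == dim(donor$data)))
    abort_param("donor, recipient and mask must share one shape")
  x <- recipient$data
  x[mask] <- donor$data[mask]
  structure(list(source = volume3d(x, recipient$voxel_size_um, recipient$origin),
                 target = recipient,
                 mask = mask & TRUE,
                 provenance = provenance),
            class = "training_pair")
}

#' Build a training set by artifact transplantation
#'
#' For each requested pair an artifact (donor) cube is walked in order
#' and a clean recipient cube is sampled with replacement under
#' `pairing_seed`; the donor's air mask is computed with `params` and
#' transplanted into the recipient.  How donors are matched to
#' recipients is a free choice of the factory — anatomical
#' correspondence between donor and recipient regions cannot be
#' guaranteed, a known limitation of transplant-based pair synthesis.
#'
#' @param clean_cubes list of artifact-free `volume3d` cubes.
#' @param artifact_cubes list of artifact-bearing `volume3d` cubes.
#' @param params a [mask_params()].
#' @param n_pairs number of pairs to emit (default: one per donor).
#' @param pairing_seed integer seed for recipient sampling.
#' @return list of `training_pair` objects with provenance
#'   `(donor, recipient)` indices.
#' @export
build_training_set <- function(clean_cubes, artifact_cubes,
                               params = mask_params(),
                               n_pairs = length(artifact_cubes),
                               pairing_seed = 1L) {
  if (!length(clean_cubes) || !length(artifact_cubes))
    abort_param("clean_cubes and artifact_cubes must be non-empty")
  masks <- lapply(artifact_cubes, make_air_mask, params = params)
  with_seed(pairing_seed, {
    donors <- rep_len(seq_along(artifact_cubes), n_pairs)
    recipients <- sample.int(length(clean_cubes), n_pairs, replace = TRUE)
    lapply(seq_len(n_pairs), function(i) {
      transplant_artifacts(artifact_cubes[[donors[i]]],
                           clean_cubes[[recipients[i]]],
                           masks[[donors[i]]],
                           provenance = list(donor = donors[i],
                                             recipient = recipients[i]))
    })
  })
}
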