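# Whole-scan artifact suppression: tile the volume into
# non-overlapping cubes, flag the cubes that contain air artifacts,
# run the generator on exactly those, and reassemble at the original
# coordinates.  Unflagged cubes are copied bit-exactly, so the
# operation is idempotent on artifact-free data.

#' Plan a non-overlapping tiling of a volume
#'
#' Origins lie on the `edge`-spaced lattice.  Policy `"crop"` keeps
#' only full cubes and records the uncovered margins; `"pad_reflect"`
#' mirrors the volume up to the next multiple of `edge` per axis and
#' records the padding for trimming after processing.
#'
#' @param vol a `volume3d`.
#' @param edge tile edge in voxels.
#' @param remainder_policy `"crop"` (default) or `"pad_reflect"`.
#' @return a `tile_plan`: list with `edge`, `origins` (0-based integer
#'   matrix), `policy`, `padded_shape`, `margins`, and a `flags`
#'   placeholder filled by [suppress_air_artifacts()].
#' @export
plan_tiles <- function(vol, edge, remainder_policy = c("crop", "pad_reflect")) {
  remainder_policy <- match.arg(remainder_policy)
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  if (remainder_policy == "crop") {
    if (any(d < edge))
      abort_param(sprintf(
        "crop policy needs every dimension >= edge (%d); volume is %s",
        edge, paste(d, collapse = "x")))
    n_tiles <- d %/% edge
    covered <- n_tiles * edge
    margins <- d - covered
    padded <- d
  } else {
    padded <- as.integer(ceiling(d / edge) * edge)
    n_tiles <- padded %/% edge
    margins <- c(0L, 0L, 0L)
  }
  origins <- as.matrix(expand.grid(z = seq_len(n_tiles[1]) - 1L,
                                   y = seq_len(n_tiles[2]) - 1L,
                                   x = seq_len(n_tiles[3]) - 1L)) * edge
  structure(list(edge = as.integer(edge), origins = origins,
                 policy = remainder_policy,
                 input_shape = d, padded_shape = padded, margins = margins,
                 flags = rep(NA, nrow(origins))),
            class = "tile_plan")
}

reflect_pad <- function(x, padded) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    i <- seq_len(padded[a])
    # mirror indices without repeating the edge sample
    per <- if (d[a] > 1) c(seq_len(d[a]), seq(d[a] - 1L, 2L)) else 1L
    per[(i - 1L) %% length(per) + 1L]
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Suppress air artifacts across a whole volume
#'
#' Tiles the volume with [plan_tiles()], classifies every tile with
#' [classify_artifact_cube()] (the same rule used when building
#' training data), replaces flagged tiles by the generator output and
#' reassembles.  Voxels of unflagged tiles — and, under the `"crop"`
#' policy, uncovered margins — are bit-identical to the input.
#'
#' @param vol an 8-bit `volume3d`.
#' @param model a trained `generator_model` (or checkpoint path).
#' @param params a [mask_params()] for artifact detection.
#' @param min_extreme_fraction detection threshold, as in
#'   [classify_artifact_cube()].
#' @param remainder_policy passed to [plan_tiles()].
#' @return list with `volume` (same shape as input) and `plan` (the
#'   `tile_plan` with per-tile `flags` and `scores` filled in).
#' @export
suppress_air_artifacts <- function(vol, model, params = mask_params(),
                                   min_extreme_fraction = 0.001,
                                   remainder_policy = c("crop", "pad_reflect")) {
  remainder_policy <- match.arg(remainder_policy)
  if (is.character(model)) model <- load_generator(model)
  vol <- as_volume3d(vol)
  edge <- model$spec$cube_edge
  plan <- plan_tiles(vol, edge, remainder_policy)
  work <- if (plan$policy == "pad_reflect" &&
              any(plan$padded_shape != plan$input_shape)) {
    reflect_pad(vol$data, plan$padded_shape)
  } else {
    vol$data
  }
  out <- work
  flags <- logical(nrow(plan$origins))
  scores <- numeric(nrow(plan$origins))
  for (i in seq_len(nrow(plan$origins))) {
    o <- plan$origins[i, ]
    iz <- o[1] + 1:edge; iy <- o[2] + 1:edge; ix <- o[3] + 1:edge
    cube <- volume3d(work[iz, iy, ix, drop = FALSE], vol$voxel_size_um,
                     vol$origin + as.integer(o))
    cl <- classify_artifact_cube(cube, params, min_extreme_fraction)
    flags[i] <- cl$is_artifact
    scores[i] <- cl$score
    if (cl$is_artifact) {
      out[iz, iy, ix] <- generate(model, cube)$data
    }
  }
  plan$flags <- flags
  plan$scores <- scores
  d <- plan$input_shape
  out <- out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  list(volume = volume3d(out, vol$voxel_size_um, vol$origin), plan = plan)
}
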