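#' Construct a 3D volume
#'
#' `volume3d` is the in-memory carrier used by every stage of the
#' pipeline: a dense 3D array of 8-bit voxel intensities together with
#' an isotropic voxel size in micrometres and the integer voxel offset
#' of the block within its parent volume.  Arrays are indexed
#' `(z, y, x)` with `z` the slice axis.
#'
#' @param data numeric 3D array of intensities in `[0, 255]`.
#' @param voxel_size_um positive isotropic voxel edge length in um.
#' @param origin integer 3-vector, voxel offset (0-based) of this block
#'   within a parent volume; `c(0, 0, 0)` for a standalone volume.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size_um = 1, origin = c(0L, 0L, 0L)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_param("`data` must be a 3D array")
  if (any(dim(data) < 1L)) abort_param("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    abort_param("`voxel_size_um` must be a positive scalar")
  if (length(origin) != 3L) abort_param("`origin` must be a 3-vector")
  storage.mode(data) <- "double"   # one storage type, so round trips and
                                   # conservation checks stay bit-identical
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 origin = as.integer(origin)),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x), %.3g um/voxel, origin (%s)\n",
              d[1], d[2], d[3], x$voxel_size_um,
              paste(x$origin, collapse = ",")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

as_volume3d <- function(x, template = NULL) {
  if (inherits(x, "volume3d")) return(x)
  volume3d(x,
           voxel_size_um = if (is.null(template)) 1 else template$voxel_size_um,
           origin = if (is.null(template)) c(0L, 0L, 0L) else template$origin)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a volume to 8-bit
#'
#' Maps arbitrary numeric intensities into `[0, 255]`.  Mode `"minmax"`
#' sends the observed minimum to 0 and maximum to 255; a constant
#' volume maps to all zeros (documented convention, so flat sub-blocks
#' of phantoms are legal input).  Mode `"fixed_window"` maps the window
#' `[lo, hi]` linearly onto `[0, 255]` and clips outside it — the
#' windowing used when ingesting floating-point phase-retrieved
#' reconstructions is a user choice, as no canonical window exists.
#' Rounding is half-away-from-zero, then clipping, for cross-platform
#' determinism.
#'
#' @param vol a `volume3d` or numeric 3D array.
#' @param mode `"minmax"` or `"fixed_window"`.
#' @param lo,hi window bounds for `"fixed_window"` (`lo < hi`).
#' @return a `volume3d` with intensities in `[0, 255]`.
#' @export
to_uint8 <- function(vol, mode = c("minmax", "fixed_window"),
                     lo = NULL, hi = NULL) {
  mode <- match.arg(mode)
  v <- as_volume3d(vol)
  x <- v$data
  if (mode == "minmax") {
    r <- range(x)
    if (r[1] == r[2]) {
      y <- array(0, dim(x))
    } else {
      y <- (x - r[1]) / (r[2] - r[1]) * 255
    }
  } else {
    if (is.null(lo) || is.null(hi) || !(lo < hi))
      abort_param("fixed_window requires lo < hi")
    y <- (x - lo) / (hi - lo) * 255
  }
  y <- pmin(pmax(round_half_away(y), 0), 255)
  volume3d(array(y, dim(x)), v$voxel_size_um, v$origin)
}

slice_file_names <- function(n) sprintf("slice_%0*d.tif", max(4L, nchar(n)), seq_len(n) - 1L)

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  stats::setNames(as.list(vals), keys)
}

#' Read a 3D volume from disk
#'
#' Supported formats: a directory of single-slice TIFF files
#' (`tiff-stack`, slices ordered by file name along the z axis), NIfTI
#' (`.nii`/`.nii.gz`), and raw binary with a plain-text `key=value`
#' sidecar (`<path>.meta` holding `shape`, `dtype`, `voxel_size_um`).
#' When no voxel size is stored, 1.0 um is assumed with a warning.
#'
#' @param path file (nifti, raw) or directory (tiff-stack).
#' @param format one of `"tiff-stack"`, `"nifti"`, `"raw"`.
#' @return a `volume3d`.
#' @export
read_volume <- function(path, format = c("tiff-stack", "nifti", "raw")) {
  format <- match.arg(format)
  switch(format,
    "tiff-stack" = {
      if (!dir.exists(path)) abort_io(paste0("no such directory: ", path))
      files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
      if (!length(files)) abort_io(paste0("no TIFF slices in ", path))
      slices <- lapply(files, function(f) {
        s <- try(tiff::readTIFF(f), silent = TRUE)
        if (inherits(s, "try-error")) abort_io(paste0("unreadable TIFF: ", f))
        round_half_away(s * 255)
      })
      dims <- unique(lapply(slices, dim))
      if (length(dims) != 1L)
        abort_format(paste0("inconsistent slice shapes in TIFF stack: ", path))
      d <- dims[[1L]]
      arr <- array(0, c(length(slices), d[1], d[2]))
      for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
      vs <- 1
      meta <- file.path(path, "voxel_size_um.txt")
      if (file.exists(meta)) {
        vs <- as.numeric(readLines(meta, warn = FALSE)[1L])
      } else {
        log_msg("warn", "no voxel size stored with ", path, "; assuming 1 um")
      }
      volume3d(arr, vs)
    },
    "nifti" = {
      if (!file.exists(path)) abort_io(paste0("no such file: ", path))
      img <- try(RNifti::readNifti(path), silent = TRUE)
      if (inherits(img, "try-error")) abort_io(paste0("unreadable NIfTI: ", path))
      arr <- array(as.numeric(img), dim(img))
      # stored (x, y, z); carrier convention is (z, y, x)
      arr <- aperm(arr, c(3, 2, 1))
      pd <- RNifti::pixdim(img)
      vs <- if (length(pd) >= 1 && pd[1] > 0) pd[1] * 1000 else { # mm -> um
        log_msg("warn", "no voxel size in NIfTI header of ", path, "; assuming 1 um")
        1
      }
      volume3d(arr, vs)
    },
    "raw" = {
      if (!file.exists(path)) abort_io(paste0("no such file: ", path))
      meta_path <- paste0(path, ".meta")
      if (!file.exists(meta_path))
        abort_io(paste0("missing sidecar metadata: ", meta_path))
      meta <- read_sidecar(meta_path)
      shape <- as.integer(strsplit(meta$shape, ",")[[1L]])
      if (length(shape) != 3L) abort_format("sidecar `shape` must have 3 entries")
      dtype <- meta$dtype %||% "uint8"
      if (dtype != "uint8") abort_format(paste0("unsupported raw dtype: ", dtype))
      n <- prod(shape)
      sz <- file.info(path)$size
      if (sz != n)
        abort_format(sprintf("raw byte count (%d) != shape product (%d): %s",
                             sz, n, path))
      bytes <- readBin(path, "integer", n = n, size = 1L, signed = FALSE)
      vs <- as.numeric(meta$voxel_size_um %||% {
        log_msg("warn", "no voxel_size_um in sidecar of ", path, "; assuming 1 um")
        1
      })
      volume3d(array(as.numeric(bytes), shape), vs)
    })
}

#' Write a 3D volume to disk
#'
#' Inverse of [read_volume()]; for 8-bit data the round trip is
#' bit-exact in all three formats.  TIFF stacks are written as one
#' zero-padded, numerically named file per z slice plus a
#' `voxel_size_um.txt` note; NIfTI stores the voxel size in the header
#' spacing fields (in mm); raw output gains a `<path>.meta` sidecar.
#'
#' @param vol a `volume3d` with intensities in `[0, 255]`.
#' @param path output directory (tiff-stack) or file (nifti, raw).
#' @param format one of `"tiff-stack"`, `"nifti"`, `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("tiff-stack", "nifti", "raw")) {
  format <- match.arg(format)
  vol <- as_volume3d(vol)
  x <- vol$data
  if (min(x) < 0 || max(x) > 255)
    abort_param("volume intensities must lie in [0, 255]; run to_uint8() first")
  switch(format,
    "tiff-stack" = {
      if (!dir.exists(path)) {
        ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
        if (!ok) abort_io(paste0("cannot create directory: ", path))
      }
      nz <- dim(x)[1]
      files <- file.path(path, slice_file_names(nz))
      for (i in seq_len(nz)) {
        tiff::writeTIFF(matrix(x[i, , ] / 255, dim(x)[2], dim(x)[3]),
                        files[i], bits.per.sample = 8L)
      }
      writeLines(format(vol$voxel_size_um, digits = 15),
                 file.path(path, "voxel_size_um.txt"))
    },
    "nifti" = {
      dir_ok <- dir.exists(dirname(path)) ||
        dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      if (!dir_ok) abort_io(paste0("cannot create directory for: ", path))
      arr <- aperm(x, c(3, 2, 1)) # back to stored (x, y, z)
      img <- RNifti::asNifti(arr)
      mm <- vol$voxel_size_um / 1000
      img <- RNifti::`pixdim<-`(img, c(mm, mm, mm))
      RNifti::writeNifti(img, path)
    },
    "raw" = {
      dir_ok <- dir.exists(dirname(path)) ||
        dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      if (!dir_ok) abort_io(paste0("cannot create directory for: ", path))
      writeBin(as.raw(as.integer(round_half_away(x))), path)
      writeLines(c(paste0("shape=", paste(dim(x), collapse = ",")),
                   "dtype=uint8",
                   paste0("voxel_size_um=", format(vol$voxel_size_um, digits = 15)),
                   "byte_order=none"),
                 paste0(path, ".meta"))
    })
  invisible(path)
}
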