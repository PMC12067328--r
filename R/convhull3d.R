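# 3D convex hull of voxel-center point sets, used for pore solidity.
# Incremental insertion hull: maintain an outward-oriented facet list,
# insert points one at a time, replace the facets visible from the new
# point by a fan over the horizon edges.  Candidate points are first
# reduced to per-axis line extremes, which preserves the hull of an
# axis-aligned voxel set.

reduce_to_line_extremes <- function(pts) {
  keep <- rep(FALSE, nrow(pts))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- paste(pts[, others[1]], pts[, others[2]])
    ord <- order(key, pts[, ax])
    sp <- split(ord, key[ord])
    for (idx in sp) {
      keep[idx[1]] <- TRUE
      keep[idx[length(idx)]] <- TRUE
    }
  }
  pts[keep, , drop = FALSE]
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Returns list(N, d, verts, volume, degenerate): facets satisfy
# N %*% x <= d for hull points (outward normals, unnormalized).
convex_hull3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  degen <- list(degenerate = TRUE)
  if (n < 4) return(degen)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  eps <- 1e-9 * scale
  # initial extreme pair (lexicographic min/max)
  i1 <- order(pts[, 1], pts[, 2], pts[, 3])[1]
  i2 <- order(-pts[, 1], -pts[, 2], -pts[, 3])[1]
  if (i1 == i2) return(degen)
  e12 <- pts[i2, ] - pts[i1, ]
  # farthest from the line
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * e12[3] - rel[, 3] * e12[2],
              rel[, 3] * e12[1] - rel[, 1] * e12[3],
              rel[, 1] * e12[2] - rel[, 2] * e12[1])
  dist_line <- sqrt(rowSums(cr^2))
  i3 <- which.max(dist_line)
  if (dist_line[i3] <= eps) return(degen)
  n0 <- cross3(e12, pts[i3, ] - pts[i1, ])
  dist_plane <- abs(rel %*% n0)
  i4 <- which.max(dist_plane)
  if (dist_plane[i4] <= eps * sqrt(sum(n0^2))) return(degen)

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  verts <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(v) {
    a <- pts[v[1], ]; b <- pts[v[2], ]; cc <- pts[v[3], ]
    nn <- cross3(b - a, cc - a)
    dd <- sum(nn * a)
    if (sum(nn * interior) > dd) { nn <- -nn; dd <- -dd; v <- v[c(1, 3, 2)] }
    list(n = nn, d = dd, v = v)
  }
  fs <- lapply(seq_len(nrow(verts)), function(i) orient(verts[i, ]))
  N <- do.call(rbind, lapply(fs, `[[`, "n"))
  d <- vapply(fs, `[[`, 0, "d")
  V <- do.call(rbind, lapply(fs, `[[`, "v"))

  for (p_idx in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    p <- pts[p_idx, ]
    # visibility threshold scaled per facet by the normal length
    vis <- which(as.vector(N %*% p) - d > eps * sqrt(rowSums(N^2)))
    if (!length(vis)) next
    ve <- V[vis, , drop = FALSE]
    edges <- rbind(ve[, c(1, 2)], ve[, c(2, 3)], ve[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), , drop = FALSE]
    N <- N[-vis, , drop = FALSE]; d <- d[-vis]; V <- V[-vis, , drop = FALSE]
    for (h in seq_len(nrow(horizon))) {
      f <- orient(c(horizon[h, ], p_idx))
      N <- rbind(N, f$n); d <- c(d, f$d); V <- rbind(V, f$v)
    }
  }
  vol <- 0
  for (i in seq_len(nrow(V))) {
    a <- pts[V[i, 1], ] - interior
    b <- pts[V[i, 2], ] - interior
    cc <- pts[V[i, 3], ] - interior
    vol <- vol + abs(sum(cross3(a, b) * cc)) / 6
  }
  list(N = N, d = d, verts = V, points = pts, volume = vol,
       degenerate = FALSE)
}

# Voxelized hull volume: voxel centers of the integer bounding box
# that satisfy every facet half-space (with a small tolerance so hull
# vertices themselves count as inside).
hull_voxel_volume <- function(coords) {
  coords <- as.matrix(coords)
  cand <- reduce_to_line_extremes(coords)
  hull <- convex_hull3d(cand)
  if (isTRUE(hull$degenerate)) return(list(volume_vox = NA_real_, degenerate = TRUE))
  rng <- apply(coords, 2, range)
  grid <- as.matrix(expand.grid(rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                                rng[1, 3]:rng[2, 3]))
  tol <- 1e-7 * pmax(sqrt(rowSums(hull$N^2)), 1)
  inside <- rep(TRUE, nrow(grid))
  proj <- grid %*% t(hull$N)
  for (f in seq_along(hull$d)) {
    inside <- inside & (proj[, f] <= hull$d[f] + tol[f])
  }
  list(volume_vox = sum(inside), degenerate = FALSE)
}
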