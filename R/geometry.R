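# Planar geometry helpers. All coordinates are planar meters (x, y);
# inputs are assumed already projected (e.g. UTM), no reprojection here.

# Arc length of a polyline given as an n x 2 coordinate matrix.
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

# Vectorized nearest-point search over every piece of every segment
# geometry in the network. Ties between equidistant segments resolve to the
# smallest segment id, then the earliest piece. Returns the chosen segment
# row index, piece, clamped parameter, foot point and distance.
nearest_projection <- function(network, p) {
  geoms <- network$segments$geometry
  nv <- vapply(geoms, nrow, integer(1))
  allc <- do.call(rbind, geoms)
  last_rows <- cumsum(nv)
  a_idx <- seq_len(nrow(allc))[-last_rows]
  a <- allc[a_idx, , drop = FALSE]
  b <- allc[a_idx + 1, , drop = FALSE]
  piece_seg <- rep(seq_along(geoms), nv - 1)
  piece_no <- sequence(nv - 1)

  ab <- b - a
  len2 <- ab[, 1]^2 + ab[, 2]^2
  t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) /
    ifelse(len2 > 0, len2, 1)
  t <- pmin(pmax(ifelse(len2 > 0, t, 0), 0), 1)
  fx <- a[, 1] + ab[, 1] * t
  fy <- a[, 2] + ab[, 2] * t
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2

  near <- which(d2 <= min(d2) + 1e-12)
  near <- near[order(network$segments$id[piece_seg[near]], piece_no[near])]
  k <- near[1]
  list(segment = piece_seg[k], piece = piece_no[k], t = t[k],
       point = c(fx[k], fy[k]), dist = sqrt(d2[k]))
}

# Split a polyline at (piece index, parameter t), returning the two halves.
# The foot point is inserted into both halves.
split_polyline <- function(coords, piece, t) {
  a <- coords[piece, ]
  b <- coords[piece + 1, ]
  foot <- a + (b - a) * t
  first <- rbind(coords[seq_len(piece), , drop = FALSE], foot)
  second <- rbind(foot, coords[seq(piece + 1, nrow(coords)), , drop = FALSE])
  # drop duplicated vertices created when t is exactly 0 or 1
  dedupe <- function(m) {
    keep <- c(TRUE, rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2) > 0)
    m[keep, , drop = FALSE]
  }
  list(first = dedupe(first), second = dedupe(second), foot = foot)
}

# Single-linkage clustering of planar points within `tol` meters, via
# union-find over candidate pairs found with a spatial grid hash.
# Returns an integer cluster id per point.
cluster_points <- function(coords, tol) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (tol <= 0) {
    # only exactly coincident coordinates merge
    groups <- split(seq_len(n), paste(coords[, 1], coords[, 2]))
    for (g in groups) if (length(g) > 1) for (i in g[-1]) union_(g[1], i)
  } else {
    # compare points in the same and neighbouring grid cells
    cell <- floor(coords / tol)
    idx_by_cell <- split(seq_len(n), paste(cell[, 1], cell[, 2]))
    offsets <- expand.grid(dx = -1:1, dy = -1:1)
    for (cname in names(idx_by_cell)) {
      here <- idx_by_cell[[cname]]
      cxy <- cell[here[1], ]
      cand <- integer(0)
      for (k in seq_len(nrow(offsets))) {
        nb <- idx_by_cell[[paste(cxy[1] + offsets$dx[k], cxy[2] + offsets$dy[k])]]
        cand <- c(cand, nb)
      }
      cand <- cand[cand >= here[1]]
      if (length(cand) < 2) next
      for (i in here) {
        js <- cand[cand > i]
        if (length(js) == 0) next
        d2 <- (coords[js, 1] - coords[i, 1])^2 + (coords[js, 2] - coords[i, 2])^2
        for (j in js[d2 <= tol^2]) union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
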