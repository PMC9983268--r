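#' Shape profiles: simple polygons delimiting a tissue or region
#'
#' A `shape_profile` holds the ordered vertices of a simple (non-self-
#' intersecting) closed polygon with positive area, plus the concavity
#' parameter used to build it (if any). Vertices are stored counter-clockwise
#' and unclosed (the last vertex is not a repeat of the first).
#'
#' @param vertices A two-column matrix or data frame of (x, y) vertices in
#'   boundary order.
#' @param concavity Positive real recorded for provenance; `Inf` for shapes
#'   not built by the hull estimator.
#' @return A `shape_profile` object.
#' @export
shape_profile <- function(vertices, concavity = Inf) {
  v <- as_coords_matrix(vertices)
  # drop a closing repeat vertex if supplied
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) abort("a shape profile needs at least 3 vertices")
  a <- polygon_signed_area(v)
  if (abs(a) < 1e-12 * max(1, max(abs(v)))^2) abort("polygon has (near-)zero area")
  if (a < 0) v <- v[nrow(v):1, , drop = FALSE]  # enforce counter-clockwise
  if (!polygon_is_simple(v)) abort("polygon is self-intersecting")
  structure(list(vertices = v, concavity = concavity), class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf("<shape_profile> %d vertices, area %.4g, concavity %s\n",
              nrow(x$vertices), shape_area(x), format(x$concavity)))
  invisible(x)
}

#' Polygon area of a shape profile
#' @param shape A [shape_profile] object.
#' @return Positive area in squared coordinate units.
#' @export
shape_area <- function(shape) abs(polygon_signed_area(shape$vertices))

#' Test whether points fall inside a shape profile
#' @param shape A [shape_profile].
#' @param points Two-column matrix or data frame of (x, y) points.
#' @param boundary Should points on the outline count as contained?
#' @return Logical vector.
#' @export
shape_contains <- function(shape, points, boundary = TRUE) {
  points_in_polygon(as_coords_matrix(points), shape$vertices, boundary = boundary)
}

#' Estimate a tissue outline with a concave hull
#'
#' Starts from the convex hull of the measured locations and recursively digs
#' boundary edges inward toward nearby interior points, producing a polygon
#' that follows concavities of the point cloud. An edge of length `L` is dug
#' toward the interior point `p` closest to it only when
#' `L > concavity * d(p, edge)`, when the triangle cut off contains no other
#' input point (which guarantees every input point stays inside or on the
#' hull), and when the replacement edges keep the polygon simple. Larger
#' `concavity` digs less; as `concavity` grows the result converges to the
#' convex hull.
#'
#' @param points Two-column matrix or data frame of location coordinates
#'   (at least 3 non-collinear points).
#' @param concavity Positive dig-threshold multiplier (default 2); `Inf`
#'   returns the convex hull.
#' @return A [shape_profile] containing all input points.
#' @export
estimate_shape <- function(points, concavity = 2) {
  pts <- unique(as_coords_matrix(points))
  if (nrow(pts) < 3) abort("need at least 3 distinct points to estimate a shape")
  if (concavity <= 0) abort("`concavity` must be positive")
  hull_idx <- grDevices::chull(pts)
  hull <- rev(hull_idx)  # chull returns clockwise; store counter-clockwise
  if (abs(polygon_signed_area(pts[hull, , drop = FALSE])) <
      1e-12 * max(1, max(abs(pts)))^2) {
    abort("points are collinear: no polygon can be estimated")
  }
  verts <- hull  # indices into pts, in boundary order
  if (is.finite(concavity)) {
    interior <- setdiff(seq_len(nrow(pts)), verts)
    # longest-edge-first digging; each dig consumes one interior point, so
    # the loop terminates. `done` marks edges (keyed by their start vertex)
    # already found undiggable; a dig re-opens only the two new edges.
    done <- character(0)
    while (length(interior) > 0) {
      n <- length(verts)
      starts <- verts
      ends <- verts[c(2:n, 1)]
      keys <- paste(starts, ends)
      open <- which(!(keys %in% done))
      if (length(open) == 0) break
      lens <- sqrt(rowSums((pts[ends[open], , drop = FALSE] -
                              pts[starts[open], , drop = FALSE])^2))
      i <- open[which.max(lens)]
      a <- pts[verts[i], ]; b <- pts[ends[i], ]
      cand <- dig_candidate(pts, interior, a, b, max(lens), concavity)
      if (!is.null(cand) && dig_keeps_simple(pts, verts, i, cand)) {
        verts <- append(verts, cand, after = i)
        interior <- setdiff(interior, cand)
      } else {
        done <- c(done, keys[i])
      }
    }
  }
  shape_profile(pts[verts, , drop = FALSE], concavity = concavity)
}

# Closest interior point to edge (a, b) such that digging is allowed:
# edge longer than concavity * distance, and triangle (a, p, b) empty.
dig_candidate <- function(pts, interior, a, b, edge_len, concavity) {
  if (length(interior) == 0) return(NULL)
  d <- point_segment_dist(pts[interior, , drop = FALSE], a, b)
  ord <- order(d)
  for (j in ord) {
    p_idx <- interior[j]
    if (edge_len <= concavity * d[j]) return(NULL)  # d sorted: no later point qualifies
    tri <- rbind(a, pts[p_idx, ], b)
    if (abs(polygon_signed_area(tri)) < 1e-300) next
    others <- setdiff(interior, p_idx)
    if (length(others) > 0 &&
        any(points_in_polygon(pts[others, , drop = FALSE], tri, boundary = FALSE))) {
      next  # digging would expose another input point
    }
    return(p_idx)
  }
  NULL
}

dig_keeps_simple <- function(pts, verts, i, cand) {
  n <- length(verts)
  a <- pts[verts[i], ]; b <- pts[verts[i %% n + 1], ]; p <- pts[cand, ]
  for (j in seq_len(n)) {
    if (j == i) next
    q1 <- pts[verts[j], ]; q2 <- pts[verts[j %% n + 1], ]
    if (segments_cross(a, p, q1, q2) || segments_cross(p, b, q1, q2)) return(FALSE)
  }
  TRUE
}

#' Generate a square grid of locations inside a shape
#'
#' Solves for a lattice pitch (by bisection) such that the number of lattice
#' points strictly inside the polygon is within 10% of `n_target`, preferring
#' more points on ties. Mimics array-based platforms whose spots sit on a
#' regular grid.
#'
#' @param shape A [shape_profile].
#' @param n_target Requested number of locations (>= 1).
#' @return A tibble with columns `x`, `y`; all points strictly inside the
#'   polygon, on a common square lattice.
#' @export
generate_grid_locations <- function(shape, n_target) {
  stopifnot(n_target >= 1)
  v <- shape$vertices
  area <- shape_area(shape)
  if (area <= 0) abort("polygon has zero area")
  bb <- apply(v, 2, range)
  count_at <- function(h) nrow(grid_points(v, bb, h))
  # pitch bracketing: small pitch -> many points
  h_hi <- sqrt(area / max(1, n_target)) * 4  # few points
  h_lo <- sqrt(area / max(1, n_target)) / 4  # many points
  while (count_at(h_hi) > n_target && h_hi < 1e6 * sqrt(area)) h_hi <- h_hi * 2
  while (count_at(h_lo) < n_target && h_lo > 1e-9 * sqrt(area)) h_lo <- h_lo / 2
  best <- NULL
  for (iter in 1:60) {
    h <- (h_lo + h_hi) / 2
    cnt <- count_at(h)
    if (cnt >= n_target) h_lo <- h else h_hi <- h
    if (abs(cnt - n_target) <= 0.1 * n_target) {
      if (is.null(best) || abs(cnt - n_target) < abs(best$cnt - n_target) ||
          (abs(cnt - n_target) == abs(best$cnt - n_target) && cnt > best$cnt)) {
        best <- list(h = h, cnt = cnt)
      }
      if (cnt == n_target) break
    }
  }
  if (is.null(best)) {
    abort(sprintf("could not place a grid of ~%d points in the polygon", n_target))
  }
  g <- grid_points(v, bb, best$h)
  tibble::tibble(x = g[, 1], y = g[, 2])
}

grid_points <- function(v, bb, h) {
  if (bb[1, 1] + h / 2 > bb[2, 1] || bb[1, 2] + h / 2 > bb[2, 2]) {
    return(matrix(numeric(0), 0, 2))
  }
  xs <- seq(bb[1, 1] + h / 2, bb[2, 1], by = h)
  ys <- seq(bb[1, 2] + h / 2, bb[2, 2], by = h)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  g[points_in_polygon(g, v, boundary = FALSE), , drop = FALSE]
}

#' Generate uniformly random locations inside a shape
#'
#' Rejection-samples i.i.d. uniform points over the polygon (a homogeneous
#' spatial point process), mimicking imaging-based platforms whose cells sit
#' at irregular positions.
#'
#' @param shape A [shape_profile].
#' @param n Number of locations (>= 1).
#' @param seed Integer random seed; identical seeds give identical points.
#' @return A tibble with columns `x`, `y`.
#' @export
generate_random_locations <- function(shape, n, seed = 1) {
  stopifnot(n >= 1)
  v <- shape$vertices
  if (shape_area(shape) <= 0) abort("polygon has zero area")
  bb <- apply(v, 2, range)
  with_substream(substream_seed(seed, 104L), {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      m <- max(2 * (n - nrow(out)), 64)
      cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
      keep <- points_in_polygon(cand, v, boundary = FALSE)
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out <- out[seq_len(n), , drop = FALSE]
    tibble::tibble(x = out[, 1], y = out[, 2])
  })
}

#' Transfer spatial-domain labels onto new locations
#'
#' Each new location receives a label from its `k` Euclidean nearest reference
#' locations by Boyer-Moore majority voting: when a strict majority (> k/2)
#' exists among the neighbours, that label is assigned; otherwise the nearest
#' neighbour's label is used. Neighbour distance ties break toward the lowest
#' reference index, making the transfer deterministic.
#'
#' @param ref_coords Reference coordinates (two-column matrix or data frame).
#' @param ref_labels One label per reference location.
#' @param new_coords Coordinates needing labels.
#' @param k Number of neighbours (default 3).
#' @return Character vector of labels, one per new location.
#' @export
transfer_domain_labels <- function(ref_coords, ref_labels, new_coords, k = 3) {
  ref <- as_coords_matrix(ref_coords)
  if (nrow(ref) == 0) abort("empty reference set")
  if (length(ref_labels) != nrow(ref)) {
    abort("`ref_labels` must have one label per reference location")
  }
  ref_labels <- as.character(ref_labels)
  nn <- knn_indices(as_coords_matrix(new_coords), ref, k)
  apply(nn, 1, function(idx) {
    labs <- ref_labels[idx]
    # Boyer-Moore majority vote candidate ...
    cand <- labs[1]; cnt <- 1L
    for (l in labs[-1]) {
      if (cnt == 0L) { cand <- l; cnt <- 1L }
      else if (l == cand) cnt <- cnt + 1L
      else cnt <- cnt - 1L
    }
    # ... verified; fall back to the nearest neighbour when no strict majority
    if (sum(labs == cand) * 2 > length(labs)) cand else labs[1]
  })
}

# ---- affine transforms -------------------------------------------------------

#' Affine transforms between tissue regions
#'
#' An `affine_transform` is the map `y = linear %*% x + offset` with an
#' invertible 2x2 `linear` part.
#'
#' @param linear Invertible 2x2 matrix.
#' @param offset Length-2 numeric translation.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(linear, offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < 1e-14) abort("linear part must be invertible")
  structure(list(linear = linear, offset = as.numeric(offset)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\nlinear:\n"); print(x$linear)
  cat("offset:", format(x$offset), "\n")
  invisible(x)
}

#' Fit an affine map between two region shapes
#'
#' Polygons delimiting two regions generally have different vertex counts, so
#' there is no natural vertex-to-vertex correspondence. The map is instead
#' built from each shape's anchor frame - polygon centroid, principal axes of
#' the vertex cloud (orientation signs fixed so the map has positive
#' determinant, i.e. no reflection), and the vertex extent along each axis:
#' the source frame is translated to the origin, rotated to its principal
#' axes, scaled per-axis by the extent ratio, then rotated and translated into
#' the destination frame. For near-isotropic shapes (no preferred axis) the
#' coordinate axes are used. Applying the result to the source frame
#' reproduces the destination frame to numerical tolerance.
#'
#' @param src,dst [shape_profile] objects.
#' @return An [affine_transform] mapping source-region coordinates into the
#'   destination region.
#' @export
fit_affine <- function(src, dst) {
  fs <- shape_frame(src)
  fd <- shape_frame(dst)
  if (any(fs$ext <= 0) || any(fd$ext <= 0)) abort("degenerate (zero-extent) shape")
  s <- diag(fd$ext / fs$ext)
  linear <- fd$axes %*% s %*% t(fs$axes)
  offset <- fd$centroid - linear %*% fs$centroid
  affine_transform(linear, as.numeric(offset))
}

# centroid + principal axes (rotation, det +1) + half-extents of the vertices
shape_frame <- function(shape) {
  v <- shape$vertices
  ctr <- polygon_centroid(v)
  vc <- sweep(v, 2, ctr)
  cv <- crossprod(vc) / nrow(vc)
  ev <- eigen(cv, symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) <= 1e-9 * max(ev$values[1], 1e-300)) {
    axes <- diag(2)  # isotropic: no preferred axis, keep coordinate frame
  } else {
    a1 <- ev$vectors[, 1]
    # deterministic sign: largest-magnitude component positive
    if (a1[which.max(abs(a1))] < 0) a1 <- -a1
    a2 <- c(-a1[2], a1[1])  # right-handed, det +1
    axes <- cbind(a1, a2)
  }
  proj <- vc %*% axes
  ext <- apply(abs(proj), 2, max)
  list(centroid = ctr, axes = axes, ext = ext)
}

#' Least-squares affine map from point correspondences
#'
#' Solves the 6-parameter affine map minimising squared residuals over paired
#' points; exact (zero residual) for 3 non-degenerate pairs.
#'
#' @param src_points,dst_points Matched coordinate sets (>= 3 points).
#' @return An [affine_transform].
#' @export
affine_from_points <- function(src_points, dst_points) {
  s <- as_coords_matrix(src_points)
  d <- as_coords_matrix(dst_points)
  stopifnot(nrow(s) == nrow(d), nrow(s) >= 3)
  X <- cbind(1, s)
  beta <- qr.solve(X, d)  # 3 x 2: row 1 offset, rows 2:3 linear (transposed)
  affine_transform(t(beta[2:3, ]), beta[1, ])
}

#' Apply an affine transform to points
#' @param transform An [affine_transform].
#' @param points Two-column matrix or data frame.
#' @return A tibble of transformed coordinates (`x`, `y`).
#' @export
apply_affine <- function(transform, points) {
  p <- as_coords_matrix(points)
  out <- p %*% t(transform$linear)
  out <- sweep(out, 2, -transform$offset)
  tibble::tibble(x = out[, 1], y = out[, 2])
}

#' Invert an affine transform
#' @param transform An [affine_transform].
#' @return The inverse [affine_transform].
#' @export
invert_affine <- function(transform) {
  li <- solve(transform$linear)
  affine_transform(li, -as.numeric(li %*% transform$offset))
}

#' Read or write a shape profile as a vertex CSV
#'
#' Shapes serialise as a CSV of ordered vertices with columns `x`, `y`; the
#' same format is accepted as user input for reference-free tissue outlines.
#'
#' @param path CSV path.
#' @param shape A [shape_profile] (for writing).
#' @return `read_shape()` returns a [shape_profile]; `write_shape()` returns
#'   the path, invisibly.
#' @export
read_shape <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  shape_profile(tab)
}

#' @rdname read_shape
#' @export
write_shape <- function(shape, path) {
  readr::write_csv(tibble::tibble(x = shape$vertices[, 1],
                                  y = shape$vertices[, 2]), path)
  invisible(path)
}
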