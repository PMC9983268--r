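#' @importFrom rlang %||% abort .data
#' @importFrom stats dpois dnbinom rpois rnbinom rbinom runif optim optimize
#'   ks.test var sd median quantile setNames rmultinom prcomp
#' @importFrom utils head
NULL

# Deterministic substream seeds: a single user seed plus a path of integer
# indices (stage, gene, replicate, ...) hashes to an independent-looking seed,
# so adding genes or stages never perturbs draws in earlier substreams.
substream_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (v in idx) {
    # LCG-style mixing kept below 2^53 so double arithmetic is exact
    h <- (h * 69069 + (v %% 2147483647) + 1) %% 2147483647
    h <- (h * 40692) %% 2147483399
  }
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded by `seed`; restores the
# caller's RNG state afterwards.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Brute-force k-nearest-neighbour indices of `ref` rows for each `query` row.
# Euclidean distance; ties broken by lowest reference index. Chunked so the
# full distance matrix never exceeds ~8e6 doubles.
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  n_ref <- nrow(ref)
  if (k > n_ref) {
    abort(sprintf("k = %d exceeds the number of reference points (%d)", k, n_ref))
  }
  chunk <- max(1L, floor(8e6 / n_ref))
  out <- matrix(0L, nrow(query), k)
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), rowSums(ref^2), "+") -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    for (i in seq_along(idx)) {
      di <- d2[i, ]
      if (exclude_self) di[idx[i]] <- Inf
      out[idx[i], ] <- order(di)[seq_len(k)]
    }
  }
  out
}

# ---- polygon primitives ------------------------------------------------------

# Signed area by the shoelace formula; positive for counter-clockwise vertices.
polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Do open segments (p1,p2) and (p3,p4) properly intersect (crossing in their
# interiors)? Shared endpoints do not count.
segments_cross <- function(p1, p2, p3, p4, tol = 1e-12) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
     ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol)))
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# Distance from points (matrix) to segment ab.
point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Even-odd ray-casting point-in-polygon test with an explicit boundary rule:
# points within `tol` of any edge count as inside when `boundary = TRUE`
# (needed so hull input points on the outline test as contained).
points_in_polygon <- function(pts, v, boundary = TRUE, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(v)
  inside <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit & !is.na(hit))
    j <- i
  }
  if (boundary) {
    scale <- max(abs(v)) + 1
    on_bd <- rep(FALSE, nrow(pts))
    j <- n
    for (i in seq_len(n)) {
      on_bd <- on_bd | point_segment_dist(pts, v[j, ], v[i, ]) <= tol * scale
      j <- i
    }
    inside <- inside | on_bd
  }
  inside
}

as_coords_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y") %in% names(coords)))
    cbind(x = as.numeric(coords$x), y = as.numeric(coords$y))
  } else {
    m <- as.matrix(coords)
    stopifnot(ncol(m) == 2)
    colnames(m) <- c("x", "y")
    m
  }
}
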