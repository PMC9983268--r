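#' Construct an SRT dataset container
#'
#' Bundles a gene-by-location integer count matrix with per-location 2-D
#' coordinates and (optionally) per-location spatial-domain labels. This is
#' the universal input/output container of the package: reference datasets,
#' synthetic datasets and benchmark designs are all `srt_data` objects.
#'
#' @param counts Integer matrix, genes in rows and locations in columns.
#'   Row names are taken as gene identifiers (synthesised as `gene_0001`, ...
#'   when absent); column names as location identifiers.
#' @param coords Per-location coordinates: a data frame with columns
#'   `location_id` (optional), `x`, `y`, or a two-column matrix. Row order
#'   must match the column order of `counts`.
#' @param domains Optional per-location domain labels (character/factor),
#'   one per location.
#'
#' @return An object of class `srt_data`: a list with elements `counts`
#'   (integer matrix), `coords` (tibble: `location_id`, `x`, `y`), and
#'   `domains` (character vector or `NULL`).
#' @export
#' @examples
#' cnt <- matrix(rpois(6, 2), 2, 3,
#'               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' d <- srt_data(cnt, data.frame(x = 1:3, y = 0))
#' dim(d)
srt_data <- function(counts, coords, domains = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  }
  if (is.data.frame(coords)) {
    if (!all(c("x", "y") %in% names(coords))) {
      abort("`coords` must contain columns `x` and `y`")
    }
    loc_id <- if ("location_id" %in% names(coords)) {
      as.character(coords$location_id)
    } else {
      colnames(counts) %||% sprintf("loc_%04d", seq_len(nrow(coords)))
    }
    coords <- tibble::tibble(location_id = loc_id,
                             x = as.numeric(coords$x), y = as.numeric(coords$y))
  } else {
    m <- as_coords_matrix(coords)
    loc_id <- colnames(counts) %||% sprintf("loc_%04d", seq_len(nrow(m)))
    coords <- tibble::tibble(location_id = loc_id, x = m[, 1], y = m[, 2])
  }
  if (is.null(colnames(counts)) && ncol(counts) == nrow(coords)) {
    colnames(counts) <- coords$location_id
  }
  if (!is.null(domains)) domains <- as.character(domains)
  out <- structure(
    list(counts = counts, coords = coords, domains = domains),
    class = "srt_data"
  )
  validate_srt_data(out)
}

validate_srt_data <- function(x) {
  counts <- x$counts
  coords <- x$coords
  if (ncol(counts) != nrow(coords)) {
    abort(sprintf(
      "count matrix has %d locations (columns) but the coordinate table has %d rows",
      ncol(counts), nrow(coords)
    ))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    abort("all coordinates must be finite")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene identifiers")
  if (anyDuplicated(coords$location_id)) abort("duplicate location identifiers")
  if (ncol(counts) > 0 && !identical(colnames(counts), coords$location_id)) {
    abort("column order of `counts` must match the coordinate table row order")
  }
  if (!is.null(x$domains)) {
    if (length(x$domains) != nrow(coords)) {
      abort(sprintf("%d domain labels for %d locations",
                    length(x$domains), nrow(coords)))
    }
    if (anyNA(x$domains)) abort("domain labels must not be missing")
  }
  storage.mode(x$counts) <- "double" # exact integers, no 2^31 overflow on sums
  x
}

#' @export
dim.srt_data <- function(x) dim(x$counts)

#' @export
print.srt_data <- function(x, ...) {
  cat(sprintf("<srt_data> %d genes x %d locations\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$domains)) {
    tab <- table(x$domains)
    cat("domains:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf("coordinates: x in [%.3g, %.3g], y in [%.3g, %.3g]\n",
              min(x$coords$x), max(x$coords$x), min(x$coords$y), max(x$coords$y)))
  invisible(x)
}

gene_ids <- function(x) rownames(x$counts)
location_ids <- function(x) x$coords$location_id

#' Tidy an SRT dataset into long format
#'
#' @param x An `srt_data` object.
#' @param ... Unused.
#' @return A tibble with one row per (gene, location): `gene_id`,
#'   `location_id`, `x`, `y`, `domain` (if present) and `count`.
#' @method tidy srt_data
#' @export
tidy.srt_data <- function(x, ...) {
  obj <- x
  n_g <- nrow(obj$counts)
  base <- tibble::tibble(
    gene_id = rep(gene_ids(obj), times = ncol(obj$counts)),
    location_id = rep(obj$coords$location_id, each = n_g),
    x = rep(obj$coords$x, each = n_g),
    y = rep(obj$coords$y, each = n_g),
    count = as.vector(obj$counts)
  )
  if (!is.null(obj$domains)) {
    base$domain <- rep(obj$domains, each = n_g)
  }
  base
}

#' @method glance srt_data
#' @export
glance.srt_data <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$counts),
    n_locations = ncol(x$counts),
    n_domains = if (is.null(x$domains)) NA_integer_ else length(unique(x$domains)),
    total_count = sum(x$counts),
    zero_fraction = mean(x$counts == 0)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
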