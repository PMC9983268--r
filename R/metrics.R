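#' Gene-wise expression metrics
#'
#' For each gene across locations: mean, sample variance (n-1 denominator),
#' coefficient of variation `cv = sd/mean` (reported missing when the mean is
#' 0), and the proportion of zero counts.
#'
#' @param data An [srt_data] with >= 2 locations.
#' @return A tibble: `gene_id`, `mean`, `variance`, `cv`, `zero_prop`.
#' @export
gene_metrics <- function(data) {
  stopifnot(inherits(data, "srt_data"))
  if (ncol(data$counts) < 2) abort("need at least 2 locations")
  m <- unname(rowMeans(data$counts))
  v <- unname(apply(data$counts, 1, var))
  tibble::tibble(
    gene_id = gene_ids(data),
    mean = m,
    variance = v,
    cv = ifelse(m == 0, NA_real_, sqrt(v) / m),
    zero_prop = unname(rowMeans(data$counts == 0))
  )
}

#' Location-wise expression metrics
#'
#' For each location across genes: the proportion of zero counts and the
#' library size (total count).
#'
#' @param data An [srt_data] with >= 1 gene.
#' @return A tibble: `location_id`, `zero_prop`, `library_size`.
#' @export
location_metrics <- function(data) {
  stopifnot(inherits(data, "srt_data"))
  if (nrow(data$counts) < 1) abort("need at least 1 gene")
  tibble::tibble(
    location_id = location_ids(data),
    zero_prop = unname(colMeans(data$counts == 0)),
    library_size = unname(colSums(data$counts))
  )
}

#' Two-sample Kolmogorov-Smirnov comparison of metric distributions
#'
#' Missing values are dropped from each vector independently before the
#' two-sample KS test (asymptotic p-value; ties allowed).
#'
#' @param ref_values,syn_values Numeric vectors (non-empty after dropping
#'   missing values).
#' @return A one-row tibble: `statistic` (D), `p_value`, `n_ref`, `n_syn`.
#' @export
ks_compare <- function(ref_values, syn_values) {
  r <- ref_values[!is.na(ref_values)]
  s <- syn_values[!is.na(syn_values)]
  if (length(r) == 0 || length(s) == 0) {
    abort("empty vector after removing missing values")
  }
  kt <- suppressWarnings(ks.test(r, s, exact = FALSE))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = min(1, unname(kt$p.value)),
                 n_ref = length(r), n_syn = length(s))
}

#' Moran's I spatial autocorrelation
#'
#' Computes `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i
#' (x_i - xbar)^2` with zero diagonal weights and `W = sum_ij w_ij`.
#' Neighbourhood weights are binary symmetrised k-nearest-neighbour
#' (default, k = 5, not row-standardised) or inverse distance. Constant
#' vectors have undefined autocorrelation and return `NA`.
#'
#' @param values Numeric vector, one value per location.
#' @param coords Coordinates (two-column matrix or data frame, >= 3 rows).
#' @param weights `"knn"` or `"inverse_distance"`, or a precomputed n x n
#'   weight matrix (zero diagonal).
#' @param k Neighbour count for `"knn"` weights.
#' @return Moran's I (scalar), or `NA` for constant input.
#' @export
morans_i <- function(values, coords, weights = c("knn", "inverse_distance"),
                     k = 5) {
  W <- if (is.matrix(weights)) weights else {
    morans_weights(as_coords_matrix(coords), match.arg(weights), k)
  }
  n <- length(values)
  stopifnot(nrow(W) == n, n >= 3)
  z <- values - mean(values)
  den <- sum(z^2)
  if (den == 0) return(NA_real_)
  (n / sum(W)) * sum(z * (W %*% z)) / den
}

morans_weights <- function(xy, type, k = 5) {
  n <- nrow(xy)
  if (type == "knn") {
    nn <- knn_indices(xy, xy, min(k, n - 1), exclude_self = TRUE)
    W <- matrix(0, n, n)
    W[cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))] <- 1
    W <- pmax(W, t(W))  # symmetrise
  } else {
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    W <- 1 / d
  }
  diag(W) <- 0
  W
}

# Moran's I for every gene of a dataset, sharing one weight matrix
morans_i_genes <- function(data, weights = "knn", k = 5) {
  W <- if (is.matrix(weights)) weights else {
    morans_weights(as.matrix(data$coords[, c("x", "y")]), weights, k)
  }
  n <- ncol(data$counts)
  Z <- data$counts - rowMeans(data$counts)
  den <- rowSums(Z^2)
  num <- rowSums((Z %*% W) * Z)
  I <- ifelse(den == 0, NA_real_, (n / sum(W)) * num / den)
  tibble::tibble(gene_id = gene_ids(data), morans_i = I)
}

#' Fidelity report: how closely does a synthetic dataset resemble its reference?
#'
#' Assembles the six metric distributions (four gene-wise, two
#' location-wise) for the reference and the synthetic data, the per-metric
#' two-sample KS comparisons, the per-gene Moran's I pairs (when the two
#' datasets share identical locations), and the count-model preference
#' profile of both datasets. Gene-wise `cv` values missing because of
#' all-zero genes are dropped from the KS comparison and the drop count is
#' recorded.
#'
#' @param ref,syn [srt_data] objects sharing the same gene set.
#' @param weights,k Moran's I neighbourhood specification (see
#'   [morans_i()]).
#' @param model_preference Also profile count-model preference on both
#'   datasets (default TRUE; the most expensive part of the report).
#' @return An `srt_fidelity` object: list with `gene_metrics`,
#'   `location_metrics` (long tibbles with a `source` column), `ks_table`,
#'   `morans` (or `NULL` when locations differ), `model_preference`,
#'   `weight_spec`, `cv_dropped`.
#' @export
fidelity_report <- function(ref, syn, weights = "knn", k = 5,
                            model_preference = TRUE) {
  stopifnot(inherits(ref, "srt_data"), inherits(syn, "srt_data"))
  if (!setequal(gene_ids(ref), gene_ids(syn))) {
    diff <- c(setdiff(gene_ids(ref), gene_ids(syn)),
              setdiff(gene_ids(syn), gene_ids(ref)))
    abort(sprintf("gene sets differ (%d genes): %s%s",
                  length(diff), paste(head(diff, 5), collapse = ", "),
                  if (length(diff) > 5) ", ..." else ""))
  }
  gm <- dplyr::bind_rows(
    dplyr::mutate(gene_metrics(ref), source = "reference"),
    dplyr::mutate(gene_metrics(syn), source = "synthetic")
  )
  lm_ <- dplyr::bind_rows(
    dplyr::mutate(location_metrics(ref), source = "reference"),
    dplyr::mutate(location_metrics(syn), source = "synthetic")
  )
  gmr <- gene_metrics(ref); gms <- gene_metrics(syn)
  gms <- gms[match(gmr$gene_id, gms$gene_id), ]
  lmr <- location_metrics(ref); lms <- location_metrics(syn)
  ks <- dplyr::bind_rows(
    dplyr::mutate(ks_compare(gmr$mean, gms$mean), metric = "mean"),
    dplyr::mutate(ks_compare(gmr$variance, gms$variance), metric = "variance"),
    dplyr::mutate(ks_compare(gmr$cv, gms$cv), metric = "cv"),
    dplyr::mutate(ks_compare(gmr$zero_prop, gms$zero_prop), metric = "gene_zero_prop"),
    dplyr::mutate(ks_compare(lmr$zero_prop, lms$zero_prop), metric = "location_zero_prop"),
    dplyr::mutate(ks_compare(lmr$library_size, lms$library_size), metric = "library_size")
  )[, c("metric", "statistic", "p_value", "n_ref", "n_syn")]

  morans <- NULL
  same_locations <- ncol(ref$counts) == ncol(syn$counts) &&
    isTRUE(all.equal(as.matrix(ref$coords[, c("x", "y")]),
                     as.matrix(syn$coords[, c("x", "y")]), tolerance = 1e-12,
                     check.attributes = FALSE))
  if (same_locations) {
    W <- morans_weights(as.matrix(ref$coords[, c("x", "y")]),
                        if (is.matrix(weights)) "knn" else weights, k)
    if (is.matrix(weights)) W <- weights
    mr <- morans_i_genes(ref, W)
    ms <- morans_i_genes(syn, W)
    morans <- tibble::tibble(gene_id = mr$gene_id, reference = mr$morans_i,
                             synthetic = ms$morans_i[match(mr$gene_id, ms$gene_id)])
  }
  pref <- NULL
  if (model_preference) {
    pref <- dplyr::bind_rows(
      dplyr::mutate(model_preference_summary(ref), source = "reference"),
      dplyr::mutate(model_preference_summary(syn), source = "synthetic")
    )
  }
  structure(
    list(gene_metrics = gm, location_metrics = lm_, ks_table = ks,
         morans = morans, model_preference = pref,
         weight_spec = if (is.matrix(weights)) "custom" else
           sprintf("%s (k=%d)", weights, k),
         cv_dropped = c(reference = sum(is.na(gmr$cv)),
                        synthetic = sum(is.na(gms$cv)))),
    class = "srt_fidelity"
  )
}

#' @export
print.srt_fidelity <- function(x, ...) {
  cat("<srt_fidelity>\nKS comparisons (reference vs synthetic):\n")
  print(as.data.frame(x$ks_table), row.names = FALSE, digits = 3)
  if (!is.null(x$morans)) {
    ok <- stats::complete.cases(x$morans[, c("reference", "synthetic")])
    cat(sprintf("Moran's I concordance (Pearson r, %s): %.3f\n",
                x$weight_spec,
                stats::cor(x$morans$reference[ok], x$morans$synthetic[ok])))
  }
  if (sum(x$cv_dropped) > 0) {
    cat(sprintf("cv dropped for all-zero genes: %d (reference), %d (synthetic)\n",
                x$cv_dropped[["reference"]], x$cv_dropped[["synthetic"]]))
  }
  invisible(x)
}

#' @method tidy srt_fidelity
#' @export
tidy.srt_fidelity <- function(x, ...) x$ks_table

#' @method glance srt_fidelity
#' @export
glance.srt_fidelity <- function(x, ...) {
  ok <- if (is.null(x$morans)) logical(0) else {
    stats::complete.cases(x$morans[, c("reference", "synthetic")])
  }
  tibble::tibble(
    n_metrics_nonsignificant = sum(x$ks_table$p_value > 0.05),
    max_ks_statistic = max(x$ks_table$statistic),
    morans_concordance = if (sum(ok) > 2) {
      stats::cor(x$morans$reference[ok], x$morans$synthetic[ok])
    } else NA_real_
  )
}
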