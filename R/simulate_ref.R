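#' Assign simulated counts to locations by reference rank order
#'
#' The core pattern-preserving step: the i-th largest simulated count is
#' placed at the location with the i-th largest reference expression, so the
#' synthetic gene reproduces the spatial ordering of the reference gene.
#' Ties in the reference expression are broken by a seeded uniform random
#' permutation within the tied block, avoiding any coordinate-dependent bias.
#' The output is always a permutation of the input counts.
#'
#' @param sim_counts Simulated counts (numeric vector).
#' @param ref_expr Reference expression at the same locations (same length).
#' @param seed Integer seed controlling tie-breaking.
#' @return `sim_counts` rearranged onto the locations.
#' @export
#' @examples
#' rank_assign(c(7, 0, 2), c(5, 1, 3))  # 7 to the largest reference value
rank_assign <- function(sim_counts, ref_expr, seed = 1) {
  if (length(sim_counts) != length(ref_expr)) {
    abort(sprintf("length mismatch: %d simulated counts vs %d reference values",
                  length(sim_counts), length(ref_expr)))
  }
  n <- length(ref_expr)
  tie_key <- with_substream(substream_seed(seed, 301L), sample.int(n))
  ord <- order(ref_expr, tie_key, decreasing = TRUE)
  out <- numeric(n)
  out[ord] <- sort(sim_counts, decreasing = TRUE)
  out
}

# rank_assign under the caller's RNG state (tie key drawn locally)
rank_assign_local <- function(sim_counts, ref_expr) {
  n <- length(ref_expr)
  ord <- order(ref_expr, sample.int(n), decreasing = TRUE)
  out <- numeric(n)
  out[ord] <- sort(sim_counts, decreasing = TRUE)
  out
}

#' Reference-based simulation of an SRT dataset
#'
#' Implements the three-step reference-based engine. Step 1 obtains the
#' synthetic locations: the reference's own locations by default, or a fresh
#' set (square grid or uniform random points inside the concave hull of the
#' reference locations) when `new_locations` is given. Step 2 fits the four
#' count models to each gene of the reference by maximum likelihood, selects
#' by AIC, and samples fresh counts from the winning model (fits can be
#' precomputed with [fit_genes()] and passed in, and rescaled with
#' [scale_depth()]). Step 3 assigns the sampled counts to locations by the
#' rank order of the reference expression ([rank_assign()]), preserving each
#' gene's spatial pattern. With new locations, ranking uses a pseudo-reference
#' built by sampling counts from each new location's k nearest reference
#' neighbours ([impute_reference_at_new_locations()]); model fitting always
#' uses the original reference counts.
#'
#' `simulate_tissue()` fits and ranks over the whole tissue;
#' `simulate_domains()` performs fitting, sampling and ranking independently
#' within each spatial domain before reassembling the tissue, which sharpens
#' the contrast between domains.
#'
#' @param ref An [srt_data] reference (with domain labels for
#'   `simulate_domains()`; every domain needs >= 2 locations).
#' @param new_locations Optional list `list(n = <int>, layout = "grid"|"random")`
#'   requesting freshly generated locations.
#' @param k_neighbors Neighbour count for pseudo-reference imputation and
#'   domain-label transfer (default 3).
#' @param depth_factor Positive multiplier applied to every fitted mean
#'   before sampling (default 1); see [scale_depth()].
#' @param concavity Concave-hull parameter for the tissue outline when new
#'   locations are generated.
#' @param seed Integer seed; identical inputs and seed reproduce the output
#'   exactly.
#' @param fits Optional precomputed fit tibble from [fit_genes()] (tissue
#'   mode for `simulate_tissue`, domain mode for `simulate_domains`).
#' @return An `srt_sim` object: list with `data` (synthetic [srt_data]),
#'   `fits` (per-gene, per-domain fit tibble), `config` and `seed`.
#' @export
simulate_tissue <- function(ref, new_locations = NULL, k_neighbors = 3,
                            depth_factor = 1, concavity = 2, seed = 1,
                            fits = NULL) {
  simulate_reference_based(ref, mode = "tissue", new_locations = new_locations,
                           k_neighbors = k_neighbors, depth_factor = depth_factor,
                           concavity = concavity, seed = seed, fits = fits)
}

#' @rdname simulate_tissue
#' @export
simulate_domains <- function(ref, new_locations = NULL, k_neighbors = 3,
                             depth_factor = 1, concavity = 2, seed = 1,
                             fits = NULL) {
  simulate_reference_based(ref, mode = "domain", new_locations = new_locations,
                           k_neighbors = k_neighbors, depth_factor = depth_factor,
                           concavity = concavity, seed = seed, fits = fits)
}

simulate_reference_based <- function(ref, mode, new_locations, k_neighbors,
                                     depth_factor, concavity, seed, fits) {
  stopifnot(inherits(ref, "srt_data"))
  if (mode == "domain" && is.null(ref$domains)) {
    abort("domain-specific simulation requires a reference with domain labels")
  }
  config <- list(mode = mode, new_locations = new_locations,
                 k_neighbors = k_neighbors, depth_factor = depth_factor,
                 concavity = concavity)

  # Step 2 (fitting) always uses the original reference counts
  fits <- fits %||% fit_genes(ref, mode)
  fits <- scale_depth(fits, depth_factor)

  # Step 1: locations
  if (is.null(new_locations)) {
    coords <- ref$coords
    domains <- if (mode == "domain" || !is.null(ref$domains)) ref$domains
    ref_expr <- ref$counts
  } else {
    shape <- estimate_shape(ref$coords[, c("x", "y")], concavity = concavity)
    pts <- switch(new_locations$layout %||% "random",
      grid = generate_grid_locations(shape, new_locations$n),
      random = generate_random_locations(shape, new_locations$n,
                                         seed = substream_seed(seed, 11L)),
      abort("`new_locations$layout` must be 'grid' or 'random'"))
    coords <- tibble::tibble(location_id = sprintf("loc_%05d", seq_len(nrow(pts))),
                             x = pts$x, y = pts$y)
    domains <- if (!is.null(ref$domains)) {
      transfer_domain_labels(ref$coords[, c("x", "y")], ref$domains,
                             pts, k = k_neighbors)
    }
    # Step 3 pseudo-reference for ranking only; within-domain in domain mode
    # so expression never leaks across domain boundaries
    ref_expr <- impute_pseudo_reference(ref, pts, domains, mode, k_neighbors,
                                        seed = substream_seed(seed, 12L))
  }
  n_loc <- nrow(coords)

  counts <- matrix(0, nrow(ref$counts), n_loc,
                   dimnames = list(gene_ids(ref), coords$location_id))
  blocks <- if (mode == "tissue") {
    list(list(domain = NA_character_, cols = seq_len(n_loc)))
  } else {
    lapply(unique(domains), function(d) list(domain = d, cols = which(domains == d)))
  }
  for (b in blocks) {
    if (length(b$cols) == 0) next
    bf <- if (is.na(b$domain)) fits else fits[fits$domain == b$domain, ]
    bf <- bf[match(gene_ids(ref), bf$gene_id), ]
    for (g in seq_len(nrow(counts))) {
      gseed <- substream_seed(seed, 13L, g,
                              if (is.na(b$domain)) 0L else match(b$domain, unique(domains)))
      counts[g, b$cols] <- with_substream(gseed, {
        sim <- sample_counts_local(as.list(bf[g, ]), length(b$cols))
        rank_assign_local(sim, ref_expr[g, b$cols])
      })
    }
  }

  new_srt_sim(srt_data(counts, coords, domains), fits, config, seed)
}

impute_pseudo_reference <- function(ref, new_pts, new_domains, mode, k, seed) {
  if (mode == "tissue" || is.null(new_domains)) {
    return(impute_reference_at_new_locations(ref, new_pts, k = k, seed = seed))
  }
  out <- matrix(0, nrow(ref$counts), nrow(new_pts),
                dimnames = list(gene_ids(ref), NULL))
  for (d in unique(new_domains)) {
    cols_new <- which(new_domains == d)
    cols_ref <- which(ref$domains == d)
    if (length(cols_ref) == 0) {
      abort(sprintf("no reference locations carry transferred domain '%s'", d))
    }
    sub <- srt_data(ref$counts[, cols_ref, drop = FALSE],
                    ref$coords[cols_ref, ],
                    ref$domains[cols_ref])
    out[, cols_new] <- impute_reference_at_new_locations(
      sub, new_pts[cols_new, , drop = FALSE],
      k = min(k, length(cols_ref)), seed = substream_seed(seed, match(d, unique(new_domains))))
  }
  out
}

#' Pseudo-reference expression at freshly generated locations
#'
#' For each new location, finds its `k` nearest reference locations and, per
#' gene, samples one of the neighbours' counts uniformly (with replacement).
#' The resulting matrix carries the reference's spatial pattern onto the new
#' locations and is used only to rank them; model fitting stays on the
#' original reference counts.
#'
#' @param ref An [srt_data] reference.
#' @param new_coords Coordinates of the new locations.
#' @param k Neighbour count (default 3; must not exceed the reference size).
#' @param seed Integer seed.
#' @return A genes x new-locations numeric matrix; every entry is an element
#'   of the corresponding neighbour multiset.
#' @export
impute_reference_at_new_locations <- function(ref, new_coords, k = 3, seed = 1) {
  stopifnot(inherits(ref, "srt_data"))
  if (ncol(ref$counts) == 0) abort("empty reference")
  pts <- as_coords_matrix(new_coords)
  nn <- knn_indices(pts, as.matrix(ref$coords[, c("x", "y")]), k)
  n_new <- nrow(pts)
  out <- matrix(0, nrow(ref$counts), n_new,
                dimnames = list(gene_ids(ref), NULL))
  for (g in seq_len(nrow(out))) {
    pick <- with_substream(substream_seed(seed, 401L, g),
                           sample.int(k, n_new, replace = TRUE))
    out[g, ] <- ref$counts[g, nn[cbind(seq_len(n_new), pick)]]
  }
  out
}

#' Redesign a region's spatial pattern from another region
#'
#' Extrapolates the spatial expression pattern of a source tissue region onto
#' a target region: the concave-hull shape profiles of both regions are
#' estimated, an affine map from the source to the target frame is fitted
#' ([fit_affine()]), the source locations are projected into the target region
#' carrying their reference counts, and the usual new-location machinery then
#' runs on the target with the projected locations as its reference - per
#' target location a count is sampled from the `k` nearest projected
#' locations, target locations are ranked by these pseudo-reference values,
#' and freshly simulated counts (from models fitted to the source-region
#' reference counts) are assigned by rank. Counts outside the target region
#' are left untouched.
#'
#' @param ref An [srt_data] reference.
#' @param source_ids,target_ids Location identifiers of the source and target
#'   regions (each >= 3 locations).
#' @param k Neighbour count for pseudo-reference sampling (default 3).
#' @param concavity Concave-hull parameter for the region outlines.
#' @param seed Integer seed.
#' @param fits Optional precomputed tissue-mode fit tibble of the
#'   source-region counts.
#' @return An `srt_sim` whose `data` equals the reference outside the target
#'   region, with the target columns replaced by the redesigned simulation;
#'   the pseudo-reference matrix and the affine transform are attached as
#'   `pseudo_reference` and `transform`.
#' @export
redesign_region <- function(ref, source_ids, target_ids, k = 3, concavity = 2,
                            seed = 1, fits = NULL) {
  stopifnot(inherits(ref, "srt_data"))
  src_idx <- match(source_ids, location_ids(ref))
  tgt_idx <- match(target_ids, location_ids(ref))
  if (anyNA(src_idx) || anyNA(tgt_idx)) abort("unknown location identifiers")
  if (length(src_idx) < 3 || length(tgt_idx) < 3) {
    abort("both regions need at least 3 locations")
  }
  src_xy <- as.matrix(ref$coords[src_idx, c("x", "y")])
  tgt_xy <- as.matrix(ref$coords[tgt_idx, c("x", "y")])
  src_shape <- estimate_shape(src_xy, concavity = concavity)
  tgt_shape <- estimate_shape(tgt_xy, concavity = concavity)
  trans <- fit_affine(src_shape, tgt_shape)
  proj <- apply_affine(trans, src_xy)

  # projected locations carry the source counts and act as the reference
  src_counts <- ref$counts[, src_idx, drop = FALSE]
  colnames(src_counts) <- paste0("proj_", source_ids)
  proj_ref <- srt_data(src_counts,
                       tibble::tibble(location_id = paste0("proj_", source_ids),
                                      x = proj$x, y = proj$y))
  pseudo <- impute_reference_at_new_locations(proj_ref, tgt_xy,
                                              k = min(k, length(src_idx)),
                                              seed = substream_seed(seed, 21L))
  fits <- fits %||% fit_genes(
    srt_data(ref$counts[, src_idx, drop = FALSE], ref$coords[src_idx, ]),
    "tissue")

  counts <- ref$counts
  for (g in seq_len(nrow(counts))) {
    counts[g, tgt_idx] <- with_substream(substream_seed(seed, 22L, g), {
      sim <- sample_counts_local(as.list(fits[g, ]), length(tgt_idx))
      rank_assign_local(sim, pseudo[g, ])
    })
  }
  out <- new_srt_sim(
    srt_data(counts, ref$coords, ref$domains), fits,
    list(mode = "redesign", source_ids = source_ids, target_ids = target_ids,
         k_neighbors = k, concavity = concavity),
    seed)
  out$pseudo_reference <- pseudo
  out$transform <- trans
  out
}

# ---- srt_sim -----------------------------------------------------------------

new_srt_sim <- function(data, fits, config, seed) {
  structure(list(data = data, fits = fits, config = config, seed = seed),
            class = "srt_sim")
}

#' @export
print.srt_sim <- function(x, ...) {
  cat(sprintf("<srt_sim> mode '%s', seed %d\n",
              x$config$mode %||% "?", x$seed))
  print(x$data)
  invisible(x)
}

#' Tidy and summarise simulation outputs
#'
#' `tidy()` returns the per-gene (per-domain) fit table behind the
#' simulation; `glance()` a one-row summary of the synthetic dataset.
#'
#' @param x An `srt_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy srt_sim
#' @export
tidy.srt_sim <- function(x, ...) tibble::as_tibble(x$fits)

#' @rdname tidy.srt_sim
#' @method glance srt_sim
#' @export
glance.srt_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mode = x$config$mode %||% NA_character_, seed = x$seed),
    glance(x$data)
  )
}
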