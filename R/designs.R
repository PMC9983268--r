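#' Spatial-expression benchmark datasets with known truth
#'
#' Generates a null or alternative dataset for benchmarking spatial
#' expression (SE) analysis over a fixed tissue geometry with domain labels.
#' All genes are negative binomial with a shared dispersion. Non-SE genes
#' draw every location from `NB(baseline_mu, phi)` and are allocated at
#' random, so they carry no spatial pattern. SE genes keep the baseline mean
#' outside the target domain and use `fold * baseline_mu` inside it; the
#' folds vector is split equally across the SE genes (the default
#' `c(5, 1/5)` gives 50 up- and 50 down-regulated genes per 100 SE genes,
#' the low-strength sparse-platform setting; use `c(10, 1/10)` for the
#' high-strength setting, or `c(3, 1/3)` / `c(4, 1/4)` for moderate-count
#' single-cell-resolution regimes with `baseline_mu = 0.4`, `phi = 0.35`).
#'
#' @param template An [srt_data] with domain labels (its counts are ignored),
#'   or a list/tibble with `coords` and `domains`.
#' @param target_domain The domain carrying the SE signal.
#' @param n_genes Total genes (default 1000).
#' @param n_se Number of SE genes (default 100; 0 gives the null design).
#' @param baseline_mu Baseline NB mean (default 0.03, the sparse
#'   array-capture regime).
#' @param phi Shared NB overdispersion (default 0.3).
#' @param folds Positive fold changes cycled over the SE genes in equal
#'   blocks (default `c(5, 1/5)`); `n_se` must be divisible by its length.
#' @param seed Integer seed.
#' @return A list with `data` (the synthetic [srt_data]) and `truth` (tibble:
#'   `gene_id`, `is_se`, `fold`, `direction`, `domain`).
#' @export
se_benchmark <- function(template, target_domain, n_genes = 1000, n_se = 100,
                         baseline_mu = 0.03, phi = 0.3, folds = c(5, 1 / 5),
                         seed = 1) {
  coords <- if (inherits(template, "srt_data")) template$coords else template$coords
  domains <- if (inherits(template, "srt_data")) template$domains else template$domains
  if (is.null(domains)) abort("the template must carry domain labels")
  if (n_se > 0 && !target_domain %in% domains) {
    abort(sprintf("unknown domain '%s'", target_domain))
  }
  if (n_se > n_genes) abort("`n_se` must not exceed `n_genes`")
  if (any(folds <= 0)) abort("folds must be positive")
  if (n_se %% max(length(folds), 1) != 0) {
    abort("`n_se` must be divisible by the number of folds")
  }
  n_loc <- nrow(coords)
  inside <- domains == target_domain
  gene_fold <- c(rep(folds, each = n_se / max(length(folds), 1)),
                 rep(1, n_genes - n_se))
  is_se <- c(rep(TRUE, n_se), rep(FALSE, n_genes - n_se))
  counts <- matrix(0, n_genes, n_loc,
                   dimnames = list(sprintf("gene_%04d", seq_len(n_genes)),
                                   coords$location_id))
  for (g in seq_len(n_genes)) {
    counts[g, ] <- with_substream(substream_seed(seed, 61L, g), {
      x <- rnbinom(n_loc, size = 1 / phi, mu = baseline_mu)
      x <- x[sample.int(n_loc)]  # random allocation: no spatial pattern
      if (is_se[g]) {
        x[inside] <- rnbinom(sum(inside), size = 1 / phi,
                             mu = baseline_mu * gene_fold[g])
      }
      x
    })
  }
  truth <- tibble::tibble(
    gene_id = rownames(counts),
    is_se = is_se,
    fold = ifelse(is_se, gene_fold, NA_real_),
    direction = dplyr::case_when(!is_se ~ NA_character_,
                                 gene_fold > 1 ~ "up",
                                 gene_fold < 1 ~ "down",
                                 TRUE ~ "none"),
    domain = ifelse(is_se, target_domain, NA_character_)
  )
  list(data = srt_data(counts, coords, domains), truth = truth)
}

#' Experimental-design grids for spatial clustering benchmarks
#'
#' Produces domain-specific simulations under three experimental-design
#' scenarios: (I) vary the total sequencing depth at the reference's
#' locations (`depth_factors` multiply the reference total; the defaults
#' 0.5-3 mirror 50%-300% of an observed depth); (II) vary the number of
#' measured locations while holding the total depth at the reference's
#' observed total (each run's per-location mean is scaled by
#' `n_ref / n_new`); (III) the cross-product of the depth factors and
#' location numbers at fixed per-location depth (each run scales the
#' per-location mean by the depth factor alone).
#'
#' @param ref An [srt_data] reference with domain labels.
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param depth_factors Multipliers of the reference total depth
#'   (scenarios I and III).
#' @param n_locations Location numbers (scenarios II and III); defaults to
#'   a sweep including the reference's own location count.
#' @param layout Layout for newly generated locations.
#' @param seed Integer seed.
#' @param fits Optional precomputed domain-mode fit tibble.
#' @return A tibble with one row per design cell: `scenario`,
#'   `depth_factor`, `n_locations` and a list-column `sim` of `srt_sim`
#'   objects.
#' @export
clustering_scenarios <- function(ref, scenario = c("I", "II", "III"),
                                 depth_factors = c(0.5, 1, 1.5, 2, 3),
                                 n_locations = NULL, layout = "random",
                                 seed = 1, fits = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(ref, "srt_data"))
  if (any(depth_factors <= 0)) abort("depth factors must be positive")
  n_ref <- ncol(ref$counts)
  n_locations <- n_locations %||% sort(unique(c(100, 300, 1000, 2000, n_ref, 5000)))
  if (any(n_locations < 1)) abort("location numbers must be positive")
  fits <- fits %||% fit_genes(ref, "domain")
  grid <- switch(scenario,
    I = tibble::tibble(depth_factor = depth_factors, n_locations = n_ref),
    II = tibble::tibble(depth_factor = n_ref / n_locations, n_locations = n_locations),
    III = tidyr::expand_grid(depth_factor = depth_factors,
                             n_locations = n_locations)
  )
  grid$scenario <- scenario
  grid$sim <- purrr::pmap(grid[, c("depth_factor", "n_locations")], function(depth_factor, n_locations) {
    new_loc <- if (n_locations == n_ref) NULL else list(n = n_locations, layout = layout)
    simulate_domains(ref, new_locations = new_loc, depth_factor = depth_factor,
                     seed = substream_seed(seed, 71L,
                                           round(depth_factor * 1000), n_locations),
                     fits = fits)
  })
  grid[, c("scenario", "depth_factor", "n_locations", "sim")]
}

#' Synthetic ligand-receptor pair list
#'
#' Generates a synthetic stand-in for a curated ligand-receptor resource:
#' `n_pairs` distinct (ligand, receptor) gene pairs drawn from `n_ligands`
#' ligand genes and `n_receptors` receptor genes, with a controlled overlap
#' so the union spans `n_unique_genes` distinct genes (defaults mirror a
#' 930-pair, 445-ligand, 471-receptor, 691-gene resource). Entirely
#' synthetic: gene identifiers are generated, not curated.
#'
#' @param n_pairs,n_ligands,n_receptors,n_unique_genes Resource dimensions.
#' @param seed Integer seed.
#' @return A tibble with columns `ligand`, `receptor`.
#' @export
make_lr_pairs <- function(n_pairs = 930, n_ligands = 445, n_receptors = 471,
                          n_unique_genes = 691, seed = 1) {
  n_shared <- n_ligands + n_receptors - n_unique_genes
  if (n_shared < 0) abort("n_unique_genes exceeds n_ligands + n_receptors")
  genes <- sprintf("lrg_%04d", seq_len(n_unique_genes))
  ligands <- genes[seq_len(n_ligands)]
  receptors <- genes[(n_ligands - n_shared + 1):n_unique_genes]
  with_substream(substream_seed(seed, 81L), {
    seen <- character(0)
    out_l <- character(0); out_r <- character(0)
    # guarantee every ligand and receptor occurs at least once
    out_l <- c(ligands, sample(ligands, n_receptors, replace = TRUE))
    out_r <- c(sample(receptors, n_ligands, replace = TRUE), receptors)
    key <- paste(out_l, out_r)
    keep <- !duplicated(key)
    out_l <- out_l[keep]; out_r <- out_r[keep]; seen <- key[keep]
    while (length(out_l) < n_pairs) {
      m <- n_pairs - length(out_l)
      l <- sample(ligands, 2 * m, replace = TRUE)
      r <- sample(receptors, 2 * m, replace = TRUE)
      key <- paste(l, r)
      ok <- !(key %in% seen) & !duplicated(key)
      out_l <- c(out_l, l[ok]); out_r <- c(out_r, r[ok])
      seen <- c(seen, key[ok])
    }
    tibble::tibble(ligand = out_l[seq_len(n_pairs)],
                   receptor = out_r[seq_len(n_pairs)])
  })
}

#' Assign ligand-receptor pairs to ordered cell-type pairs
#'
#' Each L-R pair is independently assigned uniformly at random to one of the
#' `n_types^2` ordered cell-type pairs (A, B) - self-pairs A = B included -
#' creating the scenario that type A signals to adjacent type B through the
#' pair.
#'
#' @param lr_pairs Tibble with columns `ligand`, `receptor` (see
#'   [make_lr_pairs()]).
#' @param n_types Number of cell types (default 4, giving 16 ordered pairs).
#' @param seed Integer seed.
#' @return `lr_pairs` with added integer columns `type_a`, `type_b`.
#' @export
assign_lr_type_pairs <- function(lr_pairs, n_types = 4, seed = 1) {
  n <- nrow(lr_pairs)
  with_substream(substream_seed(seed, 82L), {
    pair_idx <- sample.int(n_types^2, n, replace = TRUE)
    dplyr::mutate(lr_pairs,
                  type_a = (pair_idx - 1L) %/% n_types + 1L,
                  type_b = (pair_idx - 1L) %% n_types + 1L)
  })
}

ccc_compositions <- list(
  c(0.70, 0.10, 0.10, 0.10),
  c(0.45, 0.45, 0.05, 0.05),
  c(0.60, 0.30, 0.05, 0.05),
  c(0.35, 0.30, 0.30, 0.05)
)

#' Cell-cell-communication benchmark generator
#'
#' Builds a single-cell-resolution dataset with a known set of interacting
#' ligand-receptor-celltype (L-R-A-B) pairs. The tissue outline is estimated
#' from `shape_source` (concave hull) and `n_locations` uniform cell
#' positions are drawn inside it. The positions are split into four
#' equal-count regions along the first principal axis of the point cloud,
#' and each cell's type is drawn from a multinomial whose probabilities are
#' the scenario's composition vector rotated per region (region r ranks
#' types r, r+1, r+2, r+3 from most to least abundant, modulo 4). A pool of
#' `cells_per_type * 4` cells is simulated - homogeneous mode draws every
#' gene for all pool cells from one shared NB and assigns types at random;
#' heterogeneous mode draws from type-specific NB parameters (synthetic
#' ground-truth parameters standing in for cell-type profiles of a real
#' single-cell reference) - and cells of the demanded types are sampled from
#' the pool onto the positions (with replacement only if a type's demand
#' exceeds the pool). Each L-R pair is assigned an ordered type pair (A, B);
#' for every A-cell with a B-cell among its `n_adjacent` nearest neighbours,
#' the ligand gene's count in that A-cell is multiplied by `fold` (rounded
#' to the nearest integer). When the same ligand gene occurs in several
#' pairs, a given cell is boosted at most once. `fold = 1` is the null
#' design and leaves the matrix untouched.
#'
#' @param shape_source An [srt_data] (its locations define the outline) or a
#'   [shape_profile].
#' @param scenario Composition scenario 1-4: dominant proportions
#'   (0.70, 0.10, 0.10, 0.10), (0.45, 0.45, 0.05, 0.05),
#'   (0.60, 0.30, 0.05, 0.05) or (0.35, 0.30, 0.30, 0.05).
#' @param n_locations Number of cell positions (default 5000).
#' @param n_genes Number of genes (default 5000); must cover all L-R genes.
#' @param cells_per_type Pool cells per type (default 2000).
#' @param expression_mode `"homogeneous"` or `"heterogeneous"`.
#' @param lr_pairs L-R pair tibble (default [make_lr_pairs()]).
#' @param fold Ligand boost fold (>= 1; 1, 5 or 10 in the canonical
#'   designs).
#' @param n_adjacent Neighbours defining adjacency (default 4).
#' @param mu_range Log-uniform range of gene-level NB means (default
#'   0.05-2, a moderate single-cell-resolution regime).
#' @param phi Gene-level NB overdispersion (default 0.35).
#' @param concavity Concave-hull parameter.
#' @param seed Integer seed.
#' @return A list with `data` (an [srt_data]; cell types stored as domain
#'   labels, regions in `data$coords$region`), `counts_unboosted` (the
#'   pre-boost matrix), `truth` (the L-R-A-B assignment with `interacting`
#'   indicator), and `boosted` (tibble of boosted gene/cell entries).
#' @export
ccc_benchmark <- function(shape_source, scenario = 1, n_locations = 5000,
                          n_genes = 5000, cells_per_type = 2000,
                          expression_mode = c("heterogeneous", "homogeneous"),
                          lr_pairs = NULL, fold = 1, n_adjacent = 4,
                          mu_range = c(0.05, 2), phi = 0.35,
                          concavity = 2, seed = 1) {
  expression_mode <- match.arg(expression_mode)
  stopifnot(scenario %in% 1:4, fold >= 1)
  n_types <- 4L
  comp <- ccc_compositions[[scenario]]
  lr_pairs <- lr_pairs %||% make_lr_pairs(seed = substream_seed(seed, 90L))

  shape <- if (inherits(shape_source, "shape_profile")) shape_source else {
    estimate_shape(shape_source$coords[, c("x", "y")], concavity = concavity)
  }
  pts <- generate_random_locations(shape, n_locations,
                                   seed = substream_seed(seed, 91L))

  # four equal-count regions along the first principal axis of the positions
  pc1 <- prcomp(as.matrix(pts), center = TRUE, scale. = FALSE)$x[, 1]
  region <- as.integer(cut(rank(pc1, ties.method = "first"),
                           breaks = seq(0, n_locations, length.out = 5),
                           labels = FALSE))

  # per-region type composition: region r puts types (r, r+1, r+2, r+3) mod 4
  # at the scenario's proportions, most to least abundant
  type_probs <- matrix(0, n_types, n_types)  # region x type
  for (r in seq_len(n_types)) {
    types_ranked <- ((r - 1 + 0:3) %% n_types) + 1
    type_probs[r, types_ranked] <- comp
  }
  cell_type <- with_substream(substream_seed(seed, 92L), {
    vapply(region, function(r) sample.int(n_types, 1, prob = type_probs[r, ]),
           integer(1))
  })

  # expression pool: cells_per_type cells per type
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  lr_genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  if (length(lr_genes) > n_genes) {
    abort("`n_genes` is too small to host all ligand/receptor genes")
  }
  gene_ids[seq_along(lr_genes)] <- lr_genes
  pool <- with_substream(substream_seed(seed, 93L), {
    mu_g <- exp(runif(n_genes, log(mu_range[1]), log(mu_range[2])))
    if (expression_mode == "homogeneous") {
      m <- matrix(rnbinom(n_genes * cells_per_type * n_types,
                          size = 1 / phi, mu = mu_g),
                  nrow = n_genes)  # recycles mu_g down columns
      type_of_pool <- sample(rep(seq_len(n_types), cells_per_type))
    } else {
      # type-specific means: synthetic ground-truth fold per (gene, type)
      type_fac <- matrix(exp(stats::rnorm(n_genes * n_types, 0, 0.5)),
                         n_genes, n_types)
      m <- matrix(0, n_genes, cells_per_type * n_types)
      type_of_pool <- rep(seq_len(n_types), each = cells_per_type)
      for (t in seq_len(n_types)) {
        cols <- which(type_of_pool == t)
        m[, cols] <- rnbinom(n_genes * length(cols), size = 1 / phi,
                             mu = mu_g * type_fac[, t])
      }
      m
    }
    list(counts = m, type = type_of_pool)
  })

  # place pool cells of the demanded type onto positions
  assignment <- with_substream(substream_seed(seed, 94L), {
    idx <- integer(n_locations)
    for (t in seq_len(n_types)) {
      need <- which(cell_type == t)
      avail <- which(pool$type == t)
      if (length(avail) == 0) abort(sprintf("no pool cells of type %d", t))
      idx[need] <- sample(avail, length(need), replace = length(need) > length(avail))
    }
    idx
  })
  counts <- pool$counts[, assignment, drop = FALSE]
  dimnames(counts) <- list(gene_ids, sprintf("cell_%05d", seq_len(n_locations)))
  counts_unboosted <- counts

  truth <- assign_lr_type_pairs(lr_pairs, n_types,
                                seed = substream_seed(seed, 95L))
  truth$interacting <- fold > 1

  # adjacency boost: A-cells with a B-cell among their n_adjacent nearest
  nn <- knn_indices(as.matrix(pts), as.matrix(pts), n_adjacent, exclude_self = TRUE)
  boosted <- tibble::tibble(gene_id = character(0), cell_id = character(0))
  if (fold > 1) {
    boost_mask <- matrix(FALSE, n_genes, n_locations,
                         dimnames = dimnames(counts))
    adj_types <- matrix(cell_type[nn], nrow = n_locations)
    for (p in seq_len(nrow(truth))) {
      a_cells <- which(cell_type == truth$type_a[p])
      if (length(a_cells) == 0) next
      has_b <- rowSums(adj_types[a_cells, , drop = FALSE] == truth$type_b[p]) > 0
      boost_mask[truth$ligand[p], a_cells[has_b]] <- TRUE
    }
    counts[boost_mask] <- round(counts[boost_mask] * fold)
    idx <- which(boost_mask, arr.ind = TRUE)
    boosted <- tibble::tibble(gene_id = rownames(boost_mask)[idx[, 1]],
                              cell_id = colnames(boost_mask)[idx[, 2]])
  }

  coords <- tibble::tibble(location_id = colnames(counts),
                           x = pts$x, y = pts$y, region = region)
  data <- srt_data(counts, coords[, c("location_id", "x", "y")],
                   domains = paste0("type_", cell_type))
  data$coords$region <- region
  list(data = data, counts_unboosted = counts_unboosted, truth = truth,
       boosted = boosted,
       config = list(scenario = scenario, fold = fold,
                     expression_mode = expression_mode,
                     n_adjacent = n_adjacent, seed = seed))
}
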