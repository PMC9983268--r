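#' Construct primitive tissue shapes
#'
#' Builds a [shape_profile] from a named primitive: a circle (discretised as
#' a regular polygon), an axis-aligned square, or an annulus. The annulus is
#' realised as a single simple polygon via a narrow angular slit joining the
#' outer and inner rings, so that even-odd containment tests exclude the
#' hole; its area differs from the ideal ring area only by the slit and the
#' discretisation error. Arbitrary user polygons can be supplied directly to
#' [shape_profile()] or loaded from a vertex CSV with [read_shape()].
#'
#' @param type `"circle"`, `"square"` or `"annulus"`.
#' @param center Length-2 centre.
#' @param r Circle radius.
#' @param side Square side length.
#' @param r_in,r_out Annulus inner/outer radii (`0 < r_in < r_out`).
#' @param n_vertices Vertices used to discretise each circular arc
#'   (default 64, minimum 16).
#' @return A [shape_profile].
#' @export
#' @examples
#' shape_area(make_shape("square", side = 2))              # 4
#' shape_area(make_shape("circle", r = 1, n_vertices = 256))  # ~ pi
make_shape <- function(type = c("circle", "square", "annulus"),
                       center = c(0, 0), r = 1, side = 1,
                       r_in = 0.5, r_out = 1, n_vertices = 64) {
  type <- match.arg(type)
  n_vertices <- max(16L, as.integer(n_vertices))
  if (type == "square") {
    if (side <= 0) abort("`side` must be positive")
    h <- side / 2
    v <- cbind(center[1] + c(-h, h, h, -h), center[2] + c(-h, -h, h, h))
    return(shape_profile(v))
  }
  if (type == "circle") {
    if (r <= 0) abort("`r` must be positive")
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    return(shape_profile(cbind(center[1] + r * cos(th), center[2] + r * sin(th))))
  }
  if (r_in <= 0 || r_out <= r_in) abort("annulus requires 0 < r_in < r_out")
  eps <- 1e-4 * 2 * pi / n_vertices  # slit half-width (radians)
  th_out <- seq(eps, 2 * pi - eps, length.out = n_vertices)
  th_in <- rev(th_out)
  v <- rbind(
    cbind(center[1] + r_out * cos(th_out), center[2] + r_out * sin(th_out)),
    cbind(center[1] + r_in * cos(th_in), center[2] + r_in * sin(th_in))
  )
  shape_profile(v)
}

#' Specify a reference-free simulation design
#'
#' A `free_design` fully describes a de novo simulation: the tissue shape,
#' how many locations to place and how, the spatial domains, a per-gene (or
#' shared) count model, and per-domain mean fold changes. Domains may be
#' given as a function of the coordinates returning one label per location,
#' or as a named list of [shape_profile]s labelled by containment (listed
#' from outermost to innermost; later shapes override earlier ones at
#' interior points, while on boundary ties the outermost label wins because
#' overriding requires strict containment). Locations outside every domain
#' shape carry the `base_domain` label.
#'
#' @param shape A [shape_profile] (see [make_shape()]).
#' @param n_locations Number of locations (>= 1).
#' @param layout `"grid"` or `"random"`.
#' @param model A tibble/data frame with one row per gene (columns `family`,
#'   `mu`, optionally `phi`, `pi0`, `gene_id`), or a single-row specification
#'   shared by `n_genes` genes.
#' @param n_genes Gene count when `model` is shared.
#' @param domains `NULL` (single domain), a labelling function
#'   `function(coords) labels`, or a named list of [shape_profile]s.
#' @param fold Named numeric vector of positive per-domain mean fold changes
#'   (mean inside the domain versus the tissue baseline); unlisted domains
#'   default to 1. Folds scale the count-component mean `mu` only; `phi` and
#'   `pi0` are untouched.
#' @param base_domain Label for locations outside all domain shapes.
#' @param seed Integer seed.
#' @return A `free_design` object.
#' @export
free_design <- function(shape, n_locations, layout = c("random", "grid"),
                        model, n_genes = NULL, domains = NULL,
                        fold = numeric(), base_domain = "background",
                        seed = 1) {
  layout <- match.arg(layout)
  stopifnot(inherits(shape, "shape_profile"), n_locations >= 1)
  model <- tibble::as_tibble(model)
  if (!"family" %in% names(model) || !"mu" %in% names(model)) {
    abort("`model` needs columns `family` and `mu`")
  }
  if (!"phi" %in% names(model)) model$phi <- NA_real_
  if (!"pi0" %in% names(model)) model$pi0 <- NA_real_
  if (nrow(model) == 1 && !is.null(n_genes)) {
    model <- model[rep(1, n_genes), ]
  }
  if (!"gene_id" %in% names(model)) {
    model$gene_id <- sprintf("gene_%04d", seq_len(nrow(model)))
  }
  if (any(model$mu < 0)) abort("baseline `mu` must be non-negative")
  if (length(fold) > 0 && (is.null(names(fold)) || any(fold <= 0))) {
    abort("`fold` must be a named vector of positive values")
  }
  structure(list(shape = shape, n_locations = n_locations, layout = layout,
                 model = model, domains = domains, fold = fold,
                 base_domain = base_domain, seed = seed),
            class = "free_design")
}

#' Run a reference-free simulation
#'
#' Generates locations inside the design's shape, labels them with spatial
#' domains, and simulates each gene independently: counts for the locations
#' of a domain are drawn from the gene's count model with the count-component
#' mean multiplied by the domain's fold change, then allocated uniformly at
#' random among that domain's locations - so genes show domain-specific mean
#' shifts but no spatial structure inside a domain.
#'
#' @param design A [free_design].
#' @return An `srt_sim` object.
#' @export
simulate_free <- function(design) {
  stopifnot(inherits(design, "free_design"))
  seed <- design$seed
  pts <- switch(design$layout,
    grid = generate_grid_locations(design$shape, design$n_locations),
    random = generate_random_locations(design$shape, design$n_locations,
                                       seed = substream_seed(seed, 51L)))
  domains <- assign_free_domains(design, pts)
  fold <- design$fold
  if (length(fold) > 0 && !all(names(fold) %in% domains)) {
    missing <- setdiff(names(fold), domains)
    abort(sprintf("fold specified for absent domain(s): %s",
                  paste(missing, collapse = ", ")))
  }
  doms <- unique(domains)
  fold_of <- function(d) if (d %in% names(fold)) fold[[d]] else 1

  model <- design$model
  n_loc <- nrow(pts)
  counts <- matrix(0, nrow(model), n_loc,
                   dimnames = list(model$gene_id,
                                   sprintf("loc_%05d", seq_len(n_loc))))
  for (g in seq_len(nrow(model))) {
    counts[g, ] <- with_substream(substream_seed(seed, 52L, g), {
      row <- numeric(n_loc)
      for (d in doms) {
        cols <- which(domains == d)
        fit <- list(family = model$family[g], mu = model$mu[g] * fold_of(d),
                    phi = model$phi[g], pi0 = model$pi0[g])
        drawn <- sample_counts_local(fit, length(cols))
        row[cols] <- drawn[sample.int(length(cols))]  # random within-domain allocation
      }
      row
    })
  }
  coords <- tibble::tibble(location_id = colnames(counts), x = pts$x, y = pts$y)
  new_srt_sim(
    srt_data(counts, coords, domains),
    dplyr::mutate(model, loglik = NA_real_, aic = NA_real_),
    list(mode = "free", layout = design$layout, fold = as.list(fold)),
    seed)
}

assign_free_domains <- function(design, pts) {
  d <- design$domains
  if (is.null(d)) return(rep(design$base_domain, nrow(pts)))
  if (is.function(d)) {
    labs <- as.character(d(pts))
    if (length(labs) != nrow(pts)) {
      abort("domain labelling function must return one label per location")
    }
    return(labs)
  }
  if (is.list(d) && all(vapply(d, inherits, logical(1), "shape_profile"))) {
    if (is.null(names(d))) abort("domain shapes must be named")
    labs <- rep(design$base_domain, nrow(pts))
    for (nm in names(d)) {
      inside <- shape_contains(d[[nm]], pts, boundary = FALSE)
      labs[inside] <- nm
    }
    return(labs)
  }
  abort("`domains` must be NULL, a function, or a named list of shape profiles")
}
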