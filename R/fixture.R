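#' Generate a synthetic reference dataset with known ground truth
#'
#' Builds an SRT dataset from fully specified per-gene count models, for use
#' as a reference in simulations and as a test bed with recoverable truth.
#' Gene-level parameters are drawn from the supplied ranges: `mu`
#' log-uniform over `mu_range`, `phi` uniform over `phi_range`, `pi0`
#' uniform over `pi0_range` (zero-inflated families only). Locations are a
#' square grid or uniform random points on the unit square; domains are
#' horizontal bands of (near-)equal size when `pattern = "layered"`
#' (contiguous, like cortical layers) or i.i.d. labels when
#' `pattern = "random"`. A fraction of genes (`n_pattern`) is spatially
#' structured: each such gene picks one domain and multiplies its
#' count-component mean there by `pattern_fold`, so the dataset contains
#' both strongly layered and unstructured genes. The defaults emulate a
#' sparse array-capture regime (low means, high zero fraction).
#'
#' @param n_genes,n_locations Dataset dimensions (>= 1).
#' @param layout `"grid"` or `"random"`.
#' @param n_domains Number of spatial domains (>= 1).
#' @param family Count family for all genes (`"nb"`, `"poisson"`, `"zip"`,
#'   `"zinb"`), or a vector to sample from per gene.
#' @param mu_range Log-uniform range for baseline means (default
#'   `c(0.005, 0.5)`, median ~0.05).
#' @param phi_range Uniform range for NB overdispersion.
#' @param pi0_range Uniform range for structural-zero probability.
#' @param pattern `"layered"` (contiguous bands) or `"random"` (no spatial
#'   structure in the domain labels).
#' @param n_pattern Number of spatially structured genes (default 10% of
#'   `n_genes`; 0 for none).
#' @param pattern_fold Mean fold change of structured genes inside their
#'   domain (default 5).
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @return A list with `data` (an [srt_data]) and `truth`, a tibble of the
#'   generating parameters per gene: `gene_id`, `family`, `mu`, `phi`,
#'   `pi0`, `pattern_domain` (`NA` for unstructured genes), `fold`, plus a
#'   nested `domain_means` tibble of the realised count-component mean per
#'   (gene, domain).
#' @export
make_reference_fixture <- function(n_genes = 100, n_locations = 400,
                                   layout = c("grid", "random"),
                                   n_domains = 4,
                                   family = "nb",
                                   mu_range = c(0.005, 0.5),
                                   phi_range = c(0.2, 1.5),
                                   pi0_range = c(0.1, 0.5),
                                   pattern = c("layered", "random"),
                                   n_pattern = round(0.1 * n_genes),
                                   pattern_fold = 5,
                                   seed = 1) {
  layout <- match.arg(layout)
  pattern <- match.arg(pattern)
  stopifnot(n_genes >= 1, n_locations >= 1, n_domains >= 1,
            n_pattern <= n_genes, pattern_fold > 0)
  if (!all(family %in% c("poisson", "zip", "nb", "zinb"))) {
    abort("`family` must be drawn from poisson/zip/nb/zinb")
  }
  if (length(mu_range) != 2 || any(mu_range <= 0) || diff(mu_range) < 0) {
    abort("`mu_range` must be an increasing positive pair")
  }

  coords <- with_substream(substream_seed(seed, 1L), {
    if (layout == "grid") {
      nx <- ceiling(sqrt(n_locations))
      g <- expand.grid(x = seq(0, 1, length.out = nx),
                       y = seq(0, 1, length.out = ceiling(n_locations / nx)))
      g[seq_len(n_locations), ]
    } else {
      data.frame(x = runif(n_locations), y = runif(n_locations))
    }
  })
  domains <- with_substream(substream_seed(seed, 2L), {
    if (n_domains == 1) {
      rep("domain_1", n_locations)
    } else if (pattern == "layered") {
      br <- quantile(coords$y, probs = seq(0, 1, length.out = n_domains + 1))
      br[1] <- -Inf; br[n_domains + 1] <- Inf
      paste0("domain_", as.integer(cut(coords$y, breaks = unique(br),
                                       labels = FALSE)))
    } else {
      paste0("domain_", sample.int(n_domains, n_locations, replace = TRUE))
    }
  })

  truth <- with_substream(substream_seed(seed, 3L), {
    fam <- if (length(family) == 1) rep(family, n_genes) else {
      sample(family, n_genes, replace = TRUE)
    }
    tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      family = fam,
      mu = exp(runif(n_genes, log(mu_range[1]), log(mu_range[2]))),
      phi = ifelse(fam %in% c("nb", "zinb"),
                   runif(n_genes, phi_range[1], phi_range[2]), NA_real_),
      pi0 = ifelse(fam %in% c("zip", "zinb"),
                   runif(n_genes, pi0_range[1], pi0_range[2]), NA_real_),
      pattern_domain = NA_character_,
      fold = 1
    )
  })
  if (n_pattern > 0) {
    dom_levels <- unique(domains)
    picked <- with_substream(substream_seed(seed, 4L),
                             sample(dom_levels, n_pattern, replace = TRUE))
    truth$pattern_domain[seq_len(n_pattern)] <- picked
    truth$fold[seq_len(n_pattern)] <- pattern_fold
  }

  counts <- matrix(0, n_genes, n_locations,
                   dimnames = list(truth$gene_id,
                                   sprintf("loc_%05d", seq_len(n_locations))))
  for (g in seq_len(n_genes)) {
    counts[g, ] <- with_substream(substream_seed(seed, 5L, g), {
      mu_loc <- rep(truth$mu[g], n_locations)
      if (!is.na(truth$pattern_domain[g])) {
        mu_loc[domains == truth$pattern_domain[g]] <-
          truth$mu[g] * truth$fold[g]
      }
      fit <- list(family = truth$family[g], phi = truth$phi[g],
                  pi0 = truth$pi0[g])
      # location-wise means differ for structured genes: draw per location
      draw_counts_mu(fit, mu_loc)
    })
  }
  dom_means <- tidyr::expand_grid(gene_id = truth$gene_id,
                                  domain = unique(domains))
  dom_means <- dplyr::left_join(
    dom_means,
    truth[, c("gene_id", "mu", "fold", "pattern_domain")],
    by = "gene_id")
  dom_means$mean <- with(dom_means,
                         ifelse(!is.na(pattern_domain) & domain == pattern_domain,
                                mu * fold, mu))
  by_gene <- split(dom_means[, c("domain", "mean")], dom_means$gene_id)
  truth$domain_means <- unname(by_gene[truth$gene_id])
  list(data = srt_data(counts, coords, domains), truth = truth)
}

# vectorised draw with a location-specific count-component mean
draw_counts_mu <- function(fit, mu_loc) {
  n <- length(mu_loc)
  x <- switch(fit$family,
    poisson = rpois(n, mu_loc),
    nb = rnbinom(n, size = 1 / fit$phi, mu = mu_loc),
    zip = rpois(n, mu_loc) * (runif(n) >= fit$pi0),
    zinb = rnbinom(n, size = 1 / fit$phi, mu = mu_loc) * (runif(n) >= fit$pi0)
  )
  as.numeric(x)
}
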