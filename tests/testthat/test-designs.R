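se_template <- function(n_loc = 600, n_domains = 4, seed = 19) {
  fx <- make_reference_fixture(n_genes = 2, n_locations = n_loc,
                               layout = "random", n_domains = n_domains,
                               pattern = "layered", n_pattern = 0, seed = seed)
  fx$data
}

test_that("SE alternative designs realise the requested fold changes and truth counts", {
  tpl <- se_template()
  res <- se_benchmark(tpl, target_domain = "domain_2", n_genes = 300,
                      n_se = 100, baseline_mu = 0.4, phi = 0.35,
                      folds = c(5, 1 / 5), seed = 2)
  expect_equal(sum(res$truth$is_se), 100)
  expect_equal(sum(res$truth$direction == "up", na.rm = TRUE), 50)
  expect_equal(sum(res$truth$direction == "down", na.rm = TRUE), 50)
  expect_identical(res$data$domains, tpl$domains)

  inside <- tpl$domains == "domain_2"
  n_in <- sum(inside); n_out <- sum(!inside)
  for (fold in c(5, 1 / 5)) {
    genes <- which(res$truth$is_se & res$truth$fold == fold)
    m_in <- mean(res$data$counts[genes, inside])
    m_out <- mean(res$data$counts[genes, !inside])
    mu_in <- 0.4 * fold
    se_in <- sqrt((mu_in + 0.35 * mu_in^2) / (n_in * length(genes)))
    expect_lt(abs(m_in - mu_in), 3 * se_in)
    expect_lt(abs(m_out - 0.4), 3 * sqrt((0.4 + 0.35 * 0.16) / (n_out * length(genes))))
  }
  expect_error(se_benchmark(tpl, target_domain = "no_such", n_genes = 10,
                            n_se = 2), "unknown domain")
})

test_that("SE null designs show no spatial signal: Moran's I inside its permutation band", {
  tpl <- se_template(n_loc = 400)
  res <- se_benchmark(tpl, target_domain = "domain_1", n_genes = 400, n_se = 0,
                      baseline_mu = 0.4, phi = 0.35, seed = 5)
  xy <- as.matrix(res$data$coords[, c("x", "y")])
  W <- Matrix::Matrix(srtgen:::morans_weights(xy, "knn", 5), sparse = TRUE)
  n <- nrow(xy); sW <- sum(W)
  keep <- which(apply(res$data$counts, 1, function(x) length(unique(x)) > 1))
  n_perm <- 199
  inside <- vapply(keep, function(g) {
    x <- res$data$counts[g, ]
    z <- x - mean(x)
    obs <- (n / sW) * sum(z * as.numeric(W %*% z)) / sum(z^2)
    Z <- withr::with_seed(9000 + g,
                          replicate(n_perm, sample(z)))
    nulls <- (n / sW) * colSums(Z * as.matrix(W %*% Z)) / sum(z^2)
    obs > quantile(nulls, 0.025) & obs < quantile(nulls, 0.975)
  }, logical(1))
  expect_gte(mean(inside), 0.93)
})

test_that("simple in/out-domain testing separates SE from non-SE genes", {
  tpl <- se_template(n_loc = 673)
  res <- se_benchmark(tpl, target_domain = "domain_3", n_genes = 500,
                      n_se = 50, baseline_mu = 0.4, phi = 0.35,
                      folds = c(5, 1 / 5), seed = 7)
  inside <- tpl$domains == "domain_3"
  pvals <- apply(res$data$counts, 1, function(x) {
    suppressWarnings(stats::wilcox.test(x[inside], x[!inside])$p.value)
  })
  score <- -log10(pvals)
  lab <- res$truth$is_se
  # AUROC of the score against the truth
  r <- rank(score)
  auroc <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gt(auroc, 0.9)
})

test_that("clustering scenario I scales total depth linearly at fixed locations", {
  fx <- make_reference_fixture(n_genes = 40, n_locations = 250,
                               mu_range = c(0.2, 2), seed = 23)
  fits <- fit_genes(fx$data, "domain")
  grid <- clustering_scenarios(fx$data, scenario = "I",
                               depth_factors = c(0.5, 1), seed = 3, fits = fits)
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$n_locations == 250))
  tot <- vapply(grid$sim, function(s) sum(s$data$counts), numeric(1))
  # expected totals: sum over domains of per-domain fitted means x location counts
  expected1 <- sum(vapply(unique(fx$data$domains), function(d) {
    f <- fits[fits$domain == d, ]
    sum(ifelse(is.na(f$pi0), f$mu, (1 - f$pi0) * f$mu)) * sum(fx$data$domains == d)
  }, numeric(1)))
  expect_lt(abs(tot[2] - expected1), 4 * sqrt(expected1 * 3))
  expect_lt(abs(tot[1] / tot[2] - 0.5), 0.1)
})

test_that("clustering scenarios II and III build the documented design grids", {
  fx <- make_reference_fixture(n_genes = 10, n_locations = 120,
                               mu_range = c(0.2, 1), seed = 29)
  fits <- fit_genes(fx$data, "domain")
  g2 <- clustering_scenarios(fx$data, scenario = "II",
                             n_locations = c(60, 120), seed = 4, fits = fits)
  expect_equal(g2$depth_factor, c(2, 1))  # total fixed: per-location mean doubles
  expect_equal(vapply(g2$sim, function(s) ncol(s$data$counts), numeric(1)),
               c(60, 120))

  g3 <- clustering_scenarios(fx$data, scenario = "III",
                             depth_factors = c(1, 2),
                             n_locations = c(60, 120, 180), seed = 4,
                             fits = fits)
  expect_equal(nrow(g3), 6)  # full cross-product
  expect_setequal(g3$depth_factor, c(1, 2))
})

test_that("synthetic L-R resources have the documented dimensions", {
  lr <- make_lr_pairs(seed = 3)
  expect_equal(nrow(lr), 930)
  expect_false(any(duplicated(paste(lr$ligand, lr$receptor))))
  expect_equal(length(unique(c(lr$ligand, lr$receptor))), 691)
  expect_lte(length(unique(lr$ligand)), 445)
  expect_lte(length(unique(lr$receptor)), 471)

  asg <- assign_lr_type_pairs(lr, n_types = 4, seed = 5)
  expect_equal(nrow(asg), 930)  # conservation over the 16 ordered pairs
  expect_true(all(asg$type_a %in% 1:4 & asg$type_b %in% 1:4))
  expect_equal(sum(table(paste(asg$type_a, asg$type_b))), 930)
})

test_that("CCC generator: compositions, null identity, adjacency boost", {
  res <- ccc_benchmark(make_shape("square", side = 10), scenario = 1,
                       n_locations = 5000, n_genes = 120, cells_per_type = 800,
                       expression_mode = "homogeneous",
                       lr_pairs = make_lr_pairs(n_pairs = 40, n_ligands = 30,
                                                n_receptors = 30,
                                                n_unique_genes = 50, seed = 2),
                       fold = 1, seed = 6)
  # fold = 1 is the null design: exactly the pre-boost matrix
  expect_identical(res$data$counts, res$counts_unboosted)
  expect_false(any(res$truth$interacting))
  # equal-count regions
  expect_equal(as.numeric(table(res$data$coords$region)), rep(1250, 4))
  # scenario 1 region 1: 70% type 1 within binomial 3 SE at 1250 cells
  r1 <- res$data$coords$region == 1
  p1 <- mean(res$data$domains[r1] == "type_1")
  expect_lt(abs(p1 - 0.70), 3 * sqrt(0.7 * 0.3 / 1250))
  # minor types ~10%
  p2 <- mean(res$data$domains[r1] == "type_2")
  expect_lt(abs(p2 - 0.10), 3 * sqrt(0.1 * 0.9 / 1250))

  # fold > 1 boosts exactly the flagged entries by the fold (rounded)
  res5 <- ccc_benchmark(make_shape("square", side = 10), scenario = 1,
                        n_locations = 1500, n_genes = 120, cells_per_type = 500,
                        expression_mode = "heterogeneous",
                        lr_pairs = make_lr_pairs(n_pairs = 40, n_ligands = 30,
                                                 n_receptors = 30,
                                                 n_unique_genes = 50, seed = 2),
                        fold = 5, seed = 6)
  expect_true(all(res5$truth$interacting))
  expect_gt(nrow(res5$boosted), 0)
  idx <- cbind(match(res5$boosted$gene_id, rownames(res5$data$counts)),
               match(res5$boosted$cell_id, colnames(res5$data$counts)))
  expect_equal(res5$data$counts[idx], round(res5$counts_unboosted[idx] * 5))
  untouched <- res5$data$counts
  untouched[idx] <- res5$counts_unboosted[idx]
  expect_identical(untouched, res5$counts_unboosted)

  # boosted A-cells' mean ligand expression rises by about the fold
  m_boost <- mean(res5$counts_unboosted[idx])
  if (m_boost > 0) {
    expect_gt(mean(res5$data$counts[idx]) / m_boost, 4)
  }
})

test_that("CCC generators are deterministic under a fixed seed", {
  args <- list(make_shape("square", side = 4), scenario = 2, n_locations = 600,
               n_genes = 60, cells_per_type = 300,
               lr_pairs = make_lr_pairs(n_pairs = 20, n_ligands = 15,
                                        n_receptors = 15, n_unique_genes = 25,
                                        seed = 4),
               fold = 5, seed = 11)
  r1 <- do.call(ccc_benchmark, args)
  r2 <- do.call(ccc_benchmark, args)
  expect_identical(r1$data$counts, r2$data$counts)
  expect_identical(r1$truth, r2$truth)
})
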