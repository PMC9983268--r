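test_that("rank assignment forces the reference ordering and conserves the multiset", {
  expect_equal(rank_assign(c(7, 0, 2), c(5, 1, 3)), c(7, 0, 2))
  expect_equal(rank_assign(1:5, 1:5), 1:5)  # monotone case: unchanged
  expect_error(rank_assign(1:3, 1:4), "length mismatch")

  # all-tied reference: a seeded permutation, multiset preserved
  out <- rank_assign(c(1, 2, 3), c(5, 5, 5), seed = 2)
  expect_setequal(out, c(1, 2, 3))
  expect_identical(rank_assign(c(1, 2, 3), c(5, 5, 5), seed = 2), out)
  perms <- unique(vapply(1:30, function(s) {
    paste(rank_assign(c(1, 2, 3), c(5, 5, 5), seed = s), collapse = "")
  }, character(1)))
  expect_gt(length(perms), 1)  # ties really are randomised across seeds
})

test_that("tissue simulation preserves spatial ranks exactly on tie-free references", {
  ref <- tie_free_reference(n_genes = 8, n_loc = 20)
  sim <- simulate_tissue(ref, seed = 3)
  rho <- vapply(seq_len(nrow(ref$counts)), function(g) {
    suppressWarnings(cor(ref$counts[g, ], sim$data$counts[g, ],
                         method = "spearman"))
  }, numeric(1))
  # synthetic ties cap Spearman below 1; tie-free genes must hit exactly 1
  tie_free <- vapply(seq_len(nrow(sim$data$counts)), function(g) {
    !anyDuplicated(sim$data$counts[g, ])
  }, logical(1))
  expect_true(all(rho[tie_free] == 1))
  # and monotone consistency must hold for every gene: sorting by reference
  # order sorts the synthetic counts
  for (g in seq_len(nrow(ref$counts))) {
    expect_true(!is.unsorted(sim$data$counts[g, order(ref$counts[g, ])]))
  }
})

test_that("simulation is deterministic and conserves sampled totals through assignment", {
  fx <- make_reference_fixture(n_genes = 30, n_locations = 120, seed = 5)
  s1 <- simulate_tissue(fx$data, seed = 11)
  s2 <- simulate_tissue(fx$data, seed = 11)
  expect_identical(s1$data$counts, s2$data$counts)
  expect_identical(s1$data$coords, s2$data$coords)
  s3 <- simulate_tissue(fx$data, seed = 12)
  expect_false(identical(s1$data$counts, s3$data$counts))

  # conservation: re-sampling with the same per-gene substream reproduces the
  # multiset that rank assignment permuted
  fits <- s1$fits
  g <- 4
  redraw <- srtgen:::with_substream(srtgen:::substream_seed(11, 13L, g, 0L), {
    srtgen:::sample_counts_local(as.list(fits[g, ]), ncol(fx$data$counts))
  })
  expect_equal(sort(redraw), sort(unname(s1$data$counts[g, ])))
})

test_that("domain-specific simulation matches each domain's own moments", {
  # one gene with very different NB means in two domains
  withr::with_seed(41, {
    n_per <- 400
    cnt <- rbind(gA = c(rnbinom(n_per, size = 2, mu = 1),
                        rnbinom(n_per, size = 2, mu = 12)),
                 gB = rnbinom(2 * n_per, size = 2, mu = 3))
    ref <- srt_data(cnt, data.frame(x = runif(2 * n_per), y = runif(2 * n_per)),
                    domains = rep(c("d1", "d2"), each = n_per))
  })
  sim <- simulate_domains(ref, seed = 13)
  expect_identical(sim$data$domains, ref$domains)  # labels pass through
  for (d in c("d1", "d2")) {
    cols <- ref$domains == d
    ref_mean <- mean(ref$counts["gA", cols])
    ref_var <- var(ref$counts["gA", cols])
    syn_mean <- mean(sim$data$counts["gA", cols])
    expect_lt(abs(syn_mean - ref_mean), 3 * sqrt(ref_var / sum(cols)))
  }
  # per-domain fits recorded for every gene
  expect_setequal(unique(sim$fits$domain), c("d1", "d2"))
  expect_equal(nrow(sim$fits), 2 * nrow(ref$counts))

  tiny <- srt_data(matrix(1:4, 2, 2), data.frame(x = 1:2, y = 1:2),
                   domains = c("a", "b"))
  expect_error(simulate_domains(tiny, seed = 1), "fewer than 2")
})

test_that("pseudo-reference imputation samples uniformly from the k nearest neighbours", {
  ref <- srt_data(matrix(c(0, 0, 9, 5), 1, 4,
                         dimnames = list("g1", NULL)),
                  data.frame(x = c(0, 1, 2, 50), y = 0))
  # coincident with a reference location, k = 1: that location's count
  imp <- impute_reference_at_new_locations(ref, cbind(2, 0), k = 1, seed = 1)
  expect_equal(as.numeric(imp), 9)

  # k = 3 neighbours {0, 0, 9}: imputed value in {0, 9}, 0 with freq ~ 2/3
  vals <- vapply(1:1000, function(s) {
    as.numeric(impute_reference_at_new_locations(ref, cbind(1, 0), k = 3,
                                                 seed = s))
  }, numeric(1))
  expect_true(all(vals %in% c(0, 9)))
  expect_lt(abs(mean(vals == 0) - 2 / 3), 3 * sqrt(2 / 9 / 1000) + 0.02)

  expect_error(impute_reference_at_new_locations(
    srt_data(matrix(0, 1, 0), data.frame(x = numeric(0), y = numeric(0))),
    cbind(0, 0)), "empty reference")
})

test_that("simulation onto new locations keeps gene-wise distributions and geometry", {
  fx <- make_reference_fixture(n_genes = 40, n_locations = 300,
                               layout = "random", mu_range = c(0.2, 2),
                               seed = 9)
  sim <- simulate_tissue(fx$data, new_locations = list(n = 200, layout = "random"),
                         seed = 21)
  expect_equal(ncol(sim$data$counts), 200)
  hull <- estimate_shape(fx$data$coords[, c("x", "y")], concavity = 2)
  expect_true(all(shape_contains(hull, sim$data$coords[, c("x", "y")])))
  # fitted models come from the original reference, so per-gene means track it
  expect_gt(cor(rowMeans(fx$data$counts), rowMeans(sim$data$counts)), 0.9)

  # domain labels transferred onto the new locations
  simd <- simulate_domains(fx$data, new_locations = list(n = 150, layout = "grid"),
                           seed = 22)
  expect_equal(length(simd$data$domains), ncol(simd$data$counts))
  expect_true(all(simd$data$domains %in% unique(fx$data$domains)))
})

test_that("region redesign transfers the source gradient into the target region", {
  # reference on [0,2]x[0,1]: source = left half with an x-gradient gene,
  # target = right half with flat expression
  withr::with_seed(61, {
    n_half <- 250
    src_xy <- cbind(runif(n_half, 0, 1), runif(n_half))
    tgt_xy <- cbind(runif(n_half, 1.05, 2.05), runif(n_half))
    xy <- rbind(src_xy, tgt_xy)
    grad <- rpois(2 * n_half, lambda = c(exp(3 * src_xy[, 1]), rep(5, n_half)))
    flat <- rpois(2 * n_half, 2)
    ref <- srt_data(rbind(grad = grad, flat = flat),
                    data.frame(x = xy[, 1], y = xy[, 2]))
  })
  ids <- ref$coords$location_id
  res <- redesign_region(ref, source_ids = ids[1:250], target_ids = ids[251:500],
                         seed = 7)
  # locality: counts outside the target are untouched
  expect_identical(res$data$counts[, 1:250], ref$counts[, 1:250])
  # gradient orientation transfers: source rho(x, expr) and target rho share sign
  rho_src <- cor(ref$coords$x[1:250], ref$counts["grad", 1:250],
                 method = "spearman")
  rho_tgt <- cor(res$data$coords$x[251:500], res$data$counts["grad", 251:500],
                 method = "spearman")
  expect_gt(rho_src * rho_tgt, 0)
  expect_gt(abs(rho_tgt), 0.5)

  expect_error(redesign_region(ref, ids[1:2], ids[251:500]), "at least 3")
})

test_that("redesigning a region from itself reduces to neighbour imputation", {
  fx <- make_reference_fixture(n_genes = 5, n_locations = 100,
                               layout = "random", mu_range = c(0.5, 2), seed = 31)
  ids <- fx$data$coords$location_id
  res <- redesign_region(fx$data, source_ids = ids, target_ids = ids, seed = 3)
  # identity affine to numerical tolerance
  expect_equal(res$transform$linear, diag(2), tolerance = 1e-6)
  expect_equal(res$transform$offset, c(0, 0), tolerance = 1e-6)
  # pseudo-reference values are always drawn from the true neighbour counts
  expect_true(all(res$pseudo_reference %in% fx$data$counts))
})

test_that("depth scaling doubles expected library size on a Poisson reference", {
  withr::with_seed(71, {
    cnt <- matrix(rpois(50 * 200, 2), 50, 200)
    ref <- srt_data(cnt, data.frame(x = runif(200), y = runif(200)))
  })
  fits <- fit_genes(ref, "tissue")
  base <- simulate_tissue(ref, seed = 5, fits = fits)
  doubled <- simulate_tissue(ref, depth_factor = 2, seed = 5, fits = fits)
  mu_total <- 2 * sum(fits$mu) * 200
  expect_lt(abs(sum(doubled$data$counts) - mu_total), 3 * sqrt(mu_total))
  expect_gt(sum(doubled$data$counts), sum(base$data$counts))
})

test_that("tidy and glance views of a simulation expose fits and provenance", {
  fx <- make_reference_fixture(n_genes = 6, n_locations = 40, seed = 2)
  sim <- simulate_tissue(fx$data, seed = 4)
  td <- tidy(sim)
  expect_equal(nrow(td), 6)
  expect_true(all(c("gene_id", "family", "mu", "aic") %in% names(td)))
  gl <- glance(sim)
  expect_equal(gl$mode, "tissue")
  expect_equal(gl$seed, 4)
  expect_equal(gl$n_locations, 40)
})
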