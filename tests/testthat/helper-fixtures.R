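# Shared fixture builders; everything generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_srt <- function(n_genes = 3, n_loc = 4, seed = 42) {
  withr::with_seed(seed, {
    cnt <- matrix(rpois(n_genes * n_loc, 2), n_genes, n_loc,
                  dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                  sprintf("s%d", seq_len(n_loc))))
    srt_data(cnt, data.frame(x = seq_len(n_loc), y = rep(0, n_loc)))
  })
}

unit_square <- function() shape_profile(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))

# reference with strictly distinct expression values per gene (no ties),
# so rank assignment is forced and Spearman correlations are exact
tie_free_reference <- function(n_genes = 10, n_loc = 15, seed = 7) {
  withr::with_seed(seed, {
    cnt <- t(vapply(seq_len(n_genes), function(g) sample(seq_len(n_loc) * 3),
                    numeric(n_loc)))
    rownames(cnt) <- sprintf("g%02d", seq_len(n_genes))
    srt_data(cnt, data.frame(x = runif(n_loc), y = runif(n_loc)))
  })
}

# independent Moran's I oracle on small instances: direct double loop
morans_brute <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# independent ML oracle: two-stage grid search over the likelihood surface
grid_mle <- function(counts, family, refine = 2) {
  tab <- table(counts)
  v <- as.numeric(names(tab)); w <- as.numeric(tab)
  n <- length(counts)
  ll <- function(mu, phi = NULL, pi0 = 0) {
    dens <- if (is.null(phi)) dpois(v, mu) else dnbinom(v, size = 1 / phi, mu = mu)
    sum(w * log(pi0 * (v == 0) + (1 - pi0) * dens))
  }
  m <- mean(counts)
  mus <- m * seq(0.5, 3, length.out = 41)
  phis <- exp(seq(log(0.01), log(10), length.out = 41))
  pi0s <- seq(0.005, 0.95, length.out = 40)
  best <- NULL
  eval_grid <- function(mus, phis, pi0s) {
    for (mu in mus) {
      for (phi in (if (family %in% c("nb", "zinb")) phis else NA)) {
        for (pi0 in (if (family %in% c("zip", "zinb")) pi0s else 0)) {
          val <- ll(mu, if (is.na(phi)) NULL else phi, pi0)
          if (is.null(best) || val > best$ll) {
            best <<- list(mu = mu, phi = phi, pi0 = pi0, ll = val)
          }
        }
      }
    }
  }
  eval_grid(mus, phis, pi0s)
  for (r in seq_len(refine)) {
    span <- 0.25^r
    mus <- best$mu * seq(1 - span, 1 + span, length.out = 21)
    phis <- if (is.na(best$phi)) NA else best$phi * seq(1 - span, 1 + span, length.out = 21)
    pi0s <- if (best$pi0 == 0) 0 else {
      pmax(1e-4, pmin(0.99, best$pi0 + best$pi0 * span * seq(-1, 1, length.out = 21)))
    }
    eval_grid(mus, phis, pi0s)
  }
  best
}
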