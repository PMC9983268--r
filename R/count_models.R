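#' Per-gene count models: Poisson, ZIP, NB, ZINB
#'
#' Expression counts of one gene across locations are modelled by one of four
#' families. The negative binomial is parameterised by its mean `mu` and an
#' overdispersion `phi` with variance `mu + phi * mu^2` (`phi = 1/size` of the
#' size-parameterised NB; `phi -> 0` recovers the Poisson). The zero-inflated
#' families mix a point mass of structural zeros with probability `pi0` into
#' the count component, so the marginal mean is `(1 - pi0) * mu`.
#'
#' `fit_count_family()` maximises the observed-data log-likelihood of one
#' family. Poisson and the NB mean have closed forms; the remaining parameters
#' are found by direct numerical maximisation with multiple starting points
#' (a moment-based start plus `pi0` in {0.1, 0.5} for the zero-inflated
#' families). `phi` is bounded below at 1e-8 and `pi0` within [0, 1 - 1e-8]
#' during optimisation; boundary fits are legitimate and reported as-is. When
#' a zero-inflated family sees no zero counts the likelihood is flat in `pi0`
#' and `pi0` is fixed at 0.
#'
#' @param counts Non-negative integer vector of length >= 2.
#' @param family One of `"poisson"`, `"zip"`, `"nb"`, `"zinb"`.
#' @return A `count_fit` object: list with `family`, `mu`, `phi` (NA for
#'   Poisson/ZIP), `pi0` (NA for Poisson/NB), `loglik`, `aic`, `n_params`.
#' @export
#' @examples
#' fit_count_family(c(1, 2, 3), "poisson")$mu  # sample mean, closed form
fit_count_family <- function(counts, family = c("poisson", "zip", "nb", "zinb")) {
  family <- match.arg(family)
  check_counts(counts)
  tab <- count_table(counts)
  n <- length(counts)
  if (all(counts == 0) && family %in% c("zip", "zinb")) {
    abort(sprintf(
      "all-zero vector: the %s likelihood is degenerate (pi0 and mu trade off); see select_count_model()",
      toupper(family)))
  }
  fit <- switch(family,
    poisson = fit_poisson(tab, n),
    nb = fit_nb(tab, n),
    zip = fit_zi(tab, n, dispersed = FALSE),
    zinb = fit_zi(tab, n, dispersed = TRUE)
  )
  k <- c(poisson = 1L, zip = 2L, nb = 2L, zinb = 3L)[[family]]
  structure(
    list(family = family,
         mu = fit$mu,
         phi = if (family %in% c("nb", "zinb")) fit$phi else NA_real_,
         pi0 = if (family %in% c("zip", "zinb")) fit$pi0 else NA_real_,
         loglik = fit$loglik, aic = 2 * k - 2 * fit$loglik, n_params = k,
         n = n),
    class = "count_fit"
  )
}

check_counts <- function(counts) {
  if (length(counts) < 2) abort("need at least 2 observations")
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts)) {
    abort("counts must be non-negative integers")
  }
}

# likelihoods are evaluated on the tabulated unique values with multiplicity
# weights: identical value, O(#unique) instead of O(n) per evaluation
count_table <- function(counts) {
  tab <- table(counts)
  list(v = as.numeric(names(tab)), w = as.numeric(tab))
}

ll_poisson <- function(tab, mu) sum(tab$w * dpois(tab$v, mu, log = TRUE))
ll_nb <- function(tab, mu, phi) {
  sum(tab$w * dnbinom(tab$v, size = 1 / phi, mu = mu, log = TRUE))
}
ll_zi <- function(tab, mu, pi0, phi = NULL) {
  dens <- if (is.null(phi)) dpois(tab$v, mu) else dnbinom(tab$v, size = 1 / phi, mu = mu)
  sum(tab$w * log(pi0 * (tab$v == 0) + (1 - pi0) * dens))
}

PHI_MIN <- 1e-8
PI0_MAX <- 1 - 1e-8

fit_poisson <- function(tab, n) {
  mu <- sum(tab$v * tab$w) / n
  list(mu = mu, loglik = ll_poisson(tab, mu))
}

fit_nb <- function(tab, n) {
  mu <- sum(tab$v * tab$w) / n
  if (mu == 0) return(list(mu = 0, phi = PHI_MIN, loglik = 0))
  opt <- optimize(function(lp) ll_nb(tab, mu, exp(lp)),
                  interval = log(c(PHI_MIN, 1e6)), maximum = TRUE, tol = 1e-10)
  phi <- exp(opt$maximum)
  ll <- opt$objective
  # the Poisson limit can beat any interior phi when the data are underdispersed
  ll0 <- ll_poisson(tab, mu)
  if (ll0 >= ll) { phi <- PHI_MIN; ll <- ll_nb(tab, mu, phi) }
  list(mu = mu, phi = phi, loglik = ll)
}

fit_zi <- function(tab, n, dispersed) {
  mean_obs <- sum(tab$v * tab$w) / n
  p0_obs <- sum(tab$w[tab$v == 0]) / n
  if (p0_obs == 0) {
    # no observed zeros: likelihood flat in pi0, fix pi0 = 0
    base <- if (dispersed) fit_nb(tab, n) else fit_poisson(tab, n)
    return(list(mu = base$mu, phi = base$phi %||% NA_real_, pi0 = 0,
                loglik = base$loglik))
  }
  # moment start: excess zeros over the count component's own zero mass
  pi0_mom <- max(0.01, min(0.9, (p0_obs - exp(-max(mean_obs, 1e-8))) / (1 - exp(-max(mean_obs, 1e-8)))))
  starts <- unique(c(pi0_mom, 0.1, 0.5))
  best <- NULL
  for (pi0_0 in starts) {
    mu0 <- mean_obs / max(1 - pi0_0, 1e-3)
    par0 <- c(log(max(mu0, 1e-6)), stats::qlogis(pi0_0))
    if (dispersed) {
      v_obs <- sum(tab$w * (tab$v - mean_obs)^2) / n
      phi0 <- max((v_obs - mean_obs) / max(mean_obs^2, 1e-12), 0.1)
      par0 <- c(par0, log(phi0))
    }
    negll <- function(par) {
      mu <- exp(par[1])
      pi0 <- min(stats::plogis(par[2]), PI0_MAX)
      phi <- if (dispersed) max(exp(par[3]), PHI_MIN) else NULL
      ll <- ll_zi(tab, mu, pi0, phi)
      if (!is.finite(ll)) 1e12 else -ll
    }
    opt <- tryCatch(
      optim(par0, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    abort(sprintf("optimizer failed to converge for the %s fit",
                  if (dispersed) "ZINB" else "ZIP"))
  }
  mu <- exp(best$par[1])
  pi0 <- min(stats::plogis(best$par[2]), PI0_MAX)
  phi <- if (dispersed) max(exp(best$par[3]), PHI_MIN) else NA_real_
  ll <- ll_zi(tab, mu, pi0, if (dispersed) phi else NULL)
  # the nested fits (pi0 = 0, and for ZINB the phi -> 0 ZIP limit) must never
  # win: adopt them whenever the optimizer's interior solution is worse
  base <- if (dispersed) fit_nb(tab, n) else fit_poisson(tab, n)
  if (base$loglik > ll) {
    mu <- base$mu; pi0 <- 0
    phi <- if (dispersed) base$phi else NA_real_
    ll <- base$loglik
  }
  if (dispersed) {
    zip <- fit_zi(tab, n, dispersed = FALSE)
    ll_zip_limit <- ll_zi(tab, zip$mu, min(zip$pi0, PI0_MAX), PHI_MIN)
    if (ll_zip_limit > ll) {
      mu <- zip$mu; pi0 <- zip$pi0; phi <- PHI_MIN; ll <- ll_zip_limit
    }
  }
  list(mu = mu, phi = phi, pi0 = pi0, loglik = ll)
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("<count_fit> %s: mu=%.4g", x$family, x$mu))
  if (!is.na(x$phi)) cat(sprintf(", phi=%.4g", x$phi))
  if (!is.na(x$pi0)) cat(sprintf(", pi0=%.4g", x$pi0))
  cat(sprintf(", loglik=%.4g, AIC=%.4g\n", x$loglik, x$aic))
  invisible(x)
}

#' @method tidy count_fit
#' @export
tidy.count_fit <- function(x, ...) {
  tibble::tibble(family = x$family, mu = x$mu, phi = x$phi, pi0 = x$pi0,
                 loglik = x$loglik, aic = x$aic, n_params = x$n_params)
}

#' Select the best count model for a gene by AIC
#'
#' Fits all four families and returns the fit with the lowest AIC. Ties
#' (within 1e-9) break toward parsimony in the order Poisson, NB, ZIP, ZINB
#' (NB preferred over ZIP at equal parameter count). An all-zero vector
#' short-circuits to a Poisson with `mu = 0`: with no non-zero observation
#' the families are indistinguishable and the zero-inflated likelihoods are
#' flat along a `mu`-`pi0` ridge.
#'
#' @param counts Non-negative integer vector of length >= 2.
#' @return A `count_fit` object (see [fit_count_family()]).
#' @export
select_count_model <- function(counts) {
  check_counts(counts)
  if (all(counts == 0)) {
    fit <- fit_count_family(c(0, 0), "poisson")
    fit$n <- length(counts)
    fit$loglik <- 0
    fit$aic <- 2
    return(fit)
  }
  fams <- c("poisson", "nb", "zip", "zinb")  # parsimony tie-break order
  fits <- lapply(fams, function(f) fit_count_family(counts, f))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- which(aics <= min(aics) + 1e-9)[1]
  fits[[best]]
}

#' Sample counts from a fitted model
#'
#' Draws i.i.d. counts from the fitted family. Zero-inflated draws replace a
#' `pi0` fraction of count-component draws by structural zeros, so the
#' expected value is `(1 - pi0) * mu`.
#'
#' @param fit A `count_fit` (or any list with `family`, `mu`, `phi`, `pi0`).
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Integer vector of length `n`.
#' @export
sample_counts <- function(fit, n, seed = 1) {
  stopifnot(n >= 1)
  with_substream(substream_seed(seed, 205L), sample_counts_local(fit, n))
}

# draws under the caller's RNG state (used inside seeded pipelines)
sample_counts_local <- function(fit, n) {
  mu <- fit$mu
  x <- switch(fit$family,
    poisson = rpois(n, mu),
    nb = rnbinom(n, size = 1 / fit$phi, mu = mu),
    zip = rpois(n, mu) * (runif(n) >= fit$pi0),
    zinb = rnbinom(n, size = 1 / fit$phi, mu = mu) * (runif(n) >= fit$pi0)
  )
  as.numeric(x)
}

#' Fit count models to every gene of an SRT dataset
#'
#' Runs [select_count_model()] per gene, either on all locations
#' (`mode = "tissue"`) or separately within each spatial domain
#' (`mode = "domain"`), and returns the fits as a tibble - the object the
#' simulation engine samples from.
#'
#' @param data An [srt_data] object.
#' @param mode `"tissue"` or `"domain"` (requires domain labels).
#' @return A tibble with columns `gene_id`, `domain` (`NA` for tissue mode),
#'   `family`, `mu`, `phi`, `pi0`, `loglik`, `aic`, `n_params`.
#' @export
fit_genes <- function(data, mode = c("tissue", "domain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "srt_data"))
  if (mode == "domain" && is.null(data$domains)) {
    abort("domain-specific fitting requires domain labels")
  }
  one_block <- function(m, domain) {
    fits <- lapply(seq_len(nrow(m)), function(i) tidy(select_count_model(m[i, ])))
    dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(m), domain = domain),
      dplyr::bind_rows(fits)
    )
  }
  if (mode == "tissue") {
    one_block(data$counts, NA_character_)
  } else {
    doms <- unique(data$domains)
    dplyr::bind_rows(lapply(doms, function(d) {
      cols <- data$domains == d
      if (sum(cols) < 2) abort(sprintf("domain '%s' has fewer than 2 locations", d))
      one_block(data$counts[, cols, drop = FALSE], d)
    }))
  }
}

#' Proportion of genes preferring each count model
#'
#' Dataset-level profile of which family wins the AIC selection, mirroring
#' platform-level comparisons of count-model preference.
#'
#' @param data An [srt_data] object, or a fit tibble from [fit_genes()].
#' @return A tibble with columns `family`, `n_genes`, `prop` covering all
#'   four families (zero rows included); `prop` sums to 1.
#' @export
model_preference_summary <- function(data) {
  fits <- if (inherits(data, "srt_data")) fit_genes(data, "tissue") else data
  fams <- c("poisson", "zip", "nb", "zinb")
  counts <- table(factor(fits$family, levels = fams))
  tibble::tibble(family = fams,
                 n_genes = as.integer(counts),
                 prop = as.integer(counts) / sum(counts))
}

#' Rescale fitted means for sequencing-depth experiments
#'
#' Multiplies every fitted count-component mean `mu` by `depth_factor`,
#' leaving `phi` and `pi0` untouched, so the expected total count of a
#' simulation scales linearly with the factor.
#'
#' @param fits A fit tibble from [fit_genes()].
#' @param depth_factor Positive scaling factor.
#' @return The rescaled fit tibble.
#' @export
scale_depth <- function(fits, depth_factor) {
  if (!is.numeric(depth_factor) || depth_factor <= 0) {
    abort("`depth_factor` must be positive")
  }
  dplyr::mutate(fits, mu = .data$mu * depth_factor)
}
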