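#' MCMC configuration
#'
#' Defaults follow common practice for conditional GSI mixture models:
#' 20,000 sweeps with the first 1,000 discarded as burn-in, and 100
#' parametric-bootstrap correction iterations.
#'
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded (must be < `n_iter`).
#' @param n_boot parametric bootstrap iterations for bias correction
#'   (0 disables correction).
#' @param seed RNG seed used by [fit_mixture()] / [bootstrap_correct()].
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000, burn_in = 1000, n_boot = 100, seed = NULL) {
  stopifnot(n_iter >= 2, burn_in >= 0, n_boot >= 0)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_boot = as.integer(n_boot), seed = seed),
            class = "mcmc_config")
}

# core fit given a ready log-likelihood matrix; shared by fit_mixture and
# the bootstrap re-fits
#' @keywords internal
fit_from_loglik <- function(ll, counts, cfg, pi_prior) {
  C <- ncol(ll)
  alpha <- switch(pi_prior, flat = rep(1, C), one_over_C = rep(1 / C, C))
  res <- gibbs_mixture_cpp(ll, alpha, cfg$n_iter, cfg$burn_in)
  colnames(res$pi_trace) <- colnames(ll)
  dimnames(res$posterior) <- dimnames(ll)
  res
}

#' Fit the Bayesian mixture model
#'
#' Estimates mixing proportions over baseline collections for an unlabeled
#' mixture sample by Gibbs sampling, holding baseline allele frequencies at
#' their Dirichlet posterior means (the empirical-Bayes "conditional" fit).
#' The sampler alternates the latent origin of each mixture fish and the
#' mixing-proportion vector under a flat Dirichlet prior.
#'
#' @param mixture unlabeled genotype table.
#' @param baseline labeled genotype table (`collection`, optionally `repunit`).
#' @param cfg an [mcmc_config()].
#' @param lambda_policy prior for allele frequencies, see [posterior_freqs()].
#' @param pi_prior `"flat"` (Dirichlet(1) per collection, default) or
#'   `"one_over_C"`.
#' @param holdout optional per-mixture-fish collection names whose counts are
#'   decremented by the fish's own gene copies during likelihood evaluation
#'   (leave-one-out scoring of simulated fish).
#' @return object of class `gsi_result`: per-individual posterior over
#'   collections (`posterior`) and reporting units (`ru_posterior`), retained
#'   mixing-proportion trace (`pi_trace`), posterior means by collection
#'   (`pi_hat`) and reporting unit (`pi_hat_ru`), equal-tailed 95% credible
#'   intervals per unit (`ci_ru`), and `pi_corrected` (NA until
#'   [bootstrap_correct()] is run, or equal to `pi_hat_ru` if
#'   `cfg$n_boot == 0`).
#' @export
fit_mixture <- function(mixture, baseline, cfg = mcmc_config(),
                        lambda_policy = "one_over_A",
                        pi_prior = c("flat", "one_over_C"), holdout = NULL) {
  pi_prior <- match.arg(pi_prior)
  validate_geno(mixture)
  if (nrow(mixture) == 0) stop("mixture is empty", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ru_map <- ru_map_of(baseline)
  index <- build_allele_index(list(baseline, mixture))
  counts <- allele_counts(baseline, index)
  model <- posterior_freqs(counts, lambda_policy)
  ll <- likelihood_matrix(mixture, model, holdout = holdout)
  fit <- fit_from_loglik(ll, counts, cfg, pi_prior)
  finish_gsi_result(fit, mixture$indiv, ru_map, counts, model, cfg,
                    pi_prior, lambda_policy)
}

#' @keywords internal
finish_gsi_result <- function(fit, indiv, ru_map, counts, model, cfg,
                              pi_prior, lambda_policy) {
  post <- fit$posterior
  rownames(post) <- indiv
  ru_post <- to_repunit(post, ru_map)
  pi_hat <- colMeans(fit$pi_trace)
  ru_trace <- to_repunit(fit$pi_trace, ru_map)
  pi_hat_ru <- colMeans(ru_trace)
  ci_ru <- t(apply(ru_trace, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci_ru) <- c("lo", "hi")
  structure(list(posterior = post, ru_posterior = ru_post,
                 pi_trace = fit$pi_trace,
                 pi_hat = pi_hat, pi_hat_ru = pi_hat_ru, ci_ru = ci_ru,
                 pi_corrected = if (cfg$n_boot == 0) pi_hat_ru else
                   stats::setNames(rep(NA_real_, length(pi_hat_ru)), names(pi_hat_ru)),
                 mix_size = length(indiv), ru_map = ru_map,
                 counts = counts, model = model, cfg = cfg,
                 pi_prior = pi_prior, lambda_policy = lambda_policy),
            class = "gsi_result")
}

#' @export
print.gsi_result <- function(x, ...) {
  cat("gsi_result:", x$mix_size, "mixture individuals,",
      length(x$pi_hat), "collections,", length(x$pi_hat_ru), "reporting units\n")
  print(mixing_proportions(x), n = Inf)
  invisible(x)
}

#' Tidy mixing-proportion table
#'
#' @param x a `gsi_result`.
#' @return tibble: repunit, pi_hat, lo, hi (95% credible interval),
#'   pi_corrected (bootstrap bias-corrected; NA before correction).
#' @export
mixing_proportions <- function(x) {
  tibble::tibble(repunit = names(x$pi_hat_ru),
                 pi_hat = unname(x$pi_hat_ru),
                 lo = unname(x$ci_ru[, "lo"]),
                 hi = unname(x$ci_ru[, "hi"]),
                 pi_corrected = unname(x$pi_corrected))
}

#' Parametric-bootstrap bias correction
#'
#' Simulates `cfg$n_boot` mixtures of the observed size from the baseline at
#' the fitted collection proportions (posterior-predictive genotype draws,
#' scored leave-one-out), re-estimates each, and subtracts the mean
#' reporting-unit re-estimation bias from the raw estimate. Corrections that
#' go negative are clamped at 0 and the vector renormalized to sum to 1.
#'
#' @param result a `gsi_result` from [fit_mixture()].
#' @param cfg optional [mcmc_config()] override (defaults to the one used
#'   for the fit; its `n_boot` controls the number of bootstrap mixtures).
#' @return `result` with `pi_corrected` filled in and a `boot_estimates`
#'   matrix (`n_boot` x R) attached.
#' @export
bootstrap_correct <- function(result, cfg = NULL) {
  cfg <- cfg %||% result$cfg
  if (cfg$n_boot == 0) {
    result$pi_corrected <- result$pi_hat_ru
    return(result)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  counts <- result$counts
  collections <- counts$collections
  R <- length(result$pi_hat_ru)
  boot <- matrix(NA_real_, cfg$n_boot, R,
                 dimnames = list(NULL, names(result$pi_hat_ru)))
  for (b in seq_len(cfg$n_boot)) {
    origins <- sample(collections, result$mix_size, replace = TRUE,
                      prob = result$pi_hat)
    sim <- simulate_genotypes(counts, origins, result$model$lambda)
    ll <- loglik_from_enc(sim, result$model, holdout = origins)
    fit <- fit_from_loglik(ll, counts, cfg, result$pi_prior)
    ru_trace <- to_repunit(fit$pi_trace, result$ru_map)
    boot[b, ] <- colMeans(ru_trace)[colnames(boot)]
  }
  bias <- colMeans(boot) - result$pi_hat_ru
  corrected <- pmax(result$pi_hat_ru - bias, 0)
  result$pi_corrected <- corrected / sum(corrected)
  result$boot_estimates <- boot
  result
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
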