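# posterior-predictive genotype simulation: for each fish and locus, two
# gene copies are drawn sequentially from a Polya urn on (x + lambda) for
# the fish's source collection, i.e. from the collection's Dirichlet
# posterior predictive. Returns integer-coded genotypes (sorted pairs).
#' @keywords internal
simulate_genotypes <- function(counts, origins, lambda) {
  N <- length(origins)
  L <- length(counts$loci)
  a1 <- matrix(NA_integer_, N, L, dimnames = list(NULL, counts$loci))
  a2 <- a1
  ci_all <- match(origins, counts$collections)
  if (anyNA(ci_all)) stop("unknown origin collection", call. = FALSE)
  for (cc in unique(ci_all)) {
    mem <- which(ci_all == cc)
    k <- length(mem)
    for (j in seq_len(L)) {
      A <- length(counts$index[[j]])
      if (A == 0L) next
      w <- counts$x[[j]][cc, ] + lambda[j]
      d1 <- sample.int(A, k, replace = TRUE, prob = w)
      w2 <- matrix(w, k, A, byrow = TRUE)
      w2[cbind(seq_len(k), d1)] <- w2[cbind(seq_len(k), d1)] + 1
      u <- stats::runif(k) * rowSums(w2)
      cum <- w2
      if (A > 1) for (aa in 2:A) cum[, aa] <- cum[, aa] + cum[, aa - 1L]
      d2 <- A + 1L - as.integer(rowSums(cum >= u))
      a1[mem, j] <- pmin(d1, d2)
      a2[mem, j] <- pmax(d1, d2)
    }
  }
  list(a1 = a1, a2 = a2, indiv = paste0("sim_", seq_len(N)), loci = counts$loci)
}

#' Simulate individuals from a baseline collection
#'
#' Draws multilocus diploid genotypes from a collection's Dirichlet
#' posterior predictive (sequential Polya-urn draws on observed allele
#' counts plus prior mass), the same generative process used by the
#' simulation designs and the parametric bootstrap. Because the drawn gene
#' copies equal the fish's own genotype, leave-one-out evaluation of a
#' simulated fish decrements exactly these copies from the source
#' collection.
#'
#' @param counts an `allele_counts` object.
#' @param collection source collection name (or a vector of origins, one per
#'   simulated fish, in which case `n` is ignored).
#' @param n number of fish to simulate.
#' @param lambda_policy see [posterior_freqs()].
#' @param seed optional RNG seed.
#' @return genotype table of simulated fish with a `collection` column
#'   giving the (true) origin.
#' @export
simulate_individual <- function(counts, collection, n = 1,
                                lambda_policy = "one_over_A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  origins <- if (length(collection) > 1) collection else rep(collection, n)
  nA <- vapply(counts$index, length, integer(1))
  lambda <- if (lambda_policy == "one_over_A") 1 / pmax(nA, 1L) else rep(1, length(nA))
  enc <- simulate_genotypes(counts, origins, lambda)
  decode_enc(enc, counts$index, collection = origins)
}

#' @keywords internal
decode_enc <- function(enc, index, collection = NULL, repunit = NULL) {
  a1 <- enc$a1; a2 <- enc$a2
  c1 <- matrix(NA_character_, nrow(a1), ncol(a1), dimnames = dimnames(a1))
  c2 <- c1
  for (j in seq_along(index)) {
    c1[, j] <- index[[j]][a1[, j]]
    c2[, j] <- index[[j]][a2[, j]]
  }
  mats_to_geno(c1, c2, enc$indiv, collection = collection, repunit = repunit)
}

#' Simulation design
#'
#' The three mixture-evaluation regimes. Unstated sizes default to the
#' standard study design: 100% simulations use 50 mixtures of 100 fish per
#' reporting unit; equal-proportion mixtures use 20 replicates with 500 fish
#' per unit; Dirichlet ("realistic") mixtures use 100 replicates of 500 fish
#' with truth drawn from a symmetric Dirichlet(1.5).
#'
#' @param kind `"pct100"`, `"equal"` or `"dirichlet"`.
#' @param n_sims replicate mixtures (per unit for `"pct100"`).
#' @param mixture_size fish per mixture (per unit for `"equal"`).
#' @param alpha Dirichlet concentration (`"dirichlet"` only).
#' @param seed RNG seed for the design run.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(kind = c("pct100", "equal", "dirichlet"),
                       n_sims = NULL, mixture_size = NULL, alpha = NULL,
                       seed = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
                     pct100 = list(n_sims = 50, mixture_size = 100, alpha = NULL),
                     equal = list(n_sims = 20, mixture_size = 500, alpha = NULL),
                     dirichlet = list(n_sims = 100, mixture_size = 500, alpha = 1.5))
  n_sims <- n_sims %||% defaults$n_sims
  mixture_size <- mixture_size %||% defaults$mixture_size
  alpha <- alpha %||% defaults$alpha
  stopifnot(n_sims >= 1, mixture_size >= 0)
  if (kind == "dirichlet" && (is.null(alpha) || alpha <= 0)) {
    stop("dirichlet design needs alpha > 0", call. = FALSE)
  }
  structure(list(kind = kind, n_sims = as.integer(n_sims),
                 mixture_size = as.integer(mixture_size), alpha = alpha,
                 seed = seed),
            class = "sim_design")
}

# shared plumbing: fit one simulated mixture (origins known) against a
# prepared baseline model, leave-one-out, returning a gsi_result
#' @keywords internal
fit_sim_mixture <- function(counts, model, ru_map, origins, cfg,
                            pi_prior = "flat") {
  enc <- simulate_genotypes(counts, origins, model$lambda)
  ll <- loglik_from_enc(enc, model, holdout = origins)
  fit <- fit_from_loglik(ll, counts, cfg, pi_prior)
  finish_gsi_result(fit, enc$indiv, ru_map, counts, model, cfg,
                    pi_prior, "one_over_A")
}

#' @keywords internal
prep_baseline <- function(baseline, lambda_policy = "one_over_A") {
  ru_map <- ru_map_of(baseline)
  counts <- allele_counts(baseline)
  model <- posterior_freqs(counts, lambda_policy)
  units <- unique(unname(ru_map))
  list(counts = counts, model = model, ru_map = ru_map, units = units,
       unit_collections = split(names(ru_map), unname(ru_map))[units])
}

#' 100% simulations
#'
#' For each reporting unit, simulates `design$n_sims` mixtures composed
#' entirely of that unit (fish drawn from the unit's collections with equal
#' weight), analyzes each with the mixture model (leave-one-out), and
#' reports (a) the estimated mixture proportion credited back to the true
#' unit per simulation and (b) individual-level assignment accuracy and
#' efficiency at the posterior threshold, pooled over simulations.
#'
#' @param baseline labeled genotype table.
#' @param design a [sim_design()] of kind `"pct100"`.
#' @param cfg an [mcmc_config()].
#' @param threshold posterior probability threshold for individual
#'   assignment (default 0.70).
#' @return list with `mixture_props` (tibble: repunit, sim, est_prop),
#'   `individual_report` (an accuracy report, see [score_assignments()]),
#'   and `design`.
#' @export
run_100pct <- function(baseline, design, cfg = mcmc_config(), threshold = 0.70) {
  stopifnot(design$kind == "pct100")
  if (!is.null(design$seed)) set.seed(design$seed)
  bp <- prep_baseline(baseline)
  rows <- list()
  post_all <- list(); truth_all <- list()
  for (u in bp$units) {
    colls <- bp$unit_collections[[u]]
    if (length(colls) == 0) stop("reporting unit '", u, "' has no collections", call. = FALSE)
    for (s in seq_len(design$n_sims)) {
      origins <- sample(colls, design$mixture_size, replace = TRUE)
      res <- fit_sim_mixture(bp$counts, bp$model, bp$ru_map, origins, cfg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repunit = u, sim = s, est_prop = unname(res$pi_hat_ru[u]))
      post_all[[length(post_all) + 1L]] <- res$ru_posterior
      truth_all[[length(truth_all) + 1L]] <- rep(u, design$mixture_size)
    }
  }
  report <- score_assignments(do.call(rbind, post_all), unlist(truth_all), threshold)
  list(mixture_props = dplyr::bind_rows(rows), individual_report = report,
       design = design)
}

#' Equal-proportion mixture simulations
#'
#' Each replicate mixture holds `design$mixture_size` fish from every
#' reporting unit (truth `1/R` each); returns raw estimated proportions per
#' replicate against that truth.
#'
#' @inheritParams run_100pct
#' @param design a [sim_design()] of kind `"equal"`.
#' @return tibble: sim, repunit, truth, estimate.
#' @export
run_equal <- function(baseline, design, cfg = mcmc_config()) {
  stopifnot(design$kind == "equal")
  if (!is.null(design$seed)) set.seed(design$seed)
  bp <- prep_baseline(baseline)
  R <- length(bp$units)
  rows <- list()
  for (s in seq_len(design$n_sims)) {
    origins <- unlist(lapply(bp$units, function(u)
      sample(bp$unit_collections[[u]], design$mixture_size, replace = TRUE)))
    res <- fit_sim_mixture(bp$counts, bp$model, bp$ru_map, origins, cfg)
    rows[[s]] <- tibble::tibble(sim = s, repunit = bp$units,
                                truth = 1 / R,
                                estimate = unname(res$pi_hat_ru[bp$units]))
  }
  dplyr::bind_rows(rows)
}

#' Dirichlet ("realistic") mixture simulations
#'
#' Per replicate, true reporting-unit proportions are drawn from a symmetric
#' Dirichlet(`design$alpha`), fish origins are multinomial at those
#' proportions (collections within a unit equally weighted), and the mixture
#' is estimated with parametric-bootstrap bias correction. The returned
#' truth-versus-estimate table supports bias/precision assessment over a
#' realistic range of stock proportions.
#'
#' @inheritParams run_100pct
#' @param design a [sim_design()] of kind `"dirichlet"`.
#' @return tibble: sim, repunit, truth, estimate (raw posterior mean),
#'   estimate_corrected (bootstrap-corrected).
#' @export
run_dirichlet <- function(baseline, design, cfg = mcmc_config()) {
  stopifnot(design$kind == "dirichlet")
  if (!is.null(design$seed)) set.seed(design$seed)
  bp <- prep_baseline(baseline)
  R <- length(bp$units)
  rows <- list()
  for (s in seq_len(design$n_sims)) {
    truth <- rdirichlet(1, rep(design$alpha, R))[1, ]
    unit_of <- sample(bp$units, design$mixture_size, replace = TRUE, prob = truth)
    origins <- vapply(unit_of, function(u) {
      colls <- bp$unit_collections[[u]]
      if (length(colls) == 1) colls else sample(colls, 1)
    }, character(1))
    res <- fit_sim_mixture(bp$counts, bp$model, bp$ru_map, origins, cfg)
    if (cfg$n_boot > 0) res <- bootstrap_correct(res)
    rows[[s]] <- tibble::tibble(sim = s, repunit = bp$units,
                                truth = unname(truth),
                                estimate = unname(res$pi_hat_ru[bp$units]),
                                estimate_corrected = unname(res$pi_corrected[bp$units]))
  }
  dplyr::bind_rows(rows)
}

#' @keywords internal
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, byrow = TRUE)
  g / rowSums(g)
}

#' Score individual assignments at a posterior threshold
#'
#' An individual is assigned to its highest-posterior reporting unit iff
#' that posterior is at least `threshold`, else it is unassigned. Per unit:
#' accuracy = correctly assigned / total assigned to the unit (NA when
#' nothing is assigned there); efficiency = correctly assigned / truly
#' belonging.
#'
#' @param ru_posterior N x R matrix of reporting-unit posteriors (rows sum
#'   to 1), column names = unit names.
#' @param truth character vector (length N) of true reporting units.
#' @param threshold assignment threshold in (0, 1].
#' @return object of class `accuracy_report`: list with `per_unit` (tibble:
#'   repunit, n_true, n_assigned, n_correct, accuracy, efficiency),
#'   `overall` (mean accuracy/efficiency over defined units, retained
#'   fraction) and `threshold`.
#' @export
score_assignments <- function(ru_posterior, truth, threshold = 0.70) {
  stopifnot(threshold > 0, threshold <= 1, nrow(ru_posterior) == length(truth))
  units <- union(colnames(ru_posterior), unique(truth))
  top_j <- max.col(ru_posterior, ties.method = "first")
  top_p <- ru_posterior[cbind(seq_len(nrow(ru_posterior)), top_j)]
  assigned <- top_p >= threshold
  call <- ifelse(assigned, colnames(ru_posterior)[top_j], NA_character_)
  per_unit <- dplyr::bind_rows(lapply(units, function(u) {
    n_true <- sum(truth == u)
    n_assigned <- sum(!is.na(call) & call == u)
    n_correct <- sum(!is.na(call) & call == u & truth == u)
    tibble::tibble(repunit = u, n_true = n_true, n_assigned = n_assigned,
                   n_correct = n_correct,
                   accuracy = if (n_assigned > 0) n_correct / n_assigned else NA_real_,
                   efficiency = if (n_true > 0) n_correct / n_true else NA_real_)
  }))
  structure(list(per_unit = per_unit,
                 overall = list(accuracy = mean(per_unit$accuracy, na.rm = TRUE),
                                efficiency = mean(per_unit$efficiency, na.rm = TRUE),
                                retained = mean(assigned)),
                 threshold = threshold),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report (threshold ", x$threshold, "): mean accuracy ",
      format(x$overall$accuracy, digits = 3), ", mean efficiency ",
      format(x$overall$efficiency, digits = 3), ", retained ",
      format(x$overall$retained, digits = 3), "\n", sep = "")
  invisible(x)
}
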