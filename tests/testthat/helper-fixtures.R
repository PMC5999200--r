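# Compact genotype-table builders used across the suite.

# calls: named list locus -> character vector of "a/b" strings (NA = missing),
# one entry per individual.
toy_geno <- function(calls, collection = NULL, repunit = NULL,
                     indiv = NULL) {
  n <- length(calls[[1]])
  indiv <- indiv %||% sprintf("ind_%02d", seq_len(n))
  out <- tibble::tibble(indiv = indiv)
  if (!is.null(collection)) out$collection <- collection
  if (!is.null(repunit)) out$repunit <- repunit
  for (loc in names(calls)) {
    parts <- strsplit(as.character(calls[[loc]]), "/", fixed = TRUE)
    out[[loc]] <- vapply(parts, function(p) if (length(p)) p[1] else NA_character_,
                         character(1))
    out[[paste0(loc, ".1")]] <- vapply(parts, function(p)
      if (length(p) == 2) p[2] else if (length(p)) p[1] else NA_character_,
      character(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Baseline where every collection is fixed for its own private allele at
# every locus: assignment and mixture recovery are exact.
disjoint_baseline <- function(n_coll = 2, n_loci = 4, n_per = 10,
                              repunit = NULL) {
  colls <- sprintf("C%d", seq_len(n_coll))
  collection <- rep(colls, each = n_per)
  calls <- list()
  for (j in seq_len(n_loci)) {
    al <- as.character(100 + match(collection, colls))
    calls[[sprintf("L%02d", j)]] <- paste0(al, "/", al)
  }
  toy_geno(calls, collection = collection,
           repunit = repunit %||% collection)
}

# Two collections with identical genotype composition (fully confusable).
identical_pair_baseline <- function(n_per = 12, n_loci = 3) {
  calls <- list()
  pat <- c("100/101", "100/100", "101/101", "100/101")
  for (j in seq_len(n_loci)) {
    calls[[sprintf("L%02d", j)]] <- rep(rep(pat, length.out = n_per), 2)
  }
  toy_geno(calls, collection = rep(c("A", "B"), each = n_per))
}

# Numerical posterior mean of pi_1 for a C = 2 mixture via grid integration
# of prod_i (pi * L_i1 + (1 - pi) * L_i2) under a flat prior. Independent of
# the Gibbs sampler; shares only the likelihood matrix.
grid_pi_posterior_mean <- function(logL, n_grid = 2001) {
  stopifnot(ncol(logL) == 2)
  pi_grid <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  logw <- vapply(pi_grid, function(p) {
    sum(apply(logL, 1, function(r) {
      m <- max(r)
      m + log(p * exp(r[1] - m) + (1 - p) * exp(r[2] - m))
    }))
  }, numeric(1))
  w <- exp(logw - max(logw))
  sum(pi_grid * w) / sum(w)
}

# Batch-means Monte Carlo standard error of a trace mean (accounts for
# autocorrelation of the Gibbs chain).
batch_se <- function(trace, n_batch = 50) {
  m <- length(trace) %/% n_batch
  bm <- vapply(seq_len(n_batch), function(b) mean(trace[((b - 1) * m + 1):(b * m)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}
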