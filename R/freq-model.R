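#' Dirichlet-posterior allele frequencies
#'
#' Posterior-mean allele frequencies per collection:
#' `theta[c,l,a] = (x[c,l,a] + lambda_l) / (n[c,l] + A_l * lambda_l)`.
#' The default prior mass is `lambda_l = 1/A_l` per allele (unit total mass
#' per locus, the conditional-GSI convention), which guarantees every allele
#' in the index — including mixture alleles unseen in a baseline collection —
#' strictly positive frequency.
#'
#' @param counts an `allele_counts` object (built on the union allele index
#'   of baseline and any mixture to be scored).
#' @param lambda_policy `"one_over_A"` (default) or `"constant"`.
#' @param lambda_const per-allele prior mass when `lambda_policy = "constant"`.
#' @return object of class `freq_model`: list with `theta` (per locus, a
#'   C x A_l matrix of posterior-mean frequencies), `lambda` (per-locus
#'   per-allele prior mass), `counts`, `collections`, `loci`, `index`.
#'   Loci with no alleles anywhere are dropped with a warning.
#' @export
posterior_freqs <- function(counts, lambda_policy = c("one_over_A", "constant"),
                            lambda_const = 1) {
  lambda_policy <- match.arg(lambda_policy)
  nA <- vapply(counts$index, length, integer(1))
  if (any(nA == 0L)) {
    warning("dropping loci with no observed alleles: ",
            paste(counts$loci[nA == 0L], collapse = ", "))
    keep <- which(nA > 0L)
    counts$x <- counts$x[keep]
    counts$n <- counts$n[, keep, drop = FALSE]
    counts$loci <- counts$loci[keep]
    idx <- unclass(counts$index)[keep]
    nA2 <- vapply(idx, length, integer(1))
    counts$index <- structure(idx, class = "allele_index", n_alleles = nA2,
                              total_alleles = sum(nA2),
                              mean_alleles = round(mean(nA2), 1),
                              empty_loci = character(0))
    nA <- nA[keep]
  }
  lambda <- switch(lambda_policy,
                   one_over_A = 1 / nA,
                   constant = rep(lambda_const, length(nA)))
  theta <- lapply(seq_along(counts$loci), function(j) {
    A <- nA[j]
    sweep(counts$x[[j]] + lambda[j], 1, counts$n[, j] + A * lambda[j], "/")
  })
  names(theta) <- counts$loci
  structure(list(theta = theta, lambda = lambda, counts = counts,
                 collections = counts$collections, loci = counts$loci,
                 index = counts$index, ru_map = counts$ru_map),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat("freq_model:", length(x$collections), "collections x", length(x$loci),
      "loci (lambda per allele:", format(mean(x$lambda), digits = 3), "avg)\n")
  invisible(x)
}

# log-likelihood matrix from integer-coded genotypes.
#
# enc: list(a1, a2) N x L integer matrices (indices into model$index), NA
# missing. holdout: optional length-N character vector; when holdout[i] is a
# collection name, individual i's own two gene copies per non-missing locus
# are decremented from that collection's counts before computing its
# likelihood there (leave-one-out). Counts floor at 0 so that copies never
# actually present (posterior-predictive simulated fish) cannot drive
# frequencies negative; the Dirichlet prior keeps support everywhere.
#' @keywords internal
loglik_from_enc <- function(enc, model, holdout = NULL) {
  N <- nrow(enc$a1)
  collections <- model$collections
  C <- length(collections)
  L <- length(model$loci)
  jmap <- match(model$loci, enc$loci)
  if (anyNA(jmap)) stop("genotypes lack loci present in the model", call. = FALSE)
  ll <- matrix(0, N, C, dimnames = list(rownames(enc$a1), collections))
  log2c <- log(2)
  for (cc in seq_len(C)) {
    acc <- numeric(N)
    for (j in seq_len(L)) {
      a1 <- enc$a1[, jmap[j]]; a2 <- enc$a2[, jmap[j]]
      ok <- !is.na(a1)
      if (!any(ok)) next
      lth <- log(model$theta[[j]][cc, ])
      contrib <- numeric(N)
      contrib[ok] <- lth[a1[ok]] + lth[a2[ok]] + log2c * (a1[ok] != a2[ok])
      acc <- acc + contrib
    }
    ll[, cc] <- acc
  }
  if (!is.null(holdout)) {
    cnts <- model$counts
    for (cc in intersect(unique(holdout[!is.na(holdout)]), collections)) {
      ci <- match(cc, collections)
      mem <- which(!is.na(holdout) & holdout == cc)
      acc <- numeric(length(mem))
      for (j in seq_len(L)) {
        a1 <- enc$a1[mem, jmap[j]]; a2 <- enc$a2[mem, jmap[j]]
        ok <- !is.na(a1)
        if (!any(ok)) next
        xv <- cnts$x[[j]][ci, ]
        n <- cnts$n[ci, j]
        A <- length(xv)
        lam <- model$lambda[j]
        het <- ok & (a1 != a2)
        hom <- ok & !het
        contrib <- numeric(length(mem))
        if (any(hom)) {
          x1 <- pmax(xv[a1[hom]] - 2L, 0L)
          S <- n - pmin(xv[a1[hom]], 2L)
          contrib[hom] <- 2 * log((x1 + lam) / (S + A * lam))
        }
        if (any(het)) {
          x1 <- pmax(xv[a1[het]] - 1L, 0L)
          x2 <- pmax(xv[a2[het]] - 1L, 0L)
          S <- n - pmin(xv[a1[het]], 1L) - pmin(xv[a2[het]], 1L)
          contrib[het] <- log2c + log((x1 + lam) / (S + A * lam)) +
            log((x2 + lam) / (S + A * lam))
        }
        acc <- acc + contrib
      }
      ll[mem, ci] <- acc
    }
  }
  ll
}

#' Genotype log-likelihood matrix
#'
#' Diploid HWE log-likelihood of each individual's multilocus genotype given
#' each baseline collection's posterior-mean allele frequencies:
#' homozygote `a/a` contributes `log(theta_a^2)`, heterozygote `a/b`
#' `log(2 theta_a theta_b)`, missing loci contribute 0 (so an individual
#' with no data is equally likely under every collection).
#'
#' @param x genotype table (alleles must be covered by the model's index —
#'   build the index on the union of baseline and mixture).
#' @param model a `freq_model`.
#' @param holdout optional character vector (length `nrow(x)`); where it
#'   names a collection, that individual's own gene copies are removed from
#'   the collection's counts before evaluating it there (leave-one-out).
#' @return N x C matrix of log-likelihoods.
#' @export
likelihood_matrix <- function(x, model, holdout = NULL) {
  enc <- encode_genotypes(x, model$index)
  loglik_from_enc(enc, model, holdout)
}

#' @rdname likelihood_matrix
#' @param collection collection name (for the single-collection convenience
#'   form, returning one log-likelihood per individual).
#' @export
genotype_loglik <- function(x, model, collection) {
  likelihood_matrix(x, model)[, collection]
}

# rows -> posterior over collections under weights prior_w (recycled)
#' @keywords internal
softmax_rows <- function(ll, prior_w = 1) {
  w <- exp(ll - apply(ll, 1, max)) * rep(prior_w, each = nrow(ll))
  sweep(w, 1, rowSums(w), "/")
}

# collection-level matrix -> reporting-unit level (column sums by unit)
#' @keywords internal
to_repunit <- function(mat, ru_map) {
  ru <- ru_map[colnames(mat)]
  units <- unique(unname(ru))
  out <- matrix(0, nrow(mat), length(units), dimnames = list(rownames(mat), units))
  for (u in units) {
    out[, u] <- rowSums(mat[, ru == u, drop = FALSE])
  }
  out
}
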