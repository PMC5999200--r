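#' Leave-one-out self-assignment of baseline individuals
#'
#' Each labeled baseline individual is scored against every collection with
#' its own two gene copies per non-missing locus removed from its home
#' collection's allele counts before that collection's frequencies are
#' formed — the leave-one-out procedure that removes the optimistic bias of
#' scoring a fish against a baseline that contains it. The posterior uses an
#' equal prior across collections; reporting-unit posteriors are sums over
#' member collections.
#'
#' @param x labeled baseline genotype table (`collection`, optionally
#'   `repunit`).
#' @param lambda_policy passed to [posterior_freqs()].
#' @return object of class `self_assign`: list with `posterior` (N x C),
#'   `ru_posterior` (N x R), `assignments` (tibble: indiv, collection,
#'   repunit, top inferred collection and unit with posteriors), and the
#'   `ru_map`.
#' @export
self_assign_loo <- function(x, lambda_policy = "one_over_A") {
  validate_geno(x)
  if (is.null(x[["collection"]]) || anyNA(x[["collection"]])) {
    stop("self-assignment needs every individual labeled with a collection",
         call. = FALSE)
  }
  ru_map <- ru_map_of(x)
  counts <- allele_counts(x)
  model <- posterior_freqs(counts, lambda_policy)
  ll <- likelihood_matrix(x, model, holdout = x[["collection"]])
  post <- softmax_rows(ll)
  ru_post <- to_repunit(post, ru_map)
  top_c <- colnames(post)[max.col(post, ties.method = "first")]
  top_u <- colnames(ru_post)[max.col(ru_post, ties.method = "first")]
  assignments <- tibble::tibble(
    indiv = x$indiv,
    collection = x[["collection"]],
    repunit = unname(ru_map[x[["collection"]]]),
    inferred_collection = top_c,
    collection_posterior = post[cbind(seq_len(nrow(post)), match(top_c, colnames(post)))],
    inferred_repunit = top_u,
    repunit_posterior = ru_post[cbind(seq_len(nrow(ru_post)), match(top_u, colnames(ru_post)))]
  )
  structure(list(posterior = post, ru_posterior = ru_post,
                 assignments = assignments, ru_map = ru_map),
            class = "self_assign")
}

#' @export
print.self_assign <- function(x, ...) {
  cat("self_assign:", nrow(x$posterior), "individuals,",
      ncol(x$posterior), "collections,", ncol(x$ru_posterior), "reporting units\n")
  cat("top-1 collection self-assignment rate:",
      format(mean(x$assignments$collection == x$assignments$inferred_collection),
             digits = 3), "\n")
  invisible(x)
}
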