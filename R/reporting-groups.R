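#' Mis-assignment matrix from leave-one-out self-assignment
#'
#' `m[c1, c2]` is the fraction of collection `c1`'s individuals whose top
#' LOO assignment (collection level, no threshold) is `c2`; the diagonal is
#' the per-collection self-assignment rate and rows sum to 1.
#'
#' @param sa a `self_assign` object (see [self_assign_loo()]).
#' @return square matrix over collections.
#' @export
misassignment_matrix <- function(sa) {
  a <- sa$assignments
  collections <- colnames(sa$posterior)
  m <- table(factor(a$collection, levels = collections),
             factor(a$inferred_collection, levels = collections))
  m <- sweep(unclass(m), 1, pmax(rowSums(m), 1L), "/")
  dimnames(m) <- list(collections, collections)
  m
}

#' Propose reporting-unit merges
#'
#' Encodes the evidence sources used when lumping collections into
#' reporting units as an explicit, deterministic rule set (decision support
#' for a human-reviewed grouping, not automation of judgment):
#' \enumerate{
#'   \item any collection with fewer than `min_n` individuals is unioned
#'     with its nearest neighbor on the tree (smallest cophenetic distance);
#'   \item collection pairs with mutual mis-assignment at or above
#'     `mutual_cutoff` in both directions are unioned;
#'   \item unions are closed transitively.
#' }
#'
#' @param tree an `ape::phylo` over the collections (e.g. from [nj_tree()]).
#' @param mis mis-assignment matrix over the same labels.
#' @param n_by_collection named integer vector of sample sizes.
#' @param min_n small-sample threshold (default 30).
#' @param mutual_cutoff mutual mis-assignment threshold between 0 and 1.
#' @return object of class `merge_proposal`: list with `unions` (list of
#'   disjoint character vectors, each a proposed reporting unit of >= 2
#'   collections) and `evidence` (tibble: collection_a, collection_b, rule).
#' @export
propose_merges <- function(tree, mis, n_by_collection, min_n = 30,
                           mutual_cutoff = 0.20) {
  if (mutual_cutoff < 0 || mutual_cutoff > 1) {
    stop("mutual_cutoff must be in [0, 1]", call. = FALSE)
  }
  labs <- tree$tip.label
  if (!setequal(labs, rownames(mis))) {
    stop("tree tips and mis-assignment labels differ", call. = FALSE)
  }
  mis <- mis[labs, labs]
  coph <- ape::cophenetic.phylo(tree)[labs, labs]
  ev <- list()
  small <- labs[n_by_collection[labs] < min_n]
  for (s in small) {
    d <- coph[s, ]
    d[s] <- Inf
    nb <- names(which.min(d))
    ev[[length(ev) + 1L]] <- tibble::tibble(collection_a = s, collection_b = nb,
                                            rule = "small_n_tree_neighbor")
  }
  for (i in seq_along(labs)) {
    for (k in seq_along(labs)) {
      if (k <= i) next
      if (mis[i, k] >= mutual_cutoff && mis[k, i] >= mutual_cutoff) {
        ev[[length(ev) + 1L]] <- tibble::tibble(collection_a = labs[i],
                                                collection_b = labs[k],
                                                rule = "mutual_misassignment")
      }
    }
  }
  evidence <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(collection_a = character(), collection_b = character(),
                   rule = character())
  # transitive closure by union-find
  parent <- stats::setNames(seq_along(labs), labs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(evidence))) {
    a <- find(match(evidence$collection_a[r], labs))
    b <- find(match(evidence$collection_b[r], labs))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(labs), find, numeric(1))
  unions <- split(labs, roots)
  unions <- unname(unions[lengths(unions) > 1])
  structure(list(unions = unions, evidence = evidence,
                 min_n = min_n, mutual_cutoff = mutual_cutoff),
            class = "merge_proposal")
}

#' @export
print.merge_proposal <- function(x, ...) {
  cat("merge_proposal:", length(x$unions), "proposed union(s)\n")
  for (u in x$unions) cat("  -", paste(u, collapse = " + "), "\n")
  invisible(x)
}

#' Apply reporting-unit unions to a baseline
#'
#' Rewrites the `repunit` column: collections inside a union share a unit
#' named by joining the member codes; all other collections map to
#' themselves. Genotype data are untouched.
#'
#' @param x labeled genotype table.
#' @param unions list of disjoint character vectors of collection names (a
#'   `merge_proposal$unions` works directly).
#' @param sep separator for joined unit names.
#' @return the table with an updated `repunit` column.
#' @export
apply_ru_map <- function(x, unions, sep = "") {
  if (inherits(unions, "merge_proposal")) unions <- unions$unions
  members <- unlist(unions)
  if (anyDuplicated(members)) {
    stop("collection(s) in more than one union: ",
         paste(unique(members[duplicated(members)]), collapse = ", "), call. = FALSE)
  }
  collections <- unique(x[["collection"]])
  map <- stats::setNames(collections, collections)
  for (u in unions) {
    unknown <- setdiff(u, collections)
    if (length(unknown)) stop("unknown collection(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    map[u] <- paste(u, collapse = sep)
  }
  x[["repunit"]] <- unname(map[x[["collection"]]])
  x
}
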