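#' Observed and expected heterozygosity
#'
#' H_O is the fraction of heterozygous calls; H_E is Nei's unbiased
#' estimator `(2n/(2n-1)) * (1 - sum(p^2))` with `n` the number of
#' non-missing diploid individuals in the collection-locus cell.
#'
#' @param x labeled genotype table (a table without `collection` is treated
#'   as a single collection).
#' @return list with `per_cell` (tibble: collection, locus, n, H_O, H_E),
#'   `per_locus` (means over collections with n > 0), and `overall`
#'   (means over loci). Cells with no calls are excluded and flagged by
#'   `n = 0`.
#' @export
heterozygosity <- function(x) {
  if (is.null(x[["collection"]])) x[["collection"]] <- "all"
  idx <- build_allele_index(x)
  enc <- encode_genotypes(x, idx)
  collections <- unique(x[["collection"]])
  ci <- match(x[["collection"]], collections)
  rows <- list()
  for (j in seq_along(enc$loci)) {
    for (k in seq_along(collections)) {
      sel <- ci == k & !is.na(enc$a1[, j])
      n <- sum(sel)
      if (n == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          collection = collections[k], locus = enc$loci[j], n = 0L,
          H_O = NA_real_, H_E = NA_real_)
        next
      }
      ho <- mean(enc$a1[sel, j] != enc$a2[sel, j])
      p <- tabulate(c(enc$a1[sel, j], enc$a2[sel, j]), length(idx[[j]])) / (2 * n)
      he <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else 1 - sum(p^2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        collection = collections[k], locus = enc$loci[j], n = n, H_O = ho, H_E = he)
    }
  }
  per_cell <- dplyr::bind_rows(rows)
  per_locus <- per_cell %>%
    dplyr::filter(.data$n > 0) %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(H_O = mean(.data$H_O), H_E = mean(.data$H_E), .groups = "drop")
  list(per_cell = per_cell,
       per_locus = per_locus,
       overall = list(H_O = mean(per_locus$H_O), H_E = mean(per_locus$H_E)))
}

# Per-locus sufficient statistics for Weir-Cockerham theta:
# allele counts, diploid sample sizes, and per-allele heterozygote-carrier
# counts for each collection.
#' @keywords internal
wc_stats <- function(x) {
  idx <- build_allele_index(x)
  enc <- encode_genotypes(x, idx)
  collections <- unique(x[["collection"]])
  ci <- match(x[["collection"]], collections)
  C <- length(collections); L <- length(enc$loci)
  ndip <- matrix(0L, C, L, dimnames = list(collections, enc$loci))
  cnt <- het <- vector("list", L)
  for (j in seq_len(L)) {
    A <- length(idx[[j]])
    ok <- !is.na(enc$a1[, j])
    ndip[, j] <- as.integer(table(factor(ci[ok], levels = seq_len(C))))
    cnt[[j]] <- matrix(as.integer(table(
      factor(rep(ci[ok], 2), levels = seq_len(C)),
      factor(c(enc$a1[ok, j], enc$a2[ok, j]), levels = seq_len(A)))), C, A,
      dimnames = list(collections, idx[[j]]))
    ish <- ok & enc$a1[, j] != enc$a2[, j]
    het[[j]] <- matrix(as.integer(table(
      factor(rep(ci[ish], 2), levels = seq_len(C)),
      factor(c(enc$a1[ish, j], enc$a2[ish, j]), levels = seq_len(A)))), C, A,
      dimnames = list(collections, idx[[j]]))
  }
  list(cnt = cnt, het = het, ndip = ndip, collections = collections,
       loci = enc$loci, index = idx)
}

# Weir & Cockerham (1984) variance components for a subset of collections
# at one locus; returns c(a, b, c) summed over alleles, or NULL if fewer
# than 2 collections have data.
#' @keywords internal
wc_components <- function(cnt, het, ndip) {
  keep <- ndip > 0
  if (sum(keep) < 2) return(NULL)
  cnt <- cnt[keep, , drop = FALSE]
  het <- het[keep, , drop = FALSE]
  nn <- ndip[keep]
  r <- length(nn)
  nbar <- mean(nn)
  nc <- (r * nbar - sum(nn^2) / (r * nbar)) / (r - 1)
  p <- sweep(cnt, 1, 2 * nn, "/")
  h <- sweep(het, 1, nn, "/")
  acc <- c(0, 0, 0)
  for (al in seq_len(ncol(cnt))) {
    pbar <- sum(nn * p[, al]) / (r * nbar)
    s2 <- sum(nn * (p[, al] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nn * h[, al]) / (r * nbar)
    if (nbar <= 1) next
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    acc <- acc + c(a, b, cc)
  }
  acc
}

#' Weir-Cockerham F_ST
#'
#' Multiallelic theta of Weir & Cockerham (1984), combined across loci as a
#' ratio of summed variance components. Returns the pairwise
#' collection-by-collection matrix, the per-locus theta over all
#' collections, and the overall multi-collection estimate. Negative
#' estimates are reported as computed (not clamped).
#'
#' @param x labeled genotype table.
#' @return list with `pairwise` (symmetric C x C matrix, zero diagonal, NA
#'   where a pair shares no co-typed locus), `per_locus` (tibble: locus,
#'   theta), and `overall` (scalar theta across all collections and loci).
#' @export
pairwise_fst <- function(x) {
  st <- wc_stats(x)
  C <- length(st$collections); L <- length(st$loci)
  if (C < 2) stop("need at least two collections", call. = FALSE)
  pw <- matrix(0, C, C, dimnames = list(st$collections, st$collections))
  for (i in seq_len(C - 1)) {
    for (k in (i + 1):C) {
      num <- den <- 0
      for (j in seq_len(L)) {
        comp <- wc_components(st$cnt[[j]][c(i, k), , drop = FALSE],
                              st$het[[j]][c(i, k), , drop = FALSE],
                              st$ndip[c(i, k), j])
        if (!is.null(comp)) {
          num <- num + comp[1]
          den <- den + sum(comp)
        }
      }
      pw[i, k] <- pw[k, i] <- if (den > 0) num / den else NA_real_
    }
  }
  per_locus <- num_all <- den_all <- 0
  pl <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    comp <- wc_components(st$cnt[[j]], st$het[[j]], st$ndip[, j])
    if (!is.null(comp) && sum(comp) != 0) {
      pl[j] <- comp[1] / sum(comp)
      num_all <- num_all + comp[1]
      den_all <- den_all + sum(comp)
    }
  }
  list(pairwise = pw,
       per_locus = tibble::tibble(locus = st$loci, theta = pl),
       overall = if (den_all > 0) num_all / den_all else NA_real_)
}

#' Cavalli-Sforza-Edwards chord distance
#'
#' `d(i,j) = sqrt( mean_l ( 1 - sum_a sqrt(p_il_a * p_jl_a) ) )` — the
#' squared-chord-per-locus-average convention used by gendist-style tools.
#' Identical frequencies give 0; completely disjoint alleles at every locus
#' give 1. Loci untyped in either collection are dropped from that pair's
#' average.
#'
#' @param counts an `allele_counts` object (see [allele_counts()]).
#' @return symmetric labeled distance matrix.
#' @export
cse_chord_distance <- function(counts) {
  C <- length(counts$collections); L <- length(counts$loci)
  if (C < 2) stop("need at least two collections", call. = FALSE)
  if (any(rowSums(counts$n) == 0)) {
    stop("collection(s) with zero calls at every locus: ",
         paste(counts$collections[rowSums(counts$n) == 0], collapse = ", "),
         call. = FALSE)
  }
  p <- lapply(seq_len(L), function(j) {
    nn <- counts$n[, j]
    sweep(counts$x[[j]], 1, pmax(nn, 1L), "/")
  })
  d <- matrix(0, C, C, dimnames = list(counts$collections, counts$collections))
  for (i in seq_len(C - 1)) {
    for (k in (i + 1):C) {
      terms <- vapply(seq_len(L), function(j) {
        if (counts$n[i, j] == 0 || counts$n[k, j] == 0) return(NA_real_)
        1 - sum(sqrt(p[[j]][i, ] * p[[j]][k, ]))
      }, numeric(1))
      d[i, k] <- d[k, i] <- sqrt(mean(terms, na.rm = TRUE))
    }
  }
  d
}

#' Neighbor-joining tree with locus-bootstrap support
#'
#' Saitou-Nei NJ (via \pkg{ape}) on a chord-distance matrix. If `counts`
#' is supplied, support values are the percentage of `n_boot` trees — each
#' built from a chord distance recomputed after resampling loci with
#' replacement — that contain each internal bipartition; supports below 50
#' are omitted from the node labels, matching the usual display convention.
#'
#' @param d symmetric distance matrix with labels.
#' @param counts optional `allele_counts` for bootstrapping.
#' @param n_boot number of locus-bootstrap replicates.
#' @param seed RNG seed for the bootstrap (required when `n_boot > 0`).
#' @return list with `tree` (an `ape::phylo`, node labels = support >= 50,
#'   `""` otherwise), `support` (numeric per internal node, percent), and
#'   `newick` (serialized tree).
#' @export
nj_tree <- function(d, counts = NULL, n_boot = 0, seed = NULL) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(d))
  support <- rep(NA_real_, tree$Nnode)
  if (n_boot > 0) {
    if (is.null(counts)) stop("bootstrapping needs the allele_counts object", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    L <- length(counts$loci)
    btrees <- lapply(seq_len(n_boot), function(b) {
      jj <- sample.int(L, L, replace = TRUE)
      bc <- counts
      bc$x <- counts$x[jj]
      bc$n <- counts$n[, jj, drop = FALSE]
      bc$loci <- counts$loci[jj]
      ape::nj(stats::as.dist(cse_chord_distance(bc)))
    })
    cl <- ape::prop.clades(tree, btrees, rooted = FALSE)
    cl[is.na(cl)] <- 0
    support <- 100 * cl / n_boot
    tree$node.label <- ifelse(support >= 50, format(round(support), trim = TRUE), "")
  }
  list(tree = tree, support = support, newick = ape::write.tree(tree))
}
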