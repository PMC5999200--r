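#' @importFrom rlang .data
NULL

# Monte Carlo exact HWE test for one collection x locus cell.
#
# Gene copies are permuted among individuals and re-paired; the test
# statistic orders genotype configurations by their conditional probability
# given the allele counts (the multiallelic exact-test ordering), or, for
# alternative = "het_deficit", by the heterozygote count (one-sided).
# Returns the MC p-value (1 + #as-or-more-extreme) / (1 + n_perm).
#' @keywords internal
hwe_mc_cell <- function(g1, g2, n_perm, alternative = c("prob", "het_deficit")) {
  alternative <- match.arg(alternative)
  ok <- !is.na(g1)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  copies <- c(g1, g2)
  alleles <- sort(unique(copies))
  A <- length(alleles)
  if (A < 2 || n < 2) return(NA_real_)
  g1 <- match(g1, alleles); g2 <- match(g2, alleles)
  copies <- c(g1, g2)
  stat <- function(p1, p2) {
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    if (alternative == "het_deficit") return(sum(lo != hi))
    tb <- tabulate((lo - 1L) * A + hi, A * A)
    sum(lo != hi) * log(2) - sum(lgamma(tb + 1))
  }
  obs <- stat(g1, g2)
  extreme <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(copies)
    s <- stat(perm[seq_len(n)], perm[n + seq_len(n)])
    if (s <= obs + 1e-9) extreme <- extreme + 1L
  }
  (1 + extreme) / (1 + n_perm)
}

#' Hardy-Weinberg exact tests by Monte Carlo permutation
#'
#' For every collection x locus cell, gene copies are permuted among the
#' cell's individuals to obtain an exact-test p-value (probability ordering
#' of genotype configurations, suited to multiallelic loci with sparse
#' genotype classes). Monomorphic or near-empty cells are untestable and
#' excluded from the Bonferroni denominator.
#'
#' @param x labeled genotype table.
#' @param n_perm Monte Carlo permutations per cell (>= 100).
#' @param seed RNG seed (required: permutation p-values are stochastic).
#' @param alpha nominal significance level (default 0.05).
#' @param alternative `"prob"` (two-sided exact-test ordering) or
#'   `"het_deficit"` (one-sided, small p = fewer heterozygotes than expected).
#' @return object of class `hwe_report`: list with `tests` (tibble:
#'   collection, locus, n, testable, p, signif_nominal, signif_bonferroni),
#'   `alpha`, `n_tests` (testable cells), and `bonferroni_alpha`
#'   (`alpha / n_tests`).
#' @export
hwe_tests <- function(x, n_perm = 10000, seed = NULL, alpha = 0.05,
                      alternative = c("prob", "het_deficit")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x[["collection"]])) x[["collection"]] <- "all"
  idx <- build_allele_index(x)
  enc <- encode_genotypes(x, idx)
  collections <- unique(x[["collection"]])
  ci <- match(x[["collection"]], collections)
  rows <- vector("list", length(collections) * length(enc$loci))
  r <- 0L
  for (k in seq_along(collections)) {
    for (j in seq_along(enc$loci)) {
      sel <- ci == k
      g1 <- enc$a1[sel, j]; g2 <- enc$a2[sel, j]
      p <- hwe_mc_cell(g1, g2, n_perm, alternative)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(collection = collections[k],
                                  locus = enc$loci[j],
                                  n = sum(!is.na(g1)),
                                  testable = !is.na(p), p = p)
    }
  }
  tests <- dplyr::bind_rows(rows)
  n_tests <- sum(tests$testable)
  bonf <- alpha / max(n_tests, 1L)
  tests$signif_nominal <- tests$testable & tests$p < alpha
  tests$signif_bonferroni <- tests$testable & tests$p < bonf
  structure(list(tests = tests, alpha = alpha, n_tests = n_tests,
                 bonferroni_alpha = bonf),
            class = "hwe_report")
}

#' @export
print.hwe_report <- function(x, ...) {
  cat("hwe_report:", x$n_tests, "testable collection x locus cells;",
      sum(x$tests$signif_bonferroni), "significant after Bonferroni (alpha =",
      format(x$bonferroni_alpha, digits = 3), ")\n")
  invisible(x)
}
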