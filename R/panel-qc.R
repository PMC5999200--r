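#' Duplicate-based genotyping error rate
#'
#' Compares redundant/control sample pairs locus by locus. At each locus
#' where both members have a call, the two genotypes are matched as
#' multisets of two alleles, so a heterozygote/homozygote pair sharing one
#' allele counts one discordant allele call, not two. The error rate is
#' discordant allele calls / (2 x co-typed locus comparisons) — the
#' per-allele-call denominator.
#'
#' @param x genotype table containing both members of every pair.
#' @param pairs two-column data frame (`indiv_a`, `indiv_b`) of replicate
#'   pairs.
#' @return list with `error_rate`, `n_discordant`, `n_cotyped` (locus
#'   comparisons with both calls present), `per_locus` (tibble: locus,
#'   n_discordant, n_cotyped) and `excluded_pairs` (pairs with zero co-typed
#'   loci).
#' @export
genotyping_error_rate <- function(x, pairs) {
  if (nrow(pairs) == 0) stop("no duplicate pairs supplied", call. = FALSE)
  m <- allele_mats(x)
  ia <- match(pairs[[1]], m$indiv)
  ib <- match(pairs[[2]], m$indiv)
  if (anyNA(ia) || anyNA(ib)) {
    stop("pair member(s) missing from the genotype table", call. = FALSE)
  }
  L <- length(m$loci)
  per_err <- per_n <- stats::setNames(integer(L), m$loci)
  excluded <- integer(0)
  for (p in seq_along(ia)) {
    a1 <- m$a1[ia[p], ]; a2 <- m$a2[ia[p], ]
    b1 <- m$a1[ib[p], ]; b2 <- m$a2[ib[p], ]
    ok <- !is.na(a1) & !is.na(b1)
    if (!any(ok)) { excluded <- c(excluded, p); next }
    # multiset intersection size of {a1,a2} and {b1,b2} per locus
    shared <- integer(L)
    exact <- ok & a1 == b1 & a2 == b2
    shared[exact] <- 2L
    # calls are sorted pairs, so non-identical genotypes share at most one
    # allele as multisets: any single equality means exactly one shared call
    part <- ok & !exact
    shared[part] <- as.integer(a1[part] == b1[part] | a1[part] == b2[part] |
                                 a2[part] == b1[part] | a2[part] == b2[part])
    err <- ifelse(ok, 2L - shared, 0L)
    per_err <- per_err + err
    per_n <- per_n + as.integer(ok)
  }
  n_cotyped <- sum(per_n)
  list(error_rate = sum(per_err) / (2 * n_cotyped),
       n_discordant = sum(per_err),
       n_cotyped = n_cotyped,
       per_locus = tibble::tibble(locus = m$loci,
                                  n_discordant = unname(per_err),
                                  n_cotyped = unname(per_n)),
       excluded_pairs = pairs[excluded, , drop = FALSE])
}

#' Screen candidate loci
#'
#' Applies the five rejection criteria used when trimming a candidate
#' microsatellite panel. A locus is rejected if any criterion fires:
#' \describe{
#'   \item{null_alleles}{F_IS above `fis_null` together with a one-sided
#'     heterozygote-deficit exact-test p-value below 0.05 (a statistical
#'     proxy — null alleles manifest as apparent heterozygote deficit).}
#'   \item{low_variability}{fewer than `min_alleles` distinct alleles.}
#'   \item{poor_amplification}{mean read depth per sample below `min_depth`
#'     or above `max_depth` (skipped with a warning when no depth table).}
#'   \item{multi_copy}{fraction of individuals with more than two called
#'     alleles above `max_multiallelic_frac` (0 = any such individual).}
#'   \item{scoring_difficulty}{fraction of ambiguous/failed (missing) calls
#'     above `max_ambiguous_frac`.}
#' }
#'
#' @param x genotype table of test samples.
#' @param depth optional numeric matrix (individuals x loci, colnames =
#'   loci) of summed read depth.
#' @param n_alleles_called optional integer matrix (individuals x loci) of
#'   the number of distinct alleles called per individual (from the raw
#'   caller output); when absent, criterion (iv) never fires.
#' @param thresholds named list overriding any of `min_alleles` (4),
#'   `min_depth` (200), `max_depth` (10000), `fis_null` (0.2),
#'   `max_multiallelic_frac` (0), `max_ambiguous_frac` (0.05).
#' @param n_perm,seed Monte Carlo settings for the heterozygote-deficit test.
#' @return object of class `locus_qc`: tibble with one row per locus —
#'   supporting statistics, one logical column per criterion, and
#'   `status` (`"pass"`/`"reject"`).
#' @export
screen_loci <- function(x, depth = NULL, n_alleles_called = NULL,
                        thresholds = list(), n_perm = 2000, seed = NULL) {
  th <- utils::modifyList(list(min_alleles = 4, min_depth = 200,
                               max_depth = 10000, fis_null = 0.2,
                               max_multiallelic_frac = 0,
                               max_ambiguous_frac = 0.05), thresholds)
  if (!is.null(seed)) set.seed(seed)
  idx <- build_allele_index(x)
  enc <- encode_genotypes(x, idx)
  L <- length(enc$loci)
  if (is.null(depth)) warning("no depth table: poor_amplification criterion skipped")
  rows <- vector("list", L)
  for (j in seq_len(L)) {
    a1 <- enc$a1[, j]; a2 <- enc$a2[, j]
    ok <- !is.na(a1)
    n <- sum(ok)
    A <- length(idx[[j]])
    # F_IS = 1 - H_O / H_E over the pooled test sample
    ho <- if (n > 0) mean(a1[ok] != a2[ok]) else NA_real_
    he <- if (n > 1) {
      p <- tabulate(c(a1[ok], a2[ok]), A) / (2 * n)
      (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    } else NA_real_
    fis <- if (!is.na(he) && he > 0) 1 - ho / he else NA_real_
    hd_p <- if (A >= 2 && n >= 2) hwe_mc_cell(a1, a2, n_perm, "het_deficit") else NA_real_
    mean_depth <- if (!is.null(depth)) mean(depth[, enc$loci[j]], na.rm = TRUE) else NA_real_
    multi_frac <- if (!is.null(n_alleles_called))
      mean(n_alleles_called[, enc$loci[j]] > 2, na.rm = TRUE) else 0
    amb_frac <- mean(!ok)
    crit <- c(
      null_alleles = isTRUE(fis > th$fis_null) && isTRUE(hd_p < 0.05),
      low_variability = A < th$min_alleles,
      poor_amplification = !is.null(depth) &&
        (isTRUE(mean_depth < th$min_depth) || isTRUE(mean_depth > th$max_depth)),
      multi_copy = isTRUE(multi_frac > th$max_multiallelic_frac),
      scoring_difficulty = amb_frac > th$max_ambiguous_frac
    )
    rows[[j]] <- tibble::tibble(
      locus = enc$loci[j], n_alleles = A, fis = fis, het_deficit_p = hd_p,
      mean_depth = mean_depth, multi_frac = multi_frac, ambiguous_frac = amb_frac,
      null_alleles = crit[["null_alleles"]],
      low_variability = crit[["low_variability"]],
      poor_amplification = crit[["poor_amplification"]],
      multi_copy = crit[["multi_copy"]],
      scoring_difficulty = crit[["scoring_difficulty"]],
      status = if (any(crit)) "reject" else "pass")
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("locus_qc", class(out))
  out
}
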