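#' Synthetic-baseline configuration
#'
#' Defaults emulate the study conditions the package is designed around: 35
#' populations genotyped at 101 microsatellite loci averaging 8.4 alleles
#' per locus, mean pairwise F_ST near 0.051, ~45 individuals per river,
#' a per-allele genotyping error rate of 0.14%, and a low background rate of
#' missing calls.
#'
#' @param n_pops number of populations (collections).
#' @param n_loci number of loci.
#' @param mean_alleles_per_locus mean of the shifted-Poisson allele-count
#'   draw (`A_l = 2 + Poisson(mean - 2)`, so every locus is polymorphic).
#' @param fst_target Balding-Nichols drift parameter F (between populations,
#'   or within groups when `hierarchical_groups` is set).
#' @param n_per_pop individuals per population.
#' @param missing_rate per-call probability of a missing genotype.
#' @param error_rate per-allele-call probability of a miscall (replaced by a
#'   uniformly chosen different allele).
#' @param n_duplicates number of individuals re-genotyped as duplicate
#'   samples (fresh observation of the same true genotype).
#' @param duplicate_error `"none"` (default): duplicates are error-free
#'   control re-reads, so the duplicate-discordance estimator targets
#'   `error_rate` itself; `"both"`: duplicates carry independent miscalls
#'   too, in which case discordance reflects the combined error of the two
#'   runs (about twice the per-run rate).
#' @param hierarchical_groups optional `list(n_groups =, fst_between =)`
#'   giving a two-level structure: group frequencies diverge from the
#'   ancestor at `fst_between`, populations from their group at
#'   `fst_target`; populations are split into groups as evenly as possible
#'   and `repunit` is set to the group.
#' @param seed RNG seed (required — generation is fully deterministic given
#'   the config).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 35, n_loci = 101, mean_alleles_per_locus = 8.4,
                       fst_target = 0.051, n_per_pop = 45, missing_rate = 0.02,
                       error_rate = 0.0014, n_duplicates = 0,
                       duplicate_error = c("none", "both"),
                       hierarchical_groups = NULL, seed) {
  duplicate_error <- match.arg(duplicate_error)
  stopifnot(fst_target > 0, fst_target < 1, missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1, n_per_pop >= 1,
            mean_alleles_per_locus >= 2)
  if (missing(seed)) stop("sim_config needs an explicit seed", call. = FALSE)
  if (!is.null(hierarchical_groups)) {
    stopifnot(hierarchical_groups$n_groups >= 1,
              hierarchical_groups$fst_between > 0, hierarchical_groups$fst_between < 1)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate tiny-alpha draw
  g / sum(g)
}

#' Generate a synthetic baseline
#'
#' Balding-Nichols divergence model: per locus, an ancestral frequency
#' vector is drawn from a symmetric Dirichlet over `A_l` alleles, and each
#' population's frequencies from `Dirichlet(p_anc * (1 - F) / F)` (optionally
#' through an intermediate group level). Diploid genotypes are drawn under
#' Hardy-Weinberg, then per-allele miscalls, missing calls, and duplicate
#' re-genotypes are layered on — in that order, so duplicates share the true
#' genotype but not the noise.
#'
#' @param cfg a [sim_config()].
#' @return list with `baseline` (genotype table with `collection` and
#'   `repunit`), `true_freqs` (per locus, a pops x alleles frequency
#'   matrix), `duplicate_pairs` (tibble `indiv_a`, `indiv_b`), and `cfg`.
#' @export
generate_baseline <- function(cfg) {
  set.seed(cfg$seed)
  P <- cfg$n_pops; L <- cfg$n_loci
  pops <- sprintf("pop_%02d", seq_len(P))
  group_of <- NULL
  if (!is.null(cfg$hierarchical_groups)) {
    G <- cfg$hierarchical_groups$n_groups
    group_of <- sort(rep_len(seq_len(G), P))
  }
  loci <- sprintf("Locus%03d", seq_len(L))
  true_freqs <- vector("list", L); names(true_freqs) <- loci
  for (j in seq_len(L)) {
    A <- 2L + stats::rpois(1, cfg$mean_alleles_per_locus - 2)
    labels <- as.character(seq(100L, by = 3L, length.out = A))
    anc <- rdirichlet1(rep(1, A))
    pf <- matrix(0, P, A, dimnames = list(pops, labels))
    if (is.null(group_of)) {
      for (p in seq_len(P)) {
        pf[p, ] <- rdirichlet1(anc * (1 - cfg$fst_target) / cfg$fst_target)
      }
    } else {
      Fb <- cfg$hierarchical_groups$fst_between
      gf <- t(vapply(seq_len(max(group_of)), function(g)
        rdirichlet1(anc * (1 - Fb) / Fb), numeric(A)))
      for (p in seq_len(P)) {
        pf[p, ] <- rdirichlet1(gf[group_of[p], ] * (1 - cfg$fst_target) / cfg$fst_target)
      }
    }
    true_freqs[[j]] <- pf
  }
  N <- P * cfg$n_per_pop
  collection <- rep(pops, each = cfg$n_per_pop)
  indiv <- paste0(collection, "_", sprintf("%03d", sequence(rep(cfg$n_per_pop, P))))
  true1 <- matrix(NA_integer_, N, L, dimnames = list(indiv, loci))
  true2 <- true1
  for (j in seq_len(L)) {
    A <- ncol(true_freqs[[j]])
    for (p in seq_len(P)) {
      rowsel <- which(collection == pops[p])
      draws <- sample.int(A, 2 * length(rowsel), replace = TRUE,
                          prob = true_freqs[[j]][p, ])
      true1[rowsel, j] <- draws[seq_along(rowsel)]
      true2[rowsel, j] <- draws[length(rowsel) + seq_along(rowsel)]
    }
  }
  observe <- function(t1, t2) {
    o1 <- corrupt_calls(t1, true_freqs, cfg$error_rate)
    o2 <- corrupt_calls(t2, true_freqs, cfg$error_rate)
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(length(o1)) < cfg$missing_rate, nrow(o1))
      o1[miss] <- NA_integer_; o2[miss] <- NA_integer_
    }
    list(a1 = pmin(o1, o2), a2 = pmax(o1, o2))
  }
  obs <- observe(true1, true2)
  repunit <- if (is.null(group_of)) collection else
    sprintf("group_%d", group_of[match(collection, pops)])
  baseline <- decode_enc(list(a1 = obs$a1, a2 = obs$a2, indiv = indiv, loci = loci),
                         true_freqs_index(true_freqs),
                         collection = collection, repunit = repunit)
  duplicate_pairs <- tibble::tibble(indiv_a = character(), indiv_b = character())
  if (cfg$n_duplicates > 0) {
    dup_i <- sample.int(N, min(cfg$n_duplicates, N))
    # duplicates are control re-reads: error-free by default, so the
    # discordance-based estimator's expectation equals error_rate (each
    # discordance reflects one erroneous call in the error-prone member)
    dup_err <- if (identical(cfg$duplicate_error, "both")) cfg$error_rate else 0
    dob <- local({
      o1 <- corrupt_calls(true1[dup_i, , drop = FALSE], true_freqs, dup_err)
      o2 <- corrupt_calls(true2[dup_i, , drop = FALSE], true_freqs, dup_err)
      if (cfg$missing_rate > 0) {
        miss <- matrix(stats::runif(length(o1)) < cfg$missing_rate, nrow(o1))
        o1[miss] <- NA_integer_; o2[miss] <- NA_integer_
      }
      list(a1 = pmin(o1, o2), a2 = pmax(o1, o2))
    })
    dups <- decode_enc(list(a1 = dob$a1, a2 = dob$a2,
                            indiv = paste0(indiv[dup_i], "_dup"), loci = loci),
                       true_freqs_index(true_freqs),
                       collection = collection[dup_i],
                       repunit = repunit[dup_i])
    baseline <- dplyr::bind_rows(baseline, dups)
    duplicate_pairs <- tibble::tibble(indiv_a = indiv[dup_i],
                                      indiv_b = paste0(indiv[dup_i], "_dup"))
  }
  list(baseline = baseline, true_freqs = true_freqs,
       duplicate_pairs = duplicate_pairs, cfg = cfg)
}

# per-allele miscall: with prob error_rate replace by a uniformly chosen
# *different* allele at the locus
#' @keywords internal
corrupt_calls <- function(calls, true_freqs, error_rate) {
  if (error_rate == 0) return(calls)
  for (j in seq_len(ncol(calls))) {
    A <- ncol(true_freqs[[j]])
    if (A < 2) next
    hit <- which(stats::runif(nrow(calls)) < error_rate)
    if (length(hit)) {
      shift <- sample.int(A - 1L, length(hit), replace = TRUE)
      calls[hit, j] <- 1L + (calls[hit, j] - 1L + shift) %% A
    }
  }
  calls
}

#' @keywords internal
true_freqs_index <- function(true_freqs) {
  lapply(true_freqs, colnames)
}

#' Generate a mixture sample from true population frequencies
#'
#' Fish origins are multinomial at `props`; genotypes are drawn under
#' Hardy-Weinberg from the true (not sampled) population frequencies, with
#' no missingness or genotyping error.
#'
#' @param true_freqs per-locus pops x alleles frequency matrices (from
#'   [generate_baseline()]).
#' @param props named numeric vector over populations, summing to 1.
#' @param n mixture size (0 gives an empty table with a valid truth record).
#' @param seed RNG seed.
#' @return list with `mixture` (unlabeled genotype table), `truth`
#'   (list: `props`, `origin` — true population per fish).
#' @export
generate_mixture <- function(true_freqs, props, n, seed) {
  if (any(props < 0)) stop("props must be non-negative", call. = FALSE)
  if (abs(sum(props) - 1) > 1e-8) stop("props must sum to 1", call. = FALSE)
  set.seed(seed)
  pops <- rownames(true_freqs[[1]])
  if (is.null(names(props))) names(props) <- pops
  loci <- names(true_freqs)
  origin <- if (n > 0) sample(names(props), n, replace = TRUE, prob = props) else character(0)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (j in seq_along(loci)) {
    A <- ncol(true_freqs[[j]])
    for (p in unique(origin)) {
      rowsel <- which(origin == p)
      draws <- sample.int(A, 2 * length(rowsel), replace = TRUE,
                          prob = true_freqs[[j]][p, ])
      d1 <- draws[seq_along(rowsel)]
      d2 <- draws[length(rowsel) + seq_along(rowsel)]
      a1[rowsel, j] <- pmin(d1, d2)
      a2[rowsel, j] <- pmax(d1, d2)
    }
  }
  mixture <- decode_enc(list(a1 = a1, a2 = a2,
                             indiv = if (n > 0) sprintf("mix_%04d", seq_len(n)) else character(0),
                             loci = loci),
                        true_freqs_index(true_freqs))
  list(mixture = mixture, truth = list(props = props, origin = origin))
}
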