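#' Baseline summary statistics bundle
#'
#' One-call wrapper over the baseline-characterization stage: allele index
#' summary, observed/expected heterozygosity, Hardy-Weinberg report,
#' Weir-Cockerham F_ST (pairwise and per-locus), chord distances, and the
#' NJ tree with locus-bootstrap support. If `outdir` is given, each artifact
#' is written there (CSVs, newick, and a JSON manifest with the seeds used).
#'
#' @param x labeled baseline genotype table.
#' @param n_perm HWE Monte Carlo permutations per cell.
#' @param n_boot_tree locus-bootstrap replicates for the NJ tree (0 = none).
#' @param seed RNG seed for the stochastic components.
#' @param outdir optional output directory (created if needed).
#' @return list: `index`, `het`, `hwe`, `fst`, `chord`, `nj`.
#' @export
baseline_summary <- function(x, n_perm = 1000, n_boot_tree = 100, seed = 1,
                             outdir = NULL) {
  validate_geno(x)
  if (nrow(x) == 0) stop("empty baseline", call. = FALSE)
  index <- build_allele_index(x)
  counts <- allele_counts(x, index)
  het <- heterozygosity(x)
  hwe <- hwe_tests(x, n_perm = n_perm, seed = seed)
  fst <- pairwise_fst(x)
  chord <- cse_chord_distance(counts)
  nj <- nj_tree(chord, counts = counts, n_boot = n_boot_tree, seed = seed + 1L)
  out <- list(index = index, het = het, hwe = hwe, fst = fst, chord = chord, nj = nj)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(het$per_cell, file.path(outdir, "heterozygosity.csv"))
    readr::write_csv(hwe$tests, file.path(outdir, "hwe_tests.csv"))
    readr::write_csv(fst$per_locus, file.path(outdir, "fst_per_locus.csv"))
    utils::write.csv(fst$pairwise, file.path(outdir, "fst_pairwise.csv"))
    utils::write.csv(chord, file.path(outdir, "chord_distance.csv"))
    writeLines(nj$newick, file.path(outdir, "nj_tree.nwk"))
    write_manifest(file.path(outdir, "manifest.json"),
                   list(stage = "baseline_summary", seed = seed, n_perm = n_perm,
                        n_boot_tree = n_boot_tree,
                        n_individuals = nrow(x), n_loci = length(index),
                        total_alleles = attr(index, "total_alleles")))
  }
  out
}

#' @keywords internal
write_manifest <- function(path, fields) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste(names(fields), vapply(fields, format, character(1)),
                     sep = ": "), path)
  }
  invisible(path)
}

#' @keywords internal
subset_loci <- function(x, loci) {
  keep <- intersect(names(x), c(META_COLS, as.vector(rbind(loci, paste0(loci, ".1")))))
  x[, keep, drop = FALSE]
}

#' Assignment accuracy of cumulative multiplex subsets
#'
#' Runs 100% simulations on nested locus subsets: each multiplex alone
#' first, then the best multiplex (highest mean individual accuracy alone)
#' with the remaining multiplexes added one at a time in decreasing order of
#' their stand-alone accuracy. Quantifies how accuracy grows as PCR
#' multiplexes are added to the panel.
#'
#' @param baseline labeled genotype table.
#' @param multiplex_map named character vector, locus -> multiplex label;
#'   must cover every locus of the baseline.
#' @param design a [sim_design()] of kind `"pct100"`.
#' @param cfg an [mcmc_config()].
#' @param threshold posterior assignment threshold.
#' @return list with `alone` (tibble: multiplex, n_loci, accuracy,
#'   efficiency) and `cumulative` (tibble: step, multiplexes, n_loci,
#'   accuracy, efficiency, mean_est_prop).
#' @export
subset_accuracy <- function(baseline, multiplex_map, design = sim_design("pct100"),
                            cfg = mcmc_config(), threshold = 0.70) {
  loci <- geno_loci(baseline)
  if (!all(loci %in% names(multiplex_map))) {
    stop("multiplex_map must cover all loci", call. = FALSE)
  }
  plexes <- unique(unname(multiplex_map[loci]))
  plex_loci <- split(loci, unname(multiplex_map[loci]))[plexes]
  if (any(lengths(plex_loci) == 0)) stop("multiplex with zero loci", call. = FALSE)
  run_one <- function(sub_loci) {
    r <- run_100pct(subset_loci(baseline, sub_loci), design, cfg, threshold)
    list(accuracy = r$individual_report$overall$accuracy,
         efficiency = r$individual_report$overall$efficiency,
         mean_est_prop = mean(r$mixture_props$est_prop))
  }
  alone <- lapply(plex_loci, run_one)
  alone_tbl <- tibble::tibble(multiplex = plexes,
                              n_loci = lengths(plex_loci)[plexes],
                              accuracy = vapply(alone, `[[`, numeric(1), "accuracy"),
                              efficiency = vapply(alone, `[[`, numeric(1), "efficiency"))
  ord <- plexes[order(-alone_tbl$accuracy)]
  cum_rows <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    sub <- unlist(plex_loci[ord[seq_len(k)]], use.names = FALSE)
    res <- if (k == 1) alone[[ord[1]]] else run_one(sub)
    cum_rows[[k]] <- tibble::tibble(step = k,
                                    multiplexes = paste(ord[seq_len(k)], collapse = "+"),
                                    n_loci = length(sub),
                                    accuracy = res$accuracy,
                                    efficiency = res$efficiency,
                                    mean_est_prop = res$mean_est_prop)
  }
  list(alone = alone_tbl, cumulative = dplyr::bind_rows(cum_rows))
}

#' Estimate the composition of fishery samples
#'
#' Fits the mixture model to one or more mixture genotype tables against a
#' common baseline, applies the parametric-bootstrap bias correction, and
#' returns tidy per-unit proportions with 95% credible intervals plus
#' per-individual top assignments. Empty mixture tables are skipped with a
#' warning. Alleles found only in a mixture are handled through the union
#' allele index (they receive prior mass everywhere).
#'
#' @param baseline labeled genotype table.
#' @param mixtures a single genotype table or a named list of them.
#' @param cfg an [mcmc_config()]; its `n_boot` drives the correction.
#' @param threshold posterior threshold used for flagging confident
#'   individual assignments.
#' @param outdir optional output directory for CSV reports.
#' @return named list per mixture: `result` (the `gsi_result`),
#'   `proportions` (see [mixing_proportions()]), `individuals` (tibble:
#'   indiv, top repunit, posterior, assigned at threshold).
#' @export
estimate_fishery <- function(baseline, mixtures, cfg = mcmc_config(),
                             threshold = 0.70, outdir = NULL) {
  if (is.data.frame(mixtures)) mixtures <- list(mixture = mixtures)
  if (is.null(names(mixtures))) names(mixtures) <- paste0("mixture_", seq_along(mixtures))
  out <- list()
  for (nm in names(mixtures)) {
    mix <- mixtures[[nm]]
    if (nrow(mix) == 0) {
      warning("mixture '", nm, "' is empty; skipped")
      next
    }
    res <- fit_mixture(mix, baseline, cfg)
    if (cfg$n_boot > 0) res <- bootstrap_correct(res)
    rp <- res$ru_posterior
    top_j <- max.col(rp, ties.method = "first")
    individuals <- tibble::tibble(
      indiv = rownames(rp),
      repunit = colnames(rp)[top_j],
      posterior = rp[cbind(seq_len(nrow(rp)), top_j)],
      assigned = rp[cbind(seq_len(nrow(rp)), top_j)] >= threshold)
    out[[nm]] <- list(result = res, proportions = mixing_proportions(res),
                      individuals = individuals)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(out[[nm]]$proportions,
                       file.path(outdir, paste0(nm, "_proportions.csv")))
      readr::write_csv(individuals, file.path(outdir, paste0(nm, "_individuals.csv")))
      write_manifest(file.path(outdir, paste0(nm, "_manifest.json")),
                     list(stage = "estimate_fishery", mixture = nm,
                          n = nrow(mix), seed = cfg$seed,
                          n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                          n_boot = cfg$n_boot, threshold = threshold))
    }
  }
  out
}
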