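test_that("posterior-mean frequencies follow the Dirichlet formula", {
  tbl <- toy_geno(list(L1 = c("a/a", "a/a", "a/a", "a/a", "a/a",
                              "a/b", "b/b", "b/b", "b/b", "b/b")),
                  collection = rep(c("P", "Q"), each = 5))
  cnt <- allele_counts(tbl)
  # P: x = (10, 0), n = 10, A = 2, lambda = 1/2 -> theta = (10.5, 0.5)/11
  m <- posterior_freqs(cnt)
  expect_equal(unname(m$theta$L1["P", ]), c(10.5, 0.5) / 11)
  # symmetric counts give 1/2 regardless of lambda
  tbl2 <- toy_geno(list(L1 = c("a/b", "a/b")), collection = c("P", "P"))
  m2 <- posterior_freqs(allele_counts(tbl2), "constant", lambda_const = 3.7)
  expect_equal(unname(m2$theta$L1["P", ]), c(0.5, 0.5))
  expect_true(all(vapply(m$theta, function(t) max(abs(rowSums(t) - 1)), 1) < 1e-12))
})

test_that("genotype log-likelihood is the diploid HWE likelihood", {
  # counts tuned so theta is exactly (0.25, 0.75) at HomLoc (lambda = 1)
  # and (0.2, 0.3, 0.5) at HetLoc (lambda = 2)
  hom <- c("b/b", "b/b", "b/b", "b/b", "a/a", NA, NA)   # x = (2, 8), n = 10
  het <- c("c/c", "c/c", "c/c", "c/b", "c/b", "b/b", "a/a")  # x = (2,4,8), n = 14
  tbl <- toy_geno(list(HomLoc = hom, HetLoc = het), collection = rep("P", 7))
  cnt <- allele_counts(tbl)
  m1 <- posterior_freqs(cnt, "constant", lambda_const = 1)
  expect_equal(unname(m1$theta$HomLoc["P", ]), c(0.25, 0.75))
  fish_hom <- toy_geno(list(HomLoc = "a/a", HetLoc = NA))
  expect_equal(genotype_loglik(fish_hom, m1, "P")[[1]], log(0.0625))
  m2 <- posterior_freqs(cnt, "constant", lambda_const = 2)
  expect_equal(unname(m2$theta$HetLoc["P", ]), c(0.2, 0.3, 0.5))
  fish_het <- toy_geno(list(HomLoc = NA, HetLoc = "a/b"))
  expect_equal(genotype_loglik(fish_het, m2, "P")[[1]], log(2 * 0.2 * 0.3))
  # all loci missing -> log-likelihood 0 everywhere
  blank <- toy_geno(list(HomLoc = NA, HetLoc = NA))
  expect_equal(unname(likelihood_matrix(blank, m1)[1, ]), 0)
})

test_that("likelihood matrix is invariant to locus order and allele relabeling", {
  set.seed(3)
  gb <- generate_baseline(sim_config(n_pops = 3, n_loci = 6, n_per_pop = 15,
                                     fst_target = 0.08, seed = 12))
  base <- gb$baseline
  mix <- generate_mixture(gb$true_freqs, c(pop_01 = 1, pop_02 = 0, pop_03 = 0),
                          n = 8, seed = 4)$mixture
  model <- posterior_freqs(allele_counts(base, build_allele_index(list(base, mix))))
  ll <- likelihood_matrix(mix, model)
  # permute locus column pairs
  loci <- geno_loci(base)
  perm <- sample(loci)
  shuffle <- function(x) x[, c("indiv", intersect(c("collection", "repunit"), names(x)),
                               as.vector(rbind(perm, paste0(perm, ".1"))))]
  model_p <- posterior_freqs(allele_counts(shuffle(base),
                                           build_allele_index(list(shuffle(base), shuffle(mix)))))
  ll_p <- likelihood_matrix(shuffle(mix), model_p)
  expect_equal(ll, ll_p, tolerance = 1e-12)
  # relabel alleles at one locus (prefix that keeps string sort order)
  relab <- function(x) {
    for (cc in c(loci[1], paste0(loci[1], ".1"))) {
      x[[cc]] <- ifelse(is.na(x[[cc]]), NA, paste0("al", x[[cc]]))
    }
    x
  }
  model_r <- posterior_freqs(allele_counts(relab(base),
                                           build_allele_index(list(relab(base), relab(mix)))))
  expect_equal(likelihood_matrix(relab(mix), model_r), ll, tolerance = 1e-12)
})

test_that("leave-one-out equals manual decrement on a 3-individual toy", {
  tbl <- toy_geno(list(L1 = c("a/b", "a/a", "b/c"),
                       L2 = c("x/x", "x/y", NA)),
                  collection = c("P", "P", "Q"))
  sa <- self_assign_loo(tbl)
  idx <- build_allele_index(tbl)
  for (i in 1:3) {
    reduced <- tbl[-i, , drop = FALSE]
    # collection Q vanishes when its only member is removed; keep the row
    # but with all calls missing so the collection survives with n = 0
    if (!tbl$collection[i] %in% reduced$collection) {
      ghost <- tbl[i, , drop = FALSE]
      ghost[, setdiff(names(ghost), c("indiv", "collection", "repunit"))] <- NA
      reduced <- dplyr::bind_rows(reduced, ghost)
    }
    model_i <- posterior_freqs(allele_counts(reduced, idx))
    ll_i <- likelihood_matrix(tbl[i, , drop = FALSE], model_i)
    ll_i <- ll_i[, colnames(sa$posterior), drop = FALSE]
    post_i <- exp(ll_i) / sum(exp(ll_i))
    expect_equal(unname(sa$posterior[i, ]), unname(post_i[1, ]), tolerance = 1e-12)
  }
})

test_that("self-assignment degenerate cases behave", {
  one <- toy_geno(list(L1 = c("a/b", "a/a", "b/b")), collection = rep("only", 3))
  sa1 <- self_assign_loo(one)
  expect_true(all(sa1$posterior == 1))
  # two identical collections: mean posterior ~ 0.5 each
  sa2 <- self_assign_loo(identical_pair_baseline(n_per = 20, n_loci = 4))
  expect_equal(unname(colMeans(sa2$posterior)), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(unname(rowSums(sa2$posterior)), rep(1, 40), tolerance = 1e-9)
})

test_that("Gibbs posterior mean matches grid integration (C=2, small n)", {
  instances <- list(
    list(base = toy_geno(list(L1 = c("a/a", "a/b", "b/b", "a/a", "b/b", "a/b"),
                              L2 = c("x/y", "x/x", "y/y", "x/x", "y/y", "x/y")),
                         collection = rep(c("P", "Q"), each = 3)),
         mix = toy_geno(list(L1 = c("a/a", "a/b", "b/b"),
                             L2 = c("x/x", NA, "y/y")), indiv = paste0("m", 1:3))),
    list(base = toy_geno(list(L1 = c("a/b", "a/c", "c/c", "b/b", "b/c", "a/a")),
                         collection = rep(c("P", "Q"), each = 3)),
         mix = toy_geno(list(L1 = c("a/a", "c/c", "a/c", "b/c")),
                        indiv = paste0("m", 1:4)))
  )
  for (ins in instances) {
    cfg <- mcmc_config(n_iter = 21000, burn_in = 1000, n_boot = 0, seed = 42)
    res <- fit_mixture(ins$mix, ins$base, cfg)
    model <- res$model
    logL <- likelihood_matrix(ins$mix, model)
    grid_mean <- grid_pi_posterior_mean(logL)
    se <- batch_se(res$pi_trace[, "P"])
    expect_lt(abs(res$pi_hat["P"] - grid_mean), 3 * se + 1e-4)
  }
})

test_that("mixture fitting hits its analytic endpoints", {
  # disjoint alleles, mixture 100% from C1
  # posterior mean of pi under a flat prior is ~(n_1 + 1)/(n + 2), so a
  # mixture of 150 fish is needed before 0.99 is reachable
  base <- disjoint_baseline(n_coll = 2, n_loci = 4, n_per = 160)
  mix <- base[base$collection == "C1", ][1:150, ]
  mix$collection <- NULL; mix$repunit <- NULL
  mix$indiv <- paste0("m", seq_len(nrow(mix)))
  res <- fit_mixture(mix, base, mcmc_config(n_iter = 4000, burn_in = 500,
                                            n_boot = 0, seed = 9))
  expect_gte(res$pi_hat["C1"], 0.99)
  expect_true(all(abs(rowSums(res$posterior) - 1) < 1e-9))
  expect_true(all(abs(rowSums(res$pi_trace) - 1) < 1e-9))
  # identical collections: posterior mean ~ prior mean (0.5, 0.5)
  same <- identical_pair_baseline(n_per = 15, n_loci = 3)
  mix2 <- same[1:10, ]; mix2$collection <- NULL; mix2$indiv <- paste0("m", 1:10)
  res2 <- fit_mixture(mix2, same, mcmc_config(n_iter = 8000, burn_in = 1000,
                                              n_boot = 0, seed = 10))
  expect_equal(unname(res2$pi_hat), c(0.5, 0.5), tolerance = 0.05)
  # credible intervals bracket the posterior mean
  expect_true(all(res2$ci_ru[, "lo"] <= res2$pi_hat_ru + 1e-9 &
                    res2$pi_hat_ru <= res2$ci_ru[, "hi"] + 1e-9))
  # config validation
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(fit_mixture(mix[0, ], base), "empty")
})

test_that("bootstrap correction reduces to identity with zero bias or zero boots", {
  base <- disjoint_baseline(n_coll = 3, n_loci = 3, n_per = 20)
  mix <- base[c(1:20, 21:40, 41:60), ]
  mix$collection <- NULL; mix$repunit <- NULL; mix$indiv <- paste0("m", 1:60)
  cfg0 <- mcmc_config(n_iter = 2000, burn_in = 200, n_boot = 0, seed = 2)
  res0 <- fit_mixture(mix, base, cfg0)
  expect_equal(res0$pi_corrected, res0$pi_hat_ru)
  # with boots on a perfectly separable baseline the correction is tiny
  cfg <- mcmc_config(n_iter = 2000, burn_in = 200, n_boot = 80, seed = 2)
  res <- bootstrap_correct(fit_mixture(mix, base, cfg))
  expect_equal(sum(res$pi_corrected), 1, tolerance = 1e-12)
  expect_lt(max(abs(res$pi_corrected - res$pi_hat_ru)), 0.02)
})
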