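test_that("posterior-predictive simulation recovers collection frequencies", {
  # near-fixed collection: simulated fish are almost surely homozygous
  tbl <- toy_geno(list(L1 = rep("a/a", 40)), collection = rep("P", 40))
  cnt <- allele_counts(tbl)
  sim <- simulate_individual(cnt, "P", n = 200, seed = 1)
  expect_gt(mean(sim$L1 == "a" & sim$L1.1 == "a"), 0.95)
  # frequency recovery: 10,000 gene copies vs posterior mean
  tbl2 <- toy_geno(list(L1 = c(rep("a/b", 10), rep("a/a", 15), rep("b/b", 5))),
                   collection = rep("P", 30))
  cnt2 <- allele_counts(tbl2)
  model2 <- posterior_freqs(cnt2)
  sim2 <- simulate_individual(cnt2, "P", n = 5000, seed = 2)
  p_a <- mean(c(sim2$L1, sim2$L1.1) == "a")
  theta_a <- model2$theta$L1["P", "a"]
  expect_lt(abs(p_a - theta_a), 3 * sqrt(theta_a * (1 - theta_a) / 10000))
  # empty counts: draws uniform over the locus's alleles
  tbl3 <- toy_geno(list(L1 = c("a/b", "b/c", NA), L2 = c(NA, NA, "x/y")),
                   collection = c("P", "P", "Q"))
  sim3 <- simulate_individual(allele_counts(tbl3), "Q", n = 3000, seed = 3)
  fr <- table(c(sim3$L1, sim3$L1.1)) / 6000
  expect_true(all(abs(fr - 1 / 3) < 0.03))
})

test_that("assignment scoring implements the accuracy/efficiency definitions", {
  # 10 fish truly from G; 8 assigned in total to G of which 6 are correct
  units <- c("G", "H")
  truth <- c(rep("G", 10), rep("H", 4))
  post <- matrix(0, 14, 2, dimnames = list(NULL, units))
  # 6 G fish confidently and correctly assigned to G
  post[1:6, "G"] <- 0.95; post[1:6, "H"] <- 0.05
  # 2 G fish assigned to H (wrongly)
  post[7:8, "H"] <- 0.9; post[7:8, "G"] <- 0.1
  # 2 G fish below threshold
  post[9:10, "G"] <- 0.6; post[9:10, "H"] <- 0.4
  # 2 H fish wrongly assigned to G
  post[11:12, "G"] <- 0.85; post[11:12, "H"] <- 0.15
  # 2 H fish correct
  post[13:14, "H"] <- 1
  rep_ <- score_assignments(post, truth, threshold = 0.70)
  g <- rep_$per_unit[rep_$per_unit$repunit == "G", ]
  expect_identical(g$n_assigned, 8L)  # 6 correct + 2 from elsewhere
  expect_equal(g$accuracy, 6 / 8)
  expect_equal(g$efficiency, 6 / 10)
  # perfect posteriors
  perf <- score_assignments(diag(2)[c(1, 2, 1), ] %>%
                              `colnames<-`(units), c("G", "H", "G"))
  expect_equal(perf$overall$accuracy, 1)
  expect_equal(perf$overall$retained, 1)
  # nothing above threshold
  none <- score_assignments(matrix(0.5, 3, 2, dimnames = list(NULL, units)),
                            rep("G", 3), threshold = 0.70)
  expect_equal(none$overall$retained, 0)
  expect_true(all(is.na(none$per_unit$accuracy)))
})

test_that("raising the threshold never increases the retained fraction", {
  set.seed(5)
  post <- gsimix:::softmax_rows(matrix(rnorm(200 * 4, sd = 2), 200, 4,
                                       dimnames = list(NULL, LETTERS[1:4])))
  truth <- sample(LETTERS[1:4], 200, TRUE)
  retained <- vapply(seq(0.05, 1, by = 0.05), function(th)
    score_assignments(post, truth, th)$overall$retained, numeric(1))
  expect_true(all(diff(retained) <= 1e-12))
})

test_that("100% simulations are exact on a disjoint-allele baseline", {
  base <- disjoint_baseline(n_coll = 4, n_loci = 4, n_per = 12,
                            repunit = rep(c("U1", "U2"), each = 24))
  # prior mass: est for the true unit is ~(n + 2)/(n + 4), so n = 100
  # comfortably clears 0.95
  des <- sim_design("pct100", n_sims = 2, mixture_size = 100, seed = 21)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 200, n_boot = 0, seed = 22)
  out <- run_100pct(base, des, cfg)
  expect_true(all(out$mixture_props$est_prop > 0.95))
  expect_equal(out$individual_report$overall$accuracy, 1)
  expect_equal(out$individual_report$overall$efficiency, 1)
})

test_that("equal-proportion mixtures are unbiased on separable baselines", {
  base <- disjoint_baseline(n_coll = 4, n_loci = 3, n_per = 12)
  des <- sim_design("equal", n_sims = 3, mixture_size = 25, seed = 31)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 200, n_boot = 0, seed = 32)
  out <- run_equal(base, des, cfg)
  expect_equal(nrow(out), 12L)  # 3 sims x 4 units
  sums <- tapply(out$estimate, out$sim, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(abs(out$estimate - 0.25) < 0.03))
})

test_that("Dirichlet mixtures return coherent truth and track it", {
  base <- disjoint_baseline(n_coll = 3, n_loci = 3, n_per = 12)
  des <- sim_design("dirichlet", n_sims = 4, mixture_size = 40, alpha = 1.5,
                    seed = 41)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 200, n_boot = 10, seed = 42)
  out <- run_dirichlet(base, des, cfg)
  tsum <- tapply(out$truth, out$sim, sum)
  expect_true(all(abs(tsum - 1) < 1e-9))
  esum <- tapply(out$estimate_corrected, out$sim, sum)
  expect_true(all(abs(esum - 1) < 1e-6))
  # separable baseline: estimates track multinomial truth closely
  expect_lt(mean(abs(out$estimate - out$truth)), 0.08)
})

test_that("simulation designs are deterministic given their seeds", {
  base <- disjoint_baseline(n_coll = 3, n_loci = 3, n_per = 10)
  des <- sim_design("equal", n_sims = 2, mixture_size = 15, seed = 7)
  cfg <- mcmc_config(n_iter = 800, burn_in = 100, n_boot = 0, seed = 8)
  expect_identical(run_equal(base, des, cfg), run_equal(base, des, cfg))
})

test_that("design constructor applies the standard study sizes", {
  expect_identical(sim_design("pct100")$n_sims, 50L)
  expect_identical(sim_design("pct100")$mixture_size, 100L)
  expect_identical(sim_design("equal")$n_sims, 20L)
  expect_identical(sim_design("equal")$mixture_size, 500L)
  d <- sim_design("dirichlet")
  expect_identical(c(d$n_sims, d$mixture_size), c(100L, 500L))
  expect_equal(d$alpha, 1.5)
  expect_error(sim_design("dirichlet", alpha = 0), "alpha")
})
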