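test_that("duplicate discordance arithmetic matches the worked example", {
  # 56 pairs fully co-typed at 101 loci with 16 discordant allele calls in
  # total -> 16 / (2 * 101 * 56) = 0.00141... ~ 0.14%
  L <- 101; P <- 56
  calls <- stats::setNames(
    lapply(seq_len(L), function(j) rep("100/103", 2 * P)),
    sprintf("L%03d", seq_len(L)))
  tbl <- toy_geno(calls, indiv = c(sprintf("orig_%02d", 1:P), sprintf("dup_%02d", 1:P)))
  # plant 16 single-allele discordances in the duplicates, at most 4 per
  # locus (4 + 4 + 4 + 4 across four loci)
  planted <- list(L001 = 1:4, L005 = 11:14, L050 = 21:24, L101 = 31:34)
  for (loc in names(planted)) {
    for (p in planted[[loc]]) {
      tbl[[paste0(loc, ".1")]][P + p] <- "106"  # het 100/106 vs 100/103
    }
  }
  pairs <- tibble::tibble(indiv_a = sprintf("orig_%02d", 1:P),
                          indiv_b = sprintf("dup_%02d", 1:P))
  er <- genotyping_error_rate(tbl, pairs)
  expect_identical(er$n_discordant, 16L)
  expect_identical(er$n_cotyped, 101L * 56L)
  expect_equal(er$error_rate, 16 / (2 * 101 * 56))
  expect_equal(round(100 * er$error_rate, 2), 0.14)
  expect_identical(max(er$per_locus$n_discordant), 4L)
  # identical duplicates -> zero (orig_01/orig_02 share every genotype)
  clean <- genotyping_error_rate(tbl, tibble::tibble(indiv_a = "orig_01",
                                                     indiv_b = "orig_02"))
  expect_equal(clean$error_rate, 0)
})

test_that("error rate is invariant to pair order and member swaps", {
  tbl <- toy_geno(list(L1 = c("1/2", "1/3", "2/2", "2/3"),
                       L2 = c("5/5", "5/6", "5/6", "5/6")),
                  indiv = c("a1", "a2", "b1", "b2"))
  p1 <- tibble::tibble(indiv_a = c("a1", "b1"), indiv_b = c("a2", "b2"))
  p2 <- tibble::tibble(indiv_a = c("b2", "a2"), indiv_b = c("b1", "a1"))
  e1 <- genotyping_error_rate(tbl, p1)
  e2 <- genotyping_error_rate(tbl, p2)
  expect_equal(e1$error_rate, e2$error_rate)
  expect_identical(e1$n_discordant, e2$n_discordant)
  # het/hom mismatch sharing one allele counts a single error
  tbl2 <- toy_geno(list(L1 = c("1/1", "1/2")), indiv = c("x", "y"))
  e3 <- genotyping_error_rate(tbl2, tibble::tibble(indiv_a = "x", indiv_b = "y"))
  expect_identical(e3$n_discordant, 1L)
})

test_that("injected error rate is recovered from generated duplicates", {
  cfg <- sim_config(n_pops = 4, n_loci = 60, n_per_pop = 40, fst_target = 0.05,
                    missing_rate = 0.01, error_rate = 0.002,
                    n_duplicates = 120, seed = 55)
  gb <- generate_baseline(cfg)
  er <- genotyping_error_rate(gb$baseline, gb$duplicate_pairs)
  n <- 2 * er$n_cotyped
  ci <- 0.002 + c(-3, 3) * sqrt(0.002 * 0.998 / n)
  expect_gte(er$error_rate, ci[1])
  expect_lte(er$error_rate, ci[2])
})

test_that("locus screening fires each criterion on targeted fixtures", {
  n <- 60
  set.seed(9)
  hwe_calls <- function(A) {
    g1 <- sample.int(A, n, TRUE); g2 <- sample.int(A, n, TRUE)
    paste0(100 + g1, "/", 100 + g2)
  }
  calls <- list(
    Clean = hwe_calls(6),
    Tri = hwe_calls(3),                                   # < 4 alleles
    Shallow = hwe_calls(5),                               # depth 150
    Nully = {g <- sample.int(6, n, TRUE); paste0(100 + g, "/", 100 + g)},  # all hom
    Patchy = replace(hwe_calls(5), 1:10, NA)              # 17% failed calls
  )
  depth <- matrix(900, n, 5, dimnames = list(NULL, names(calls)))
  depth[, "Shallow"] <- 150
  extra <- matrix(2L, n, 5, dimnames = list(NULL, names(calls)))
  extra[1:3, "Clean"] <- 3L  # pretend the raw caller saw 3 alleles; Clean -> multi_copy
  tbl <- toy_geno(calls)
  qc <- screen_loci(tbl, depth = depth, n_alleles_called = extra,
                    n_perm = 500, seed = 10)
  get <- function(l) qc[qc$locus == l, ]
  expect_true(get("Tri")$low_variability)
  expect_true(get("Shallow")$poor_amplification)
  expect_true(get("Nully")$null_alleles)        # all-homozygote: F_IS = 1
  expect_true(get("Patchy")$scoring_difficulty)
  expect_true(get("Clean")$multi_copy)
  expect_identical(get("Patchy")$status, "reject")
  # with benign inputs the clean locus passes
  qc2 <- screen_loci(tbl, depth = NULL, n_alleles_called = NULL,
                     n_perm = 500, seed = 10) |> suppressWarnings()
  expect_identical(qc2[qc2$locus == "Clean", ]$status, "pass")
})

test_that("relaxing thresholds never turns a pass into a reject", {
  set.seed(13)
  n <- 50
  g <- function(A) paste0(100 + sample.int(A, n, TRUE), "/", 100 + sample.int(A, n, TRUE))
  tbl <- toy_geno(list(A1 = g(4), A2 = g(8), A3 = replace(g(5), 1:4, NA)))
  depth <- matrix(250, n, 3, dimnames = list(NULL, c("A1", "A2", "A3")))
  strict <- screen_loci(tbl, depth, thresholds = list(min_alleles = 6,
                                                      min_depth = 300,
                                                      max_ambiguous_frac = 0.01),
                        n_perm = 300, seed = 2)
  relaxed <- screen_loci(tbl, depth, thresholds = list(min_alleles = 2,
                                                       min_depth = 100,
                                                       max_ambiguous_frac = 0.2),
                         n_perm = 300, seed = 2)
  passed_strict <- strict$locus[strict$status == "pass"]
  passed_relaxed <- relaxed$locus[relaxed$status == "pass"]
  expect_true(all(passed_strict %in% passed_relaxed))
  expect_gt(length(passed_relaxed), length(passed_strict))
})
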