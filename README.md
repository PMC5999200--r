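# gsimix

Genetic stock identification (GSI) from multiallelic microsatellite
baselines: given reference collections of genotyped individuals of known
river of origin, `gsimix` estimates which stocks a mixed sample — typically
a fishery catch — was drawn from, and quantifies how much the baseline can
be trusted to do so. It is aimed at fisheries and wildlife geneticists
running sequenced-microsatellite (or any multiallelic amplicon) panels over
dozens of weakly differentiated populations.

The package covers the full baseline-to-fishery workflow:

* **Genotype I/O** — wide CSV (`indiv,collection,repunit,Locus,Locus.1,...`)
  and 4-digit genepop; missing-data filtering (individuals with more than
  50% missing calls are dropped); dense allele indexing.
* **Panel QC** — the five standard locus-rejection criteria (null alleles,
  <4 alleles, depth out of range, >2 alleles per individual, unscorable
  calls) and duplicate-based genotyping-error estimation.
* **Baseline statistics** — observed/expected heterozygosity, Monte Carlo
  exact Hardy–Weinberg tests with Bonferroni correction, Weir–Cockerham
  F<sub>ST</sub>, Cavalli-Sforza–Edwards chord distances, neighbor-joining
  trees with locus-bootstrap support.
* **Reporting groups** — rule-based merge proposals from the tree, the
  mis-assignment matrix and sample sizes.
* **The mixture model** — a Bayesian conditional GSI mixture: baseline
  allele frequencies at their Dirichlet posterior means
  (&theta;<sub>cla</sub> = (x<sub>cla</sub> + &lambda;<sub>l</sub>) /
  (n<sub>cl</sub> + A<sub>l</sub>&lambda;<sub>l</sub>), &lambda;<sub>l</sub>
  = 1/A<sub>l</sub>), diploid HWE genotype likelihoods, a Gibbs sampler on
  (z, &pi;) with a flat Dirichlet prior on the mixing proportions &pi;,
  95% credible intervals, and parametric-bootstrap bias correction of the
  reporting-unit proportions. Leave-one-out handling for both real
  (self-assignment) and simulated fish.
* **Evaluation designs** — 100% simulations, equal-proportion mixtures and
  Dirichlet(1.5) "realistic" mixtures, scored by assignment accuracy
  (correct / assigned) and efficiency (correct / truly belonging) at a
  posterior threshold of 0.70.
* **Synthetic data** — a Balding–Nichols generator
  (population frequencies ~ Dirichlet(p<sub>anc</sub>(1−F)/F)) with
  missingness, per-allele miscalls and duplicate samples, so the whole
  pipeline is testable without any external data.

## Worked example

Simulate a six-river baseline falling into three regional reporting groups,
check it, and estimate a 200-fish mixture:

```r
library(gsimix)

cfg <- sim_config(n_pops = 6, n_loci = 48, n_per_pop = 50, fst_target = 0.05,
                  hierarchical_groups = list(n_groups = 3, fst_between = 0.08),
                  seed = 42)
gb <- generate_baseline(cfg)

build_allele_index(gb$baseline)
#> allele_index: 48 loci, 349 alleles (mean 7.3 per locus)

self_assign_loo(gb$baseline)
#> self_assign: 300 individuals, 6 collections, 3 reporting units
#> top-1 collection self-assignment rate: 1

mix <- generate_mixture(gb$true_freqs,
                        c(pop_01 = 0.35, pop_02 = 0.25, pop_03 = 0.2,
                          pop_04 = 0.1, pop_05 = 0.1, pop_06 = 0),
                        n = 200, seed = 7)
res <- fit_mixture(mix$mixture, gb$baseline,
                   mcmc_config(n_iter = 5000, burn_in = 500, n_boot = 50, seed = 8))
res <- bootstrap_correct(res)
mixing_proportions(res)
#> # A tibble: 3 × 5
#>   repunit pi_hat     lo    hi pi_corrected
#>   <chr>    <dbl>  <dbl> <dbl>        <dbl>
#> 1 group_1  0.553 0.484  0.620       0.569
#> 2 group_2  0.345 0.284  0.411       0.336
#> 3 group_3  0.102 0.0655 0.147       0.0949
```

The true regional composition is (0.60, 0.30, 0.10); `pi_hat` is the raw
posterior mean per reporting group with its 95% credible interval
(`lo`–`hi`), and `pi_corrected` the parametric-bootstrap bias-corrected
estimate. The gap between estimate and truth here reflects baseline
sampling noise (50 fish per river), not bias — widening the baseline
tightens it.

For real data, start from `read_genotypes()`, run
`filter_missing_individuals()`, then `baseline_summary()`,
`propose_merges()`/`apply_ru_map()`, and finally `estimate_fishery()`,
which writes tidy per-unit proportion and per-individual assignment tables.

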