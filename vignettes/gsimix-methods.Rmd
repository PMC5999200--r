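---
title: "Models and methods behind gsimix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gsimix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsimix)
```

`gsimix` estimates the population-of-origin composition of mixed samples
(e.g. a fishery catch) from multiallelic microsatellite baselines, and
provides the supporting machinery a baseline study needs: panel quality
control, baseline summary statistics, reporting-group construction, and
simulation-based evaluation of assignment accuracy. This vignette records
the models, the defaults, and the design decisions, in that order of
importance.

## The conditional mixture model

A baseline consists of `C` collections (river populations) genotyped at `L`
loci; collection `c` has observed allele counts `x[c,l,a]` out of `n[c,l]`
gene copies at locus `l`. Allele frequencies get independent Dirichlet
priors with per-allele mass `lambda_l`; we hold each collection's
frequencies at their posterior means,

    theta[c,l,a] = (x[c,l,a] + lambda_l) / (n[c,l] + A_l * lambda_l),

the empirical-Bayes "conditional" fit familiar from conditional GSI
software. The default `lambda_l = 1/A_l` places unit total prior mass on
each locus and guarantees that an allele seen only in the mixture has
non-zero frequency in every collection, so no genotype has likelihood zero.
The alternative full-Bayes treatment (resampling baseline frequencies
inside the MCMC) is deliberately out of scope: the conditional fit is the
default in the tools this package mirrors and makes the sampler's output
directly checkable against numerical integration.

A diploid genotype contributes the Hardy–Weinberg likelihood
`theta_a^2` (homozygote) or `2 theta_a theta_b` (heterozygote) per locus,
multiplied across loci; missing loci contribute a factor of 1, so a fish
with no data is equally likely everywhere.

Mixing proportions `pi` over collections get a flat Dirichlet prior
(`alpha = 1` per collection; `1/C` is exposed as an option). The Gibbs
sampler alternates the latent origin `z_i` of each mixture fish
(categorical, proportional to `pi_c * L_ic`) and `pi | z` (Dirichlet). Per-fish
posteriors are Rao-Blackwellized averages of `Pr(z_i = c | pi_t, y_i)` over
retained sweeps. Reporting-unit quantities are sums over member
collections; credible intervals are central (equal-tailed) 95% quantiles of
the retained reporting-unit trace. Defaults follow standard practice for
this model family: 20,000 sweeps, 1,000 burn-in (`mcmc_config()`). The
sampler is written in C++ but draws through R's RNG, so a single
`set.seed()`/`seed` argument makes every run reproducible.

One modelling consequence worth knowing: under a flat prior the posterior
mean of a proportion estimated from `n` fish cannot exceed roughly
`(n + 1)/(n + 2)`, so a mixture of 100% purity is estimated near 0.97 at
`n = 30` and near 0.99 only at `n >= 100`. Several tests size their
mixtures accordingly.

## Leave-one-out evaluation

Self-assignment scores each baseline fish against all collections after
removing its own two gene copies per non-missing locus from its home
collection's counts — without this, a fish is compared against a baseline
that contains it and accuracy is overstated. Simulated fish receive the
same treatment: `simulate_individual()` draws genotypes from a collection's
Dirichlet posterior predictive (sequential Pólya-urn draws on `x + lambda`),
and because the drawn copies are exactly the fish's genotype, the assigner
decrements those copies from the source collection when evaluating it.
Decremented counts floor at zero (relevant only when a predictive draw
produced an allele the collection had never shown; the prior keeps the
frequency positive).

## Parametric-bootstrap bias correction

Weakly separated baselines push mixture estimates toward the prior mean,
biasing skewed compositions toward uniformity. `bootstrap_correct()`
simulates `n_boot` (default 100) mixtures of the observed size from the
baseline at the fitted collection proportions, re-estimates each, and
subtracts the mean reporting-unit re-estimation bias from the raw
estimate. Corrected values can go slightly negative; they are clamped at
zero and renormalized to sum to one — a documented deviation point from
implementations that re-project differently. On a deliberately
weakly-separated two-unit scenario (F_ST 0.01, 12 loci, truth 0.9/0.1,
mixtures of 200) the correction removes most of a raw bias of roughly
−0.13; the acceptance suite checks this property, not a specific number.

## Simulation designs and scoring

Three evaluation regimes are provided, with defaults matching the standard
study design: 100% simulations (50 mixtures of 100 fish per reporting
unit), equal-proportion mixtures (20 replicates, 500 fish per unit), and
"realistic" mixtures with truths drawn from a symmetric Dirichlet(1.5)
(100 replicates of 500 fish, estimated with bootstrap correction). Within a
multi-collection reporting unit, simulated fish draw their source
collection uniformly; the data rarely say anything about relative
within-unit abundance, so the package does not guess it (a
size-proportional option would be a one-line change in `run_100pct()`'s
origin sampling and is intentionally not a default).

Individual assignments are scored at a posterior threshold (default 0.70):
a fish is assigned to its top reporting unit only if that posterior
reaches the threshold. Per unit, *accuracy* is correctly-assigned /
total-assigned-to-unit and *efficiency* is correctly-assigned /
truly-belonging; units with nothing assigned get `NA` accuracy rather than
zero. The threshold applies at the reporting-unit level — the level at
which results are reported and management decisions are made; collection-
level posteriors remain available in every result object. For 100%
simulations both views are emitted separately (per-simulation estimated
proportion credited to the true unit, and pooled individual-level
accuracy/efficiency), because the two are often conflated in prose and
they answer different questions.

## Baseline statistics

* **Heterozygosity.** `H_O` is the fraction of heterozygous calls; `H_E`
  is Nei's unbiased estimator `(2n/(2n-1))(1 - sum p^2)` per
  collection-locus cell.
* **Hardy–Weinberg tests.** A Monte Carlo exact test: gene copies are
  permuted among a cell's individuals and re-paired; configurations are
  ordered by their conditional probability given the allele counts. The
  permutation route was chosen over asymptotic chi-square because
  multiallelic microsatellite cells have many sparse genotype classes. A
  one-sided heterozygote-deficit variant backs the null-allele screen.
  Monomorphic cells are untestable and excluded from the Bonferroni
  denominator (`alpha / #testable`).
* **F_ST.** Weir & Cockerham's (1984) multiallelic theta; multi-locus
  estimates are ratios of summed variance components (not means of
  ratios). Negative estimates are reported as computed — clamping is a
  display decision, not an estimation one.
* **Chord distance.** `d(i,j) = sqrt(mean_l (1 - sum_a sqrt(p_i p_j)))`.
  Several normalizations of the Cavalli-Sforza–Edwards distance circulate
  (with/without the 2/pi factor, per-locus vs pooled); this is the
  PHYLIP/gendist squared-chord average, chosen because only the tree
  *topology* is consumed downstream and this form is the most widely
  reproduced. Users comparing against another convention should expect a
  monotone transformation, not different trees.
* **NJ tree.** Saitou–Nei neighbor-joining via **ape**; bootstrap
  support resamples *loci* with replacement (the exchangeable unit in a
  panel), recomputes the chord distance and counts bipartitions; supports
  below 50% are omitted from the printed labels.

## Reporting-group construction

Real studies lump collections into reporting units by judgment, informed
by the tree, the mis-assignment structure, and geography. `propose_merges()`
encodes the reproducible part as an explicit rule set: small samples
(`n < 30`) join their nearest tree neighbor; collection pairs with mutual
top-assignment confusion at or above 0.20 in both directions are unioned;
unions close transitively. The 0.20 default flags pairs whose confusion is
far beyond what sampling noise produces on separable synthetic baselines
while ignoring incidental one-directional leakage. The output is decision
support — evidence is attached to every proposed union and the user applies
or rejects it via `apply_ru_map()`, which rewrites only the
collection-to-unit map, never the genotypes. Geographic adjacency is
accepted only as user input, never inferred.

## Panel quality control

Five rejection criteria screen candidate loci. Two of them —
"presence of null alleles" and "difficulty scoring" — are judgment calls
in the field; a reproducible filter needs formulas, so the package uses
explicit proxies with tunable thresholds: null alleles are flagged when
`F_IS > 0.2` together with a one-sided heterozygote-deficit exact-test
p-value below 0.05, and scoring difficulty when the ambiguous/failed call
fraction exceeds 0.05. The mechanical criteria are fewer than 4 distinct
alleles; mean read depth per sample below 200 or above 10,000 (mean was
chosen where "per sample" is ambiguous — median and minimum behave
similarly on clean data and the threshold is user-settable); and any
individual carrying more than two called alleles (duplicated genomic
region).

Duplicate-based genotyping error compares replicate pairs locus by locus,
matching genotypes as multisets (a het/hom pair sharing one allele is one
discordant call, not two); the rate divides discordant calls by
`2 x co-typed loci` — the per-allele-call denominator that treats each
discordance as one erroneous call.

## The synthetic generator

`generate_baseline()` draws ancestral allele frequencies per locus from a
symmetric Dirichlet over `A_l` alleles (`A_l = 2 + Poisson(mean - 2)`) and
population frequencies from the Balding–Nichols model,
`Dirichlet(p_anc (1-F)/F)`, optionally through an intermediate regional
level. Defaults emulate the kind of baseline the package targets — a large
sequenced-microsatellite panel over many weakly differentiated river
populations: 35 populations, 101 loci, 8.4 alleles per locus, `F = 0.051` (realized mean
pairwise theta lands close to `F`), 45 individuals per population, 0.14%
per-allele miscall rate (a miscall becomes a uniformly chosen different
allele — the simplest model consistent with the duplicate-discordance
estimator), and a 2% background missing-call rate (the study reports only
its >50%-missing exclusion rule, so a low nuisance rate was fixed once as
typical of amplicon microsatellite panels).

Duplicate samples are re-reads of the same true genotype. By default they
are error-free control reads, so the duplicate-discordance estimator's
expectation equals the configured per-call error rate; with
`duplicate_error = "both"`, both reads carry independent errors and the
estimator targets the *combined* error of the two runs (about twice the
per-run rate). The default keeps the estimator interpretable; the option
models the fully symmetric reality.

What the generator does **not** emulate: stutter and length-dependent
amplification bias, linkage between loci, family structure within
collections, and temporal allele-frequency drift between sampling years.
Tests passing on this generator therefore demonstrate correctness of the
estimators under their own assumptions, not robustness to these real-data
features.

## Numerical and testing choices

* Grid integration over a 2001-point grid on `pi` is the independent
  oracle for two-collection mixtures; Gibbs means are required to agree
  within three batch-means Monte Carlo standard errors.
* Leave-one-out posteriors are required to *exactly* match a manual
  "delete the fish and refit" computation on small baselines.
* The test and acceptance suites run the MCMC at reduced sizes (typically
  2,000 sweeps, 200 burn-in, 30–80 bootstrap iterations, 8–20 replicates)
  — sizes chosen so each property's Monte Carlo noise is well below its
  tolerance; `mcmc_config()` defaults remain the full 20,000/1,000/100.
* NJ ties and categorical sampling ties break deterministically (lowest
  index), so fixed seeds give bit-identical outputs end to end.

## Known limitations

The likelihood ignores genotyping error (at 0.14% per allele its effect on
posteriors is negligible relative to sampling noise, but panels with
percent-level error would need an error-aware emission model). Reporting
units are flat labels — there is no hierarchical prior sharing information
across units. And the conditional fit understates baseline-frequency
uncertainty for very small collections; the bootstrap correction
compensates at the point-estimate level but credible intervals remain
conditional on the baseline.
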