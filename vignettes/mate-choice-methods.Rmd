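---
title: "Testing genetic mate choice in group-housed breeding programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing genetic mate choice in group-housed breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matechoice)
```

## The problem

Conservation breeding programs increasingly house animals in groups rather
than forced one-to-one pairings, partly on the argument that free mate
choice improves reproduction and retains natural behaviors. Whether
*genetic* mate choice actually operates in such settings matters for
management: heterozygosity-based or dissimilarity-based preferences can
amplify reproductive skew, shrink effective population size, and shift
allele frequencies away from the founders. `matechoice` implements an
observational analysis of this question for populations housed in discrete
enclosures over multiple breeding seasons, where the enclosure-year defines
a closed competitive mating arena. Three non-mutually-exclusive hypotheses
are examined:

1. **Advantage of heterozygous individuals** — animals more heterozygous
   than their same-sex competitors in the enclosure breed more often.
   Tested by regression with within-group relative predictors.
2. **Advantage of dissimilar mates** — successful pairs are more
   genetically dissimilar than random opposite-sex pairs. Tested against a
   randomization null on the *mean* pair similarity.
3. **Optimum genetic distance** — successful pairs converge on an
   intermediate dissimilarity, balancing inbreeding against outbreeding.
   Tested against the same null on the *SD* of pair similarity.

Both a large genome-wide biallelic SNP panel and a small multi-allelic
panel (MHC-linked microsatellites) are supported; every statistic is
computed separately per panel, never mixed.

## Individual diversity: standardized multilocus heterozygosity

For individual $i$, `smlh()` computes

$$H_i = \frac{h_i}{\sum_{l \in \mathrm{typed}(i)} \bar H_l},$$

the count of heterozygous loci divided by the sum of mean observed
heterozygosities of exactly the loci at which $i$ was genotyped. Restricting
the denominator to the typed loci makes $H_i$ robust to missing data; with
complete data $\sum_i h_i / N = \sum_l \bar H_l$, so the population mean of
$H_i$ is exactly 1 — an identity the test suite asserts to $10^{-12}$.
$\bar H_l$ is always computed over the full loaded panel, not per
enclosure, since the metric is meant to rank individuals on a common scale.
Individuals with a zero denominator (no typed loci, or only loci that are
monomorphic for heterozygosity) get `NA` and are excluded downstream.
Half-calls (one known allele) are treated as missing throughout the
package: partial genotypes carry no information for either statistic.

## Pair similarity: the allele-sharing statistic

`pair_similarity()` computes the band-sharing-style similarity

$$D_{AB} = \frac{2\,F_{AB}}{F_A + F_B},$$

where, over loci typed in both individuals, $F_A$ and $F_B$ count the
*distinct* alleles carried by each individual (1 for a homozygous locus, 2
for a heterozygous one) and $F_{AB}$ counts the distinct alleles they
share. Set semantics are applied consistently to all three sums: this is
what guarantees $0 \le D_{AB} \le 1$, with 1 exactly when the allele sets
are identical at every shared locus and 0 when nothing is shared. The three
sums are accumulated across loci before the ratio is formed (one global
ratio per pair); averaging per-locus ratios instead would weight loci
unequally under missingness. A configurable `min_shared_loci` threshold
(default 1) controls when a pair's similarity counts as defined.

## The structured randomization null

Within one enclosure-year with $k$ observed successful pairs,
`simulate_null()` draws $k$ pairs uniformly *without replacement from the
set of all possible opposite-sex pairs* and records the mean (or SD) of
their similarities, repeating 100,000 times by default. Individuals may
recur across the drawn pairs, mirroring the polygamy seen in group housing
(males breeding with several females and vice versa). The 95% interval is
the 2.5/97.5 percentile of the draws — a percentile interval, not a normal
approximation, which is why the simulated minimum/maximum are reported
separately. `enumerate_null_exact()` produces the same distribution by
exhaustive enumeration of all $\binom{n}{k}$ subsets (capped at $10^6$
combinations) and serves as the oracle for the Monte-Carlo machinery.

Exactly how a random-mating simulation should treat individual reuse is
genuinely open: uniform-over-pairs is the minimal scheme consistent with
observed polygamy, and is the default (`null_mode = "uniform_pairs"`). A
stricter alternative, `null_mode = "match_degrees"`, rejection-samples
draws until the drawn pairing graph reproduces the observed per-sex degree
counts. Neither is asserted to be the uniquely correct null; both are
provided and tested.

The pooled test (`mc_test_pooled()`) accounts for the stratification:
each draw independently samples $k_e$ pairs within every enclosure-year
$e$, concatenates the similarity values, and computes the pooled
statistic. Per-stratum RNG streams are derived deterministically from the
master seed and the stratum id (`derive_seed()`), so results are invariant
to stratum processing order, and a pooled test over a single stratum
reproduces the per-enclosure test exactly.

Outcomes are categorical (`below_ci` / `within_ci` / `above_ci`) because
the hypotheses are directional predictions about the CI. The lower-tail
empirical p-value is reported as $(1 + \#\{t^* \le t_{obs}\})/(1 + n_{sims})$,
which cannot be exactly zero. Enclosure-years with a single successful
pair are excluded from the per-enclosure SD test (no SD exists), but their
single similarity value still contributes to the pooled statistic.

## Breeding-success regressions and model averaging

Breeding success (0/1) and offspring counts are modeled per sex with up to
four predictors: age, average weight, genome-wide heterozygosity and
MHC heterozygosity. Response families follow the biology: binomial for
success; Poisson for male offspring counts; and successes-out-of-4
binomial for female counts, since litters are capped at four. Random
intercepts (individual id for males, enclosure-year for females) are
fitted by adaptive Gauss–Hermite quadrature with 15 nodes via `lme4`,
falling back to the Laplace approximation when the quadrature fit fails;
the pipeline degrades further to a fixed-effects fit (with a message)
rather than aborting, because small simulated datasets often have
near-zero group variance.

Predictors are standardized by two sample standard deviations
(`standardize_2sd()`), putting continuous and binary effects on a
comparable scale. For the heterozygote-advantage hypothesis, predictors
are instead re-expressed *within enclosure-year × sex* as
$(x - \bar x_g)/(2 s_g)$ (`standardize_within_group()`), so a coefficient
measures the effect of standing relative to one's direct competitors; a
predictor constant within a group carries no relative information and is
set to 0 there with a warning.

`model_average()` fits all $2^p$ predictor subsets ($p \le 4$, so at most
16 fits — no heuristic search), ranks them by
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ (with $k$ counting intercept,
slopes and any random-intercept variance), keeps models within 2 AICc of
the best (configurable), renormalizes their Akaike weights, and averages
with zero substitution ("full average") by default; conditional averaging
is available behind a flag. Unconditional standard errors use
$\sqrt{\sum_m w_m (\mathrm{var}_m + (\hat\beta_m - \bar\beta)^2)}$.

Two importance summaries are reported because the field uses the same
name for both: `ri`, the sum of renormalized Akaike weights of top-set
models containing the predictor (the conventional measure, on which values
such as 0.2 between 0 and 1 arise naturally), and `ri_prop`, the raw
proportion of top-set models containing it. They coincide at 1 for a
predictor in every top model — the only case in which
`predict.averaged_model()` back-transforms without flagging the predictor
as averaged over inclusion uncertainty. No multiple-testing correction is
applied anywhere; the tests are a small fixed family of directional
predictions, reported individually.

## What the synthetic generator emulates

`sim_config()` defaults encode the target study conditions: 2 enclosures
followed for 5 seasons, 20 adults per enclosure-year (≤ 21, near-even sex
ratio), ages 2–5, 1,948 SNPs with minor-allele frequencies uniform on
[0.05, 0.5] (mirroring a MAF > 5% marker filter) plus 12 microsatellites
with 2–10 Dirichlet-frequency alleles, Hardy–Weinberg genotypes, 2%
missing calls, and a baseline female success probability of 0.4
(`alpha = qlogis(0.4)`), reproducing the ~60% failure rate characteristic
of group-housed devils. Remaining defaults are the package's own choices
of realistic values, fixed once: individuals carry over between seasons
with probability 0.5 (ageing, retiring after age 5 or three appearances),
female weights ~ N(7.5, 0.8) kg and male weights ~ N(9.5, 1.0) kg, and
litter sizes 1–4 with probabilities (0.20, 0.35, 0.30, 0.15) (mean ≈ 2.4).
Mate choice is modeled as female choice over the enclosure's males — a
modeling convention, not a biological claim, as the analysis itself is
direction-agnostic.

Mechanisms: under `dissimilarity_preference` a successful female picks
male $m$ with weight $\propto \exp(\beta_{dis}(1 - D_{fm}))$; under
`optimum_distance`, $\propto \exp(-(D_{fm} - D_{opt})^2 / 2\sigma^2)$;
under `het_advantage` her own success probability gains
$\beta_{het}$ per 2-SD of genome-wide heterozygosity. Effect sizes are
stored on the 2-SD standardized scale the models estimate on, so recovery
tests compare like with like. Because genome-wide $D_{AB}$ values within
an enclosure are tightly clustered (typical spread only a few hundredths),
$\beta_{dis}$ must be large in absolute terms to produce a visible
preference: pilot simulation placed a moderate preference at
$\beta_{dis} = 30$ and a strong one at $\beta_{dis} = 100$, at which the
pooled dissimilar-mates test exceeds 80% power at the reduced test scale.

What the generator does **not** emulate: linkage disequilibrium among
SNPs, mutation or genotyping-error processes, pedigree structure across
generations (all individuals are unrelated founders), seasonal covariates,
and male-side success heterogeneity beyond what pairing induces. Passing
tests therefore demonstrate the *statistical machinery* — calibration,
power, recovery, determinism — under idealized genetics, not that real
data meet these assumptions. In particular, relatedness among real
enclosure-mates would raise similarity variance and could change the power
of both randomization tests.

## Numerical and reproducibility choices

* All randomized stages take a mandatory seed. Sub-streams are derived as
  a 31-bit polynomial hash of the master seed and a stage/stratum label,
  which keeps every derived seed a valid 32-bit integer and makes results
  independent of processing order.
* The percentile CI uses `quantile()` type 7 on the draw vector for both
  Monte-Carlo and exact distributions.
* GLM convergence relies on `stats::glm` defaults (IRLS, relative deviance
  tolerance 1e-8); coefficients beyond ±15 on the standardized scale
  trigger a complete-separation warning. Candidate models that fail to fit
  are excluded from averaging with a warning; the best model always
  remains.
* Test problem sizes are deliberately modest so the whole suite runs in
  minutes: the calibration study uses 1,000 replicate studies of 4
  enclosure-years (8F × 8M, 200 SNPs) with 2,000 draws per null; power
  uses 100 replicates per preference strength; effect-size recovery uses
  200 replicates of ~400 females. Monte-Carlo/exact agreement is asserted
  within 3 Monte-Carlo standard errors.

## Known limitations

* The female offspring-count model treats the 4-offspring cap as a
  binomial denominator, which is exact only if all four pouch positions
  are independent trials.
* Conditional $R^2$ for averaged mixed models is not computed; the
  variance decomposition for averaged models is not settled enough to
  implement without guessing.
* Repeated males across years are pooled in the male offspring-count
  model (too few repeats to support a random intercept there).
* The similarity statistic is not a kinship estimator; no
  pedigree-based or likelihood relatedness measures are provided.
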