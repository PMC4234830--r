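---
title: "Modelling transitions from outcrossing to selfing in trioecious populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transitions from outcrossing to selfing in trioecious populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioecy)
```

## The biological setting

`trioecy` models experimental populations of *Caenorhabditis elegans*-like
nematodes in which three sexes transiently coexist: XO males, XX females, and
XX self-compatible hermaphrodites.  Sex among XX animals is controlled by the
*fog-2* locus: the recessive *q71* allele abolishes hermaphrodite self-sperm,
so XX *q71/q71* homozygotes are functional females, while XX carriers of at
least one wild-type allele are hermaphrodites.  The wild-type allele is
therefore the "selfing allele": tracking its frequency tracks the transition
from a male–female (dioecious) mating system to partial or complete
self-fertilization.  Hermaphrodites cannot mate one another, so every
outcross event involves a male.

Three quantities organize the theory:

* **α (outcross fitness)** — a compound parameter for all fitness components
  expressed under outcrossing relative to selfing: male mating success,
  fertilisation, and the success of outcrossed broods.  It scales the number
  of matings per generation.
* **the cost of males** — outcrossed broods are half male, and males cannot
  reproduce alone, so outcrossing carries an intrinsic two-fold transmission
  disadvantage.
* **selfed brood weight B = 2β(1−δ)** — the relative contribution of a
  selfing hermaphrodite's brood, where β is the probability that a
  non-outcrossed hermaphrodite self-fertilises (brood level; no mixed
  broods) and δ is inbreeding depression.  With the defaults β = 1, δ = 0,
  B = 2.

Males persist alongside hermaphrodites (androdioecy) only when outcross
fitness beats the selfed brood weight: `alpha * (1 - sigma) > 2 * beta *
(1 - delta)`, i.e. α > 2 under the defaults
(`androdioecy_maintenance_condition()`).  The same threshold re-emerges
dynamically as the point where the per-generation growth factor of a rare
male lineage, α/B, crosses 1 (`rare_male_growth_factor()`).

## The life-cycle algorithm

Both engines — the stochastic individual-based simulator
(`advance_generation()`, `run_trajectory()`) and its infinite-population
limit (`deterministic_trioecy_trajectory()`) — implement the same
one-generation algorithm at fixed census size N:

1. `K = min(round(alpha * m * N), #XX)` mating pairs form: K XX individuals
   (hermaphrodites or females, indiscriminately) are drawn uniformly without
   replacement, each paired with a male drawn uniformly *with* replacement.
2. Unmated hermaphrodites become selfing pseudo-pairs with probability β;
   unmated females do not reproduce.  This asymmetry is the engine of
   reproductive assurance: when matings are scarce, hermaphrodite-producing
   genotypes keep reproducing while female-producing genotypes do not.
3. N offspring are drawn by sampling pairs and pseudo-pairs uniformly with
   replacement (pseudo-pairs down-weighted by 1−δ), with genotypes from
   Mendelian segregation.  Offspring of true pairs are male with
   probability 1/2; offspring of pseudo-pairs are XX; XX sex follows the
   *fog-2* genotype.

The stochastic engine operates on class counts (six admissible
sex-by-genotype classes) with multivariate hypergeometric and multinomial
draws.  This is distributionally exact — mating, selfing, and offspring
sampling are exchangeable within a class — and makes the per-generation cost
independent of N.

### The mating-quota male frequency

The quota `alpha * m * N` needs a male frequency `m`.  Two conventions are
implemented, and the distinction matters:

* **realized** (`quota_male_freq = NULL`): `m` is re-read from the current
  state every generation.  This is the natural free-running model, but it
  has a strong attractor: whenever hermaphrodites are rare and α > 1, the
  quota exceeds the XX pool, every XX is mated, selfing ceases entirely, and
  the population is pinned at an even sex ratio with the selfing allele
  frozen.  In that regime all α above the pinning point produce identical
  dynamics, so α is unidentifiable there.
* **observed/fixed** (`quota_male_freq = <value>`, or
  `quota_refresh_every = <gens>`): the quota uses a male frequency assayed
  at a sampled generation and held fixed until the next assay.  This is the
  convention of the inference engine — male frequencies are only *known* at
  sampled time points — and of the synthetic trajectory generator, which
  refreshes the quota at each sampled generation.  Under this convention
  the period-end allele frequency responds smoothly to α over the whole
  grid, which is what makes likelihood inference on α possible.

The deterministic recursion accepts the same options, and the two engines
agree: the mean of replicate stochastic trajectories tracks the recursion
within Monte-Carlo error (this is asserted by the test suite at N = 10^4
with 200 replicates over 15 generations for α ∈ {1, 1.41, 1.76}).

Survivorship differences between males and hermaphrodites (σ) enter only
the closed-form maintenance condition; the life-cycle algorithm models
σ = 0, the empirically supported value in the system this package
addresses, and refuses other values rather than improvising semantics.

## Inference of α from allele-count time series

`grid_likelihood_search()` estimates α from *fog-2(wt)* allele counts
sampled over time, by simulation-based likelihood:

* The series of each replicate population is cut into **periods** between
  consecutive sampled generations.  Each period is simulated independently
  from its own observed starting frequencies (allele frequency from the
  genotyped sample, boundary-clamped; male frequency from the male-count
  assay when present, else propagated deterministically).  Periods are
  conditional on the data at their start, so inference does not require the
  model to reproduce an entire multi-decade trajectory in one run.
* For each period, `n_reps` (default 20) replicate simulations give a mean
  final allele frequency; the observed end-of-period allele count is scored
  against it with a binomial log-likelihood.  The mean — not the
  per-replicate distribution — parameterises the binomial, which is the
  cruder but conventional choice for this assay; the richer mixture
  likelihood is deliberately not the default.
* Log-likelihoods are summed across periods and populations; the grid
  default is 51 points on [0, 2] (spacing 0.04), and the maximum is the ML
  estimate (ties break to the lowest α and are flagged, as is a maximum at
  a grid boundary).
* The credible interval is the contiguous grid range around the ML where
  `2 * (lnL_ML - lnL) <= ci_drop`.  The drop defaults to 3.84 (the 95%
  χ²₁ quantile), the standard likelihood-interval convention; it is exposed
  as a parameter because the convention is not uniquely determined by the
  assay design.
* Period sub-seeds are derived from the period's *content*, not its
  position or the α being scored.  Two consequences: identical periods share
  simulations, making the compound likelihood a pure sum; and all grid
  points reuse the same replicate streams (common random numbers), which
  removes Monte-Carlo jitter from the argmax without changing the estimand.

### Boundary clamping and detection power

With 48 genotyped individuals (96 alleles), an undetected allele is
compatible with a true frequency up to a few percent.  Two conventions make
the downstream log-ratios finite and conservative: `clamp_frequency()` maps
a count of 0 out of n alleles to `1/(n+1)` and a count of n to `n/(n+1)`
(so 1/97 and 96/97 at the standard sample size), and `detection_power()`
gives the probability `1 - (1-p)^(2n)` of seeing at least one copy — 0.82
for a 2% allele at the realised mean sample size of 42.7 individuals.
Non-integer sample sizes are accepted precisely so that a realised mean can
be used directly.

## Fitness estimators

**Transition fitness** (`transition_fitness()`): the OLS slope of
`ln(p_wt / p_q71)` on generation, pooling replicate populations under one
slope (shared intercept by default, matching the pooled regression
convention; per-population intercepts optional).  Frequencies are clamped
before the logit.  The estimator is essentially unbiased when the sampled
time points lie inside the transition window; once observations saturate at
fixation the clamp compresses the response and the slope is attenuated —
the price of keeping log-ratios finite.

**Competitive fitness** (`competition_fitness()`): one generation of
head-to-head competition against a GFP-marked tester is scored at the L1
stage by GFP presence/absence.  The transgene is dominant for scoring, so
marker heterozygotes produced by cross-competitor outcrossing are invisible
among the GFP-positive larvae.  `gfp_phenotype_to_allele_counts()`
reconstructs expected allele counts under random mating and selfing with no
sex-ratio segregation distortion: each competitor's progeny is outcrossed
in proportion twice its male frequency, sire origin among outcross events
is proportional to male supply (adult frequency × male frequency), and
cross-origin progeny are heterozygous.  The heterozygote share θ among
positives is evaluated at an adult-frequency estimate initialized from the
final phenotype frequencies and iterated to a fixed point (tolerance 1e-10,
at most 100 iterations; non-convergence is an error, not a silent result).
The equations themselves are a reconstruction — the original assay's
correction script is not published — so the implementation is pinned by an
independent mating-class enumeration oracle in the test suite, to 1e-8.
Fitness is then `w = ln(p_wt.t1/p_GFP.t1) - ln(p_wt.t0/p_GFP.t0)`;
`block_center_and_delta()` subtracts the per-block mean of a reference
population assayed in every block (w_t), and optionally ancestral means by
reproduction system (Δw_t).  Records whose setup deviates from the intended
50:50 mix by more than 0.15 are flagged but not silently dropped.

**Male fitness** (`male_fitness()`): with wild-type and GFP tester males
competing for *fog-2* females and a fixed 50:50 setup,
`w_m = logit(p_t1)` where `p_t1` is the non-GFP progeny fraction.  Plates
with fewer than six females transferred or fewer than twenty progeny scored
are discarded (`qc_filter_male_plates()`); fertility observations with
fewer than five progeny, or under 10% male progeny in the outcross
treatment, likewise (`qc_filter_fertility()`).  Both filters report
per-rule rejection tallies and are idempotent.

## SNP diversity statistics

`homozygosity()` returns 1 − Ho, one minus the mean per-locus heterozygote
proportion among non-missing calls — the statistic that rises toward 1
under sustained selfing (equilibrium inbreeding F = S/(2−S) at selfing
rate S).  `composite_ld_mean_r2()` computes pairwise linkage
disequilibrium from unphased genotypes as the squared composite (Burrows)
correlation.  Because partial selfing violates Hardy–Weinberg, the
normalizer includes the within-locus disequilibria
`D_A = freq(hom_ref) - p_A^2`:

```
Delta = mean(X * Y)/2 - 2 p_A p_B
r     = Delta / sqrt((p_A q_A + D_A)(p_B q_B + D_B))
```

Pairs use pairwise-complete individuals; r² is clipped to [0, 1] and
averaged over all pairs (the per-pair table is kept so other summaries can
be formed).  Loci with minor allele frequency strictly below 0.05 are
removed first (`maf_filter()`); when fewer than two loci survive, the LD
statistic is reported as absent rather than 0 — the realistic outcome for
populations driven nearly monomorphic by selfing.  Raw matrices are cleaned
in three ordered stages (`clean_snp_matrix()`): loci >80% missing, then
individuals >60% missing, then loci >50% missing.

`diversity_fitness_ancova()` tests whether per-population fitness responses
are explained by a diversity covariate: sequential (Type I) least squares
with the covariate entered first, then the reproduction system as a 3-level
factor, F against the residual mean square (residual d.f. n − 4).
Sequential sums of squares are used because the analysis reports one SS per
term in that order.

## Synthetic data: what it emulates, and what it does not

The deposited assay tables are not bundled; `gen_trajectory_dataset()`,
`gen_competition_dataset()`, `gen_snp_dataset()` and
`gen_male_fitness_dataset()` generate structurally faithful tables with
known ground truth (each with a JSON truth sidecar, and bit-reproducible
under a fixed seed).  Default sampling depths mirror the assays: 48
genotyped and 300 sexed individuals per time point, 3 replicate
populations, 12 competition blocks with 4–6 replicates and ~1230 scored
larvae, ~17 females per mating plate, 58 SNPs.

Two generator choices deserve explanation:

* **Trajectory starting conditions.** The default start is a
  mid-transition trioecious population (selfing-allele frequency 0.1, male
  frequency 0.25, samples at generations 0/10/20/30).  The real experiment
  began with the selfing allele at 2.6 × 10⁻² — but in this model a
  rare-hermaphrodite population is uninformative about α above ~1 (the
  all-mated pin described earlier), and once the allele approaches
  fixation every trajectory saturates.  The mid-transition phase is the
  window in which 96-allele samples carry information about α across its
  whole [0, 2] range; real inference escapes the problem by conditioning
  each period on observed data, which a self-contained synthetic experiment
  cannot do from an uninformative regime.
* **Competition forward model.** Final phenotype counts are drawn from the
  same mating-class model the correction inverts, at allele frequencies
  implied by the record's true fitness plus a shared Gaussian block effect
  on the log allele ratio (sd 0.25, reflecting the strong block
  heterogeneity such assays show).  With equal competitor male frequencies
  the correction is exactly consistent with the generator, so recovery
  error is pure sampling noise.

What passing recovery tests on these data do **not** show: robustness to
model misspecification (real populations violate the no-mixed-broods and
no-distortion assumptions to unknown degrees), to non-equilibrium LD
structure (the SNP generator uses contiguous blocks with a latent-variable
copula, not a recombination map), or to assay artefacts beyond the modelled
missingness and QC violations.

## Numerical choices and problem sizes

* Mating-quota rounding: round-half-to-even, then capped at the XX count.
* Largest-remainder rounding for initial Hardy–Weinberg class counts, ties
  to the lower class index; a census too small to represent the selfing
  allele (or males) at its nominal frequency is a warning, never silent.
* Extinction (no reproducing pairs) truncates trajectories with an explicit
  flag; downstream statistics drop extinct replicates with a warning and
  fail only when all replicates are lost.
* Seeds: every source of randomness flows from a caller-supplied seed
  through `derive_seed()` (a linear-congruential fold, modulus 2³¹ − 1), so
  any replicate, period or grid point can be reproduced in isolation.
* Test-suite problem sizes: parameter recovery uses 20 datasets per true
  α ∈ {0.8, 1.2, 1.6} at N = 2000 with 20 likelihood replicates;
  stochastic/deterministic agreement uses 200 replicates at N = 10⁴ over 15
  generations; transition-dynamics properties use 60 replicates at N = 10⁴
  over 50 generations.  These sizes put Monte-Carlo error well below the
  tolerances asserted while keeping the default suite comfortably
  runnable on a laptop.

## Known limitations

* σ (male survivorship) is supported only in the closed-form maintenance
  condition, not the simulators.
* The transition property — fixation of the selfing allele — holds for
  sudden-like outcross fitness (α ≲ 1.5 under the assay-cadence quota);
  at higher α the model maintains males at intermediate frequency for long
  periods, which matches the gradual-regime phenomenology but means "the
  selfing allele always fixes when α < 2" is not a theorem of this model.
* The GFP heterozygote correction is a reconstruction pinned by stated
  assumptions and an enumeration oracle, not by the original script.
* X-chromosome non-disjunction (spontaneous male production by selfing
  hermaphrodites) is not modelled: males arise only from outcrossing.
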