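---
title: "Models and methods in hostassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hostassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hostassoc)
```

`hostassoc` asks whether the population genetic structure of intimately
associated species (herbivores, parasites, pollinators, symbionts) tracks
the structure of their host plants after accounting for geography and
climate. This vignette documents the models, the numerical choices, the
synthetic-data generator, and the design decisions that were genuinely open
— in enough detail that a user can judge what a passing validation suite
does and does not establish.

## Data model

One *pair* is one host–associate study: both species sampled at the same
ordered list of at least four geographically distinct sites. Genotypes
arrive as per-site allele-copy counts (any ploidy, summed) in long-format
CSV; studies that published only genetic distances are ingested as labeled
distance matrices and simply skip the stages that need genotypes. Climate
is a per-site table of real-valued variables (19 Bioclim-style columns by
default); pairs whose site locations cannot be recovered carry a
`has_climate = FALSE` flag rather than imputed values. Site order is
canonical (first appearance) and enforced identically across every matrix —
all matrices are stored full, not triangular, so label checks are trivial.

## Genetic distance

Multiallelic markers are recoded to biallelic *pseudoloci*: a locus with
alleles A, B, C becomes three pseudoloci (A vs. not-A, B vs. not-B, C vs.
not-C), each inheriting the locus sample size; biallelic loci pass through
with the lexicographically first allele as focal. This recoding slightly
reuses information across pseudoloci of one locus (their focal counts sum
to the sample size), which is the price of a uniform biallelic downstream
model.

Pairwise FST between sites is the classic two-population
variance-components moment estimator, pooled over pseudoloci as a ratio of
sums (see the README for the closed form). Numerical conventions:

* Estimates may be negative (sampling noise around zero differentiation);
  they are *retained* in the distance matrices. Clamping to zero happens
  only where a downstream stage requires it (the beta-response regression,
  the covariance model's ecological distances).
* A site pair at which every pseudolocus is monomorphic has an undefined
  0/0 estimate; we emit 0 with a warning so matrices stay complete.
* θ̂ ≤ 1 algebraically; a fixed difference at every locus gives exactly 1.

The Rousset linearization D/(1−D) is applied before correlation analyses.
It requires D < 1; distance matrices on other scales (e.g. Nei's D, which
can exceed 1) raise an error asking the user to rescale — guessing a
rescaling silently would change the science.

## Geographic and climatic distance

Great-circle distances use the haversine formula on a sphere of radius
6378.388 km — the equatorial radius the classic geographic-distance tools
default to — exposed as an argument because reproductions against other
toolchains need to match the sphere. Log10 of distance is used in
correlations and regressions; duplicate coordinates are an error (merge or
jitter, the package will not decide).

Climatic distance is Euclidean distance between site scores in the
principal-component space of the climate table. Variables are centered but
*not* scaled by default (matching the common default of PCA tooling);
scaling is a flag because Bioclim variables mix units. The number of
retained components defaults to *all*, which makes the construction exactly
distance-preserving (an orthogonal rotation of the centered data) — the
component count is exposed for users who want a truncated climate space.

## Correlations and bootstrap

All descriptive association is Spearman rank correlation over the
S(S−1)/2 unordered site-pair entries. Confidence intervals come from
resampling the site-pair observations with replacement (1000 resamples by
default), reporting 50% and 95% percentile intervals and a one-sided
bootstrap p-value for ρ > 0 with a plus-one correction (p is never 0). The
resampling unit is the site-pair row, mirroring row-resampling bootstrap
helpers; a site-level block bootstrap would be more conservative and is
noted as an alternative, but is not the default. Degenerate resamples
(zero rank variance) are redrawn, with an error if more than 10% redraw.

The publication-bias check correlates per-study sample size (number of
pairwise comparisons) with effect size across studies; a significant
negative correlation is the classic file-drawer signature. The p-value is
the asymptotic t approximation.

## Zero-inflated beta MMRR

The regression stage fits, per pair,

y ~ ZIB(π₀, μ, φ),  logit(μ) = β₀ + β_geo·geo + β_clim·clim + β_host·host

where y is the associate genetic distance clamped at zero from below —
negative moment estimates are genuinely indistinguishable from "no
differentiation", and the clamp is precisely what gives the zero-inflation
component meaning. Predictors are standardized to zero mean / unit variance
so β's are comparable across pairs and poolable. The response must lie in
[0, 1); the raw FST scale is the default (beta support argues for it), with
a flag for a rescaled Rousset response.

Estimation is maximum likelihood: π₀'s MLE is the observed zero fraction
(it separates from the likelihood), and (β, log φ) are optimized by BFGS
with analytic gradients from five deterministic starts — a logit-scale
least-squares β start and an intercept-only fallback, crossed with φ ∈ {1,
5, 25} and a method-of-moments φ. Standard errors are the inverse observed
information. A Bayesian fit would be statistically equivalent on the logit
scale but is not desk-scale when the permutation engine refits the model a
thousand times.

Significance uses multiple matrix regression with randomization: each
permutation draws a random site relabeling and applies it *simultaneously
to rows and columns* of the response matrix (never independent cell
shuffles — preserving the matrix dependence structure is the entire point
of MMRR), then refits. A coefficient is significant when the observed
estimate falls outside the central 95% interval of its permuted-null
distribution, with the observed fit included in the reference set (it is
exchangeable with the permutations under the null; without this the rule
measured mildly anti-conservative). A two-sided permutation p-value with
plus-one correction is reported alongside. The underlying description of
this rule in the synthesis literature is ambiguous between "observed
outside the permuted interval" and "permuted interval excludes zero"; we
implement the standard MMRR rule (the former).

## The covariance-isolation model

For genotype-bearing pairs the package fits an aggregate allele-frequency
covariance model: per pseudolocus ℓ, latent frequencies θ_ℓ across sites
are multivariate normal with mean μ_ℓ and covariance μ_ℓ(1−μ_ℓ)·Ω, where

Ω_ij = (1/α₀)·exp(−(α_D D_ij + Σ_k α_E,k E_k,ij)^α₂),  Ω_ii = 1/α₀,

observed counts are binomial at f = clamp(θ, 0, 1), and the α terms are the
isolating effects of geographic distance D and ecological distances E
(climate distance, host genetic distance). Conventions and choices:

* **Standardization.** D and each E are divided by the standard deviation
  of their off-diagonal entries before entering the model, so α terms are
  per-unit-spread and comparable across factors and pairs — required
  because the synthesis stage pools α terms across studies. Negative
  entries of ecological distance matrices (possible for moment-estimated
  FST) are treated as zero.
* **Link.** The clamp-to-[0,1] Gaussian field matches the published model
  family this stage re-implements; states with f = 0 and x > 0 have zero
  posterior density (−∞ log posterior), not an exception.
* **Priors.** Exp(1) on α_D and each α_E, Gamma(1,1) on α₀, Uniform(0.1, 2)
  on the shape α₂, Uniform(0,1) on each μ_ℓ. The source analyses state no
  priors; these are weakly-informative defaults on the standardized scale,
  all exposed in the state/config. α₂ is free by default (bounded above by
  2, the validity limit of the powered-exponential family).
* **Positive definiteness.** A jitter of 1e−8/α₀ is added to the diagonal
  before factorization. Ω is *not* guaranteed positive definite for
  arbitrary parameter values, because an FST-derived E is not conditionally
  negative definite in general; the sampler simply rejects non-PD
  proposals (a failed Cholesky is treated as zero posterior density).
* **Sampler.** Metropolis-within-Gibbs in compiled code: log-scale random
  walks for α₀, α_D, α_E (with the Jacobian), a reflected-bounds walk for
  α₂, and per-locus updates of μ_ℓ and the θ_ℓ vectors — loci are
  conditionally independent given the α block, so all-locus proposals are
  evaluated in single matrix operations and accepted per locus. Proposal
  scales adapt toward 20–40% acceptance during the first 20% of burn-in
  and are then frozen, so the retained draws come from a fixed,
  detailed-balance-preserving kernel; this automates the manual
  pilot-tuning loop such analyses traditionally use. Chains are exactly
  reproducible from a seed.
* **Run lengths.** The field-standard schedule is 5×10⁶ iterations with the
  last 1×10⁶ retained (`mcmc_full_config()`); the package's validation runs
  use a desk preset of 1×10⁵ iterations, same 80% burn-in fraction
  (`mcmc_desk_config()`), which parameter-recovery tests show is sufficient
  at 10 sites × 50 pseudoloci. Retained draws are thinned to a target count
  (10,000 at full scale) since the α posteriors are heavily autocorrelated.
* Because the model constrains α > 0, per-pair posterior intervals can
  never cross zero; they are reported anyway, and the meaningful zero
  comparisons happen in the meta-analysis of pooled effects.

## Meta-analytic synthesis

Per-pair effects are pooled with DerSimonian–Laird random-effects
meta-analysis: correlations on the Fisher-z scale with variance
1/(n_pairs − 3), regression β's with their asymptotic SEs, α terms as
posterior median ± posterior SD (the source convention is unstated;
median/SD is robust to the long right tails of constrained-positive
posteriors). The effective n for a distance-matrix correlation is the
number of site pairs, which ignores their non-independence and is therefore
**anti-conservative in absolute terms** — pooled CIs should be read as
optimistic; the relative study weights, which are what pooling needs, are
unaffected by this caveat.

The interaction-type contrast uses the mixed-effects subgroup convention:
the common τ² is the *residual* (within-group) DL estimate, random-effects
weights are 1/(v + τ²), and Q_between = Q_total − Σ Q_within is referred to
χ²(groups − 1). This is exactly the omnibus moderator test of a categorical
mixed-effects meta-regression (verified against an independent
implementation in the test suite). The χ² reference holds its level on
homogeneous panels and is known to be mildly anti-conservative under strong
extra heterogeneity — a property of this standard machinery, not of the
implementation.

There is no formal phylogenetic correction (associate taxa in such
compilations are too unevenly dispersed); instead, the close-relative
pruning scan re-runs every pooling on all 2^g datasets formed by excluding
one member of each related pair (g = 4 groups → 16 datasets) and flags any
pruned dataset whose qualitative conclusion — sign, 95% CI exclusion of
zero, subgroup significance — differs from the full data.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
truth; it emulates the *structure* of a compiled literature, not any
particular ecosystem.

* **Sites and climate.** S sites uniform in a square (default 200 km side,
  minimum 1 km separation — closer "populations" are not geographically
  distinct and break log-distance), projected to plausible WGS84
  coordinates; at 200 km the median inter-site distance (~100 km) sits in
  the middle of the spread of real sampling designs, which range from
  ~16 km to >1000 km. Climate is 5 latent Gaussian-process fields
  (squared-exponential kernel, range one third of the extent) mixed
  linearly into 19 strongly intercorrelated columns plus independent
  noise — mimicking Bioclim's redundancy. The mixing matrix is recorded
  with the truth.
* **Genotypes.** Host counts are simulated from the covariance-isolation
  model over geography (+ climate); the associate is then simulated with
  the host's *realized* FST matrix as an additional ecological distance —
  the planted isolation-by-host channel is exactly the quantity the
  analysis pipeline can observe, which makes recovery tests fair. If the
  realized host FST matrix makes exp(−αH) non-PD (FST matrices carry no
  PD guarantee), the host is redrawn with a recorded seed offset. SSR mode
  instead emits multiallelic genotypes (spatially correlated
  logistic-normal allele frequencies, multinomial sampling) to exercise
  the pseudolocus recoding path.
* **Default regime.** α₀ = 10 with host α_D = 0.4 and associate
  (α_D, α_E,clim, α_E,host) = (0.15, 0.1, 0.5), 50 pseudoloci, 40 allele
  copies per site (20 diploids — the scale of typical SSR studies). This
  was calibrated once, at design time, to produce median pairwise FST
  ≈ 0.08–0.15 and per-pair correlation spreads matching what compiled
  host–associate studies report; it was not revisited afterwards.
* **Saturation.** A property worth knowing: the realized host~associate
  rank correlation is *not* monotone in the planted α_E,host. At realistic
  standardized-FST scales (off-diagonal mean ≈ 2.5 spread units), the
  isolating kernel exp(−α·distance) saturates once α ≳ 0.5: between-site
  covariances all approach zero, realized differentiation compresses
  against its ceiling, and rank correlation falls (measured host-only
  means ≈ 0 / 0.58 / 0.51 / 0.11 at α_E,host = 0 / 0.15 / 0.5 / 2). The
  generator's planted defaults sit on the informative limb; recovery of
  the *α ordering* by the covariance model still works deep into
  saturation because the low-distance site pairs remain informative.
* **Collections.** The default 20-pair collection copies the structural
  skeleton of the compiled literature: site counts 4–45, seven
  antagonistic pairs, seven distance-only pairs (only one genotype-bearing
  antagonist), four pairs without climate, and four close-relative groups.
  Antagonists draw their planted α_E,host from a larger-mean log-normal
  (0.5 vs. 0.15) and mutualists a larger geographic effect (0.3 vs. 0.1) —
  the contrast the synthesis stage is meant to detect, expressed in the
  pooled regression host coefficient (the confound-adjusted readout; the
  raw host~associate correlation deliberately retains the shared-geography
  confound).

**What passing tests do and do not show.** The generator draws from the
same model family the covariance stage fits, so α recovery validates the
sampler and likelihood, not the model's adequacy for real genotypes. Real
data differ in ways the generator deliberately omits: linkage, mutation
model, coalescent noise shared across loci, uneven sample sizes per site,
marker ascertainment, and ecological distances measured with error.
Distance-only and no-climate variants emulate reporting gaps, not biases.

## Problem sizes used in validation

The test suite and the acceptance script run at *desk scale*, chosen as the
smallest sizes at which each stage's statistical behavior is measurable:
bootstrap B = 200–1000; MMRR calibration at 200 null replicates × 200
permutations (8 sites); ZIB recovery at 30 sites × 20 replicates; MCMC
recovery at 10 sites × 50 pseudoloci × 10⁵ iterations × 10 seeds;
end-to-end collections of 20 pairs with 100 permutations and 2×10⁴ MCMC
iterations per genotype pair. Full-scale settings (B = 1000, 1000
permutations, 5×10⁶ iterations) are the defaults of `pipeline_control()`
and are what an actual synthesis should use.

## Known limitations

* The Fisher-z variance convention (site pairs as effective n) is
  anti-conservative; treat pooled correlation CIs as optimistic.
* The ZIB response must be < 1; genetic distances on scales exceeding 1 are
  rejected, not rescaled.
* The covariance model assumes a single shape exponent and scale for all
  loci; overdispersed (beta-binomial) sampling is out of scope.
* Monomorphic site pairs enter the genetic distance matrix as 0, which is a
  choice (completeness) rather than a fact.
* How per-site sample-size heterogeneity was handled in published
  distance-only matrices is unknowable from the matrices; they are ingested
  verbatim.
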