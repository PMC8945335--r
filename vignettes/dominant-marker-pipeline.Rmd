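---
title: "Population genetics of dominant binary markers: models, simulator and risk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genetics of dominant binary markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issrpop)
```

## The problem

Dominant multilocus markers (ISSR, AFLP, RAPD) score each locus as band
presence (1) or absence (0). A band is shown by dominant homozygotes *and*
heterozygotes, so genotypes are only partially observed: every statistic
downstream of the raw matrix has to reason through this dominant masking.
`issrpop` implements the full analysis chain used in conservation-genetic
surveys of small, fragmented plant populations: allele-frequency estimation,
per-population diversity, among-population differentiation with permutation
tests, multivariate and model-based structure inference, decline and
local-extinction scenario simulations, and rule-based conservation risk
scoring. The motivating use case is a cliff-dwelling succulent known from six
sites only, sampled at 20 individuals per site with 12 ISSR primers.

## Allele frequencies and diversity

Under Hardy–Weinberg, a band-absent individual is a recessive homozygote, so
the band-absence fraction `x` estimates `q^2`. The naive `sqrt(x)` is biased
upward at small samples; we apply the Lynch–Milligan Taylor correction

```
q = sqrt(x) / (1 - Var(x) / (8 x^2)),   Var(x) = x (1 - x) / n
```

clamped to [0, 1], with `x = 0` short-circuited to `q = 0` (the bias term is
undefined there). The correction needs `n >= 2` per population and complete
data; matrices containing the missing-data sentinel are rejected outright
rather than imputed, because every formula in the chain assumes complete
binary data.

Per population we report: band-state allele counts `Na` (each locus
contributes 1 or 2 observed states — a census-style convention used by
dominant-data programs), private alleles (bands seen in exactly one
population), the effective allele number `Ne = mean(1 / (p^2 + q^2))`,
`He = mean(2pq)`, Shannon `I = mean(-(p ln p + q ln q))`, and the percentage
of loci polymorphic under the 95% criterion, evaluated on *band-state*
frequencies (a locus is polymorphic when its commoner band state is at most
0.95). `He` and `I` are computed on the estimated allele frequencies for
consistency with each other; `nei_gst(..., use_band_freqs = TRUE)` exposes
the raw-band alternative because the dominant-data convention differs
between programs. Across-population summaries report `mean ± sd/sqrt(k)`.

## Differentiation

`nei_gst()` partitions gene diversity per locus (`Hs = mean 2pq`,
`Ht = 2 p̄ q̄`) and combines loci by summing components, excluding loci with
`Ht = 0`. `amova_binary()` is a one-level AMOVA on squared Euclidean
distances between band vectors — identical to Hamming counts for 0/1 data —
with the standard variance-component estimator and a permutation test that
shuffles individuals among populations with fixed sizes (the dominant-data
program convention), using the add-one p-value so p is never 0. Pairwise
`Phi_st` comes from two-population AMOVAs and is Slatkin-linearized
(`Fst/(1-Fst)`) for the Mantel test, which correlates linearized genetic
distance with log10 geographic distance, one-sided against positive
isolation by distance (the standard alternative), with a Spearman coefficient
and a bootstrap-over-pairs CI reported alongside. Gene flow uses the
Crow–Aoki finite-island correction `alpha = (n/(n-1))^2`,
`Nm = ((1/Gst)-1)/(4 alpha)`.

Numerical conventions worth noting: variance components can be negative in
near-panmictic data (we do not truncate — percentages then fall outside
[0, 100] but always sum to 100); `Gst` is undefined when every locus is
monomorphic everywhere (error); `Phi_st = 1` linearizes to `+Inf` with a
warning; a zero geographic distance is an error because log distance is
undefined.

## Structure inference

* **Minimum spanning network** — Kruskal's algorithm on Hamming distances
  with a deterministic tie-break, then every non-tree edge whose weight
  equals the bottleneck (maximum edge) of the tree path between its
  endpoints is retained, so equally-good alternative connections appear as
  cycles, as population-genetic network software draws them.
* **PCA** — covariance-matrix PCA of the centred band matrix (no scaling).
  Component signs follow the largest-magnitude-loading-positive convention,
  making scores reproducible.
* **DAPC** — groups are found by seeded k-means (25 restarts) on retained
  principal components for `k = 1..k_max` (default `min(10, n-1)`),
  choosing k by `BIC = n log(WSS/n) + k log(n)`; a linear discriminant
  analysis of the retained PCs against the groups yields at most `k-1`
  discriminant functions. When not given, the PC count is the smallest
  explaining 80% of variance.
* **Admixture clustering** — a Gibbs sampler for a Bayesian mixture with
  admixture: cluster band frequencies `theta_kl ~ Beta(1,1)`, admixture
  proportions `q_i ~ Dirichlet(1)`, allocations `z_il ~ Cat(q_i)`, and
  `band_il ~ Bernoulli(theta)`. Band phenotypes are modelled directly as
  Bernoulli draws. This is a deliberate simplification of genotype-based
  admixture software for dominant data: it cannot separate dominant
  homozygotes from heterozygotes (nothing can, per locus, from one
  individual), but it recovers cluster structure well and runs in seconds.
  `L(K)` is the posterior mean data log-likelihood; label switching is
  resolved by greedily matching each sample's `theta` to the first
  post-burn-in sample. Default chains (2,000 burn-in / 5,000 retained) are
  sized for the 120 x 65 design; field analyses that used 100,000/500,000
  iterations can set those values explicitly.
* **Evanno ΔK** — over replicate runs per K: `ΔK = |L''(K)| / sd(L(K))`,
  maximized over interior K. Zero replicate spread yields an infinite ΔK
  with a warning rather than a silent choice.

On the bundled six-population design the scan selects K = 2 and the Q matrix
cleanly separates the two ancestral clusters.

## The synthetic-data generator

No raw band matrix is distributed with the package; the generator stands in
for it and makes every downstream stage testable. Its default
(`study_preset()`) matches the motivating survey: 6 named populations x 20
individuals, 60 regular loci plus 5 private-band loci (4 + 1 in two
populations), two ancestral clusters of 4 and 2 populations, band-level
differentiation target 0.45, and site coordinates scaled to a mean pairwise
distance of 5.99 km (the layout itself is illustrative; only the mean
distance is anchored).

Per locus, an ancestral dominant-allele frequency `a ~ U(0.05, 0.95)` is
drawn; cluster frequencies diverge from `a` and population frequencies from
their cluster's value under Balding–Nichols Beta sampling
(`Beta(p(1-F)/F, (1-p)(1-F)/F)`), with the two levels sharing the
differentiation budget via `(1-Fb)(1-Fw) = 1-Ftot`, `Fb = Fw`. Frequencies
are clipped to [0.01, 0.99] to avoid degenerate monomorphic loci. Each
individual draws a diploid genotype (two Bernoulli trials) and shows the
band iff it carries at least one dominant allele. Private loci are injected
at band frequency 0.3 in exactly one population and zero elsewhere.

**Calibration.** `fst_target` is defined as the *band-level* AMOVA
differentiation the data should exhibit, because bands are what every
downstream statistic sees. Dominant masking inflates band-level Phi_st
roughly 1.4x relative to the allele-level Balding–Nichols parameter, and
populations sharing a cluster are correlated, so the generator inverts a
deterministic frequency-level Monte Carlo of the expected multi-locus Phi
(8,000 simulated loci under the exact hierarchy, fixed internal seed,
`uniroot`; memoized per design) to find the allele-level `Ftot` matching
the target. Without this
the generator would produce Phi_st ≈ 0.60 when asked for 0.45, and could
never approach 0 as `fst_target -> 0`. The calibration is part of the
generator's contract, not a tuning knob; targets 0.1–0.6 are recovered
within ±0.01–0.05 of the requested value (median over 20 replicates).

An optional `clone_rate` duplicates genotypes within populations to emulate
clonal reproduction; the default is 0 because the emulated field protocol
spaces samples (20 m) precisely to exclude clones.

What the generator does **not** emulate: linkage between loci, mutation,
scoring error or gel-to-gel band misalignment, and demographic history
beyond the two-level island structure. Passing tests therefore demonstrate
correctness of the statistics under the model's assumptions, not robustness
of ISSR scoring in the lab.

## Scenarios

`apply_scenario()` implements the two perturbations used to project
post-decline genetics: random loss of a fraction of each population
(removing `floor(fraction * n)` per population — "half" keeps the extra
individual in odd populations, a convention we fixed since either reading is
defensible), and local extinction of named populations. The comparison
recomputes the full metric suite with identical settings and tests the
change in per-population private-allele counts with a goodness-of-fit
chi-squared (post against baseline, baseline-zero populations pooled;
`df = cells - 1`). That form is the only single-statistic reading consistent
with a chi-squared over private-allele counts; counts can legitimately move
in either direction, since an allele shared only with a removed population
becomes private to a survivor.

## Risk scoring

`score_mer()` implements the Mexican MER: four criteria scored in ascending
risk, normalized by their maxima, summed and classified (`EE >= 2.0`,
`E` in [1.70, 2.0), `Pr` in [1.5, 1.70)). The published interval bounds
overlap at exactly 1.70; we resolve the boundary to the higher-risk
category and flag it. The per-level point tables are an editable config —
the qualitative worksheets behind published assessments are not printed
anywhere — and the shipped presets reconstruct a plausible assessment
timeline whose *categories* match the published sequence (special
protection with basic knowledge, threatened with full ecological knowledge,
danger of extinction once genetic evidence enters, higher totals under
decline/extinction scenarios). When genetic inputs are supplied, criterion C
takes the maximum of its ecological and genetic sub-scores, so genetic
evidence can only raise vulnerability.

`classify_iucn()` is a simplified, config-driven mapper over parts of the
red-list system: each supplied criterion (reduction A, restricted range B,
small-and-declining C, very small D, quantitative E) is graded against the
standard published bounds and the highest triggered category wins. Observed
ongoing local extinctions are imputed as a 0.5 extinction probability for
criterion E (configurable), which is what drives the critically-endangered
outcome of the extinction scenario presets.

## Problem sizes and determinism

Defaults are sized for the 120-individual, 65-locus design: AMOVA and
Mantel permutations default to 10,000 (the convention in the emulated
analyses) but every test and example uses smaller counts; admixture chains
default to 2,000/5,000 sweeps. All stochastic stages take explicit seeds;
the pipeline derives per-stage seeds from one global seed
(`stage_seed()`), so stages rerun in isolation reproduce the pipeline
exactly and two runs with the same config are byte-identical apart from the
manifest timestamp.

## Known limitations

* Allele-frequency estimation assumes Hardy–Weinberg within populations;
  clonality or inbreeding bias `q` upward.
* The admixture model ignores linkage and treats bands as independent
  Bernoulli phenotypes; `L(K)` values are not comparable to genotype-model
  log-likelihoods.
* The AMOVA is one-level (no region/population hierarchy).
* The MER/IUCN engines are screening tools over editable configs, not
  legal-grade implementations of either standard.
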