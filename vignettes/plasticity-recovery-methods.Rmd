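---
title: "Models and methods: plasticity and post-drought recovery indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: plasticity and post-drought recovery indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastrec)
```

## The problem

A drought-sensitive tree population can buffer increasing aridity in three
partly independent ways: by maintaining function during water deficit
(drought resistance), by restoring function after rewatering (post-drought
recovery), and by adjusting its phenotype to the environment (phenotypic
plasticity). Quantifying how these abilities vary **among maternal
families within one population** requires a chain of analyses — plasticity
and recovery indices, a stomatal dose-response model, ANOVA of recovery
performance, and multivariate synthesis — that this package implements as
one tested pipeline. Because the motivating kind of dataset (a split-plot
greenhouse trial with well-watered and water-stressed siblings of many
open-pollinated families) is rarely public, the package also ships a
synthetic-data generator with the same statistical anatomy, which is what
the test suite exercises end to end.

## The relative distance index

For one trait, one family and two watering treatments, let `x_ij` be the
`j`-th observation under treatment `i`. The index is the mean relative
distance over all cross-treatment pairs:

$$\mathrm{Index} = \frac{1}{n}\sum_{j,\,j'} \frac{|x_{i'j'} - x_{ij}|}{x_{i'j'} + x_{ij}},
\qquad i \ne i'.$$

Computed on end-of-stress measurements it is the phenotypic plasticity
index (PP, 0 = no plasticity); on post-recovery measurements it is the
recovery index (RE, 0 = complete recovery, 1 = none). The bound
$[0, 1]$ holds only when all values share a sign, which motivates three
numerical decisions:

* **Sign normalization.** Traits whose values are all non-positive
  (carbon/nitrogen isotope ratios near −28‰ / −2‰, predawn water
  potential) are negated before the index is formed; mixed-sign input is
  an error, because the index is then undefined rather than merely noisy.
* **Absolute distances.** The pairwise "distance or difference" is taken
  as the absolute difference, which is what keeps the index within
  $[0, 1]$.
* **Zero denominators.** A pair with $x + x' = 0$ (both zero) carries no
  information about relative change; such pairs are dropped and counted
  (`n_dropped`), never imputed. If *all* pairs drop, the index errors.

Pairs are pooled across blocks within a family (10 × 10 pairs per family
at the default design), which maximizes the number of pairs; the package
does not offer within-block pairing because the block effect is additive
and small in the stated world, and restricting pairs would quarter `n`
without changing the estimand.

### Testing among-family differences

The published procedure for comparing the index across groups is cited
rather than printed in the motivating literature, so the package commits
to a permutation test: the statistic is the F-like ratio of
between-family to within-family mean squares of the per-pair relative
distances, and the null distribution permutes family labels across
seedlings **within each watering treatment**, recomputing all pairs each
time. Stratifying by treatment preserves the per-treatment design margins
(an unstratified shuffle can strand a family without any well-watered
seedlings, leaving its index undefined) and is valid under the null that
family labels are exchangeable given treatment. The p-value uses the
add-one rule, `p = (1 + #{perm ≥ obs}) / (1 + B)`, making the test exact
in level; with `B = 499` the acceptance suite verifies a type-I error
inside [0.03, 0.07] at α = 0.05 over 500 null datasets.

## The stomatal dose-response model

Stomatal closure during soil drying is modelled log-linearly with
family-specific intercepts and slopes:

$$-\ln(g_{wv,ij}) = \alpha_0 + \alpha_i + (\beta_0 + \beta_i)\,\Psi_{pd,ij} + \varepsilon_{ij}.$$

Fitting is ordinary least squares on the transformed response. Reporting
uses the **composite** per-family coefficients $\alpha(f) = \alpha_0 +
\alpha_f$, $\beta(f) = \beta_0 + \beta_f$ with standard errors from the
full coefficient covariance, so the results do not depend on the
reference-family parameterization (the reference is the lowest family
code). Confidence intervals are t-based at 95%; the ANOVA is sequential
(Type I) in the fixed order water potential, family, interaction — the
single-df water-potential row first — and the interaction row is the test
of family-dependent stomatal sensitivity. A steeper negative slope means
more stringent (more isohydric-like) stomatal control.

The compact letter display assigns letters to the maximal groups of
mutually-overlapping confidence intervals (the maximal cliques of the
interval overlap graph, enumerated at interval left endpoints); two
families share a letter **iff** their intervals overlap, which the tests
verify against an all-pairs oracle. Note this is a CI-overlap display,
not a multiple-comparison procedure.

The fit uses all stress-phase seedlings with a valid conductance/water
potential pair, from both treatments: the well-watered points anchor the
wet end of the response and the identifiability of each family's slope
comes from the water-stressed spread.

## Recovery ANOVA

Post-recovery gas exchange is analysed per trait with the fixed-effects
model `value ~ treatment * family + block`. The split-plot whole-plot
error stratum is **deliberately not modelled**: the package reports a
single residual-MS F-test per term, with block as an additive fixed
effect. This is a documented simplification — with whole plots as the
watering units, the treatment F-test is anti-conservative in principle —
chosen because the analysis chain this package standardizes reports
exactly one significance per term, and because the generator's block
effect is additive by construction. Assumption checks are Shapiro–Wilk on
residuals (delegated to `stats::shapiro.test`; re-deriving its coefficient
tables is out of scope) and the Brown–Forsythe variant of Levene's test
(one-way ANOVA on absolute deviations from group medians), the robust
default of the model-checking tradition this follows.

## Multivariate stage

* **Clustering.** Families are points in index space; distances are
  Euclidean on the raw indices (no standardization — the indices already
  live on [0, 1]) with average linkage. Neither the distance nor the
  linkage is canonical in the motivating literature; both are arguments.
  Node support is the fraction of `B` column-bootstrap dendrograms
  containing the identical leaf set. This is a plain bootstrap
  probability, deliberately simpler than multiscale-bootstrap
  approximately-unbiased p-values (a stated non-goal); plain bootstrap
  probabilities are known to be biased downward for true clades, so
  support values here are conservative and not comparable to AU p-values.
* **PCA.** Columns of the family feature matrix (indices, per-family
  treatment-split trait means, stomatal slopes) are standardized, so the
  decomposition is of the correlation matrix; components with eigenvalue
  > 1 are retained (Kaiser rule); signs follow a deterministic convention
  (largest-|loading| entry positive) so runs are comparable. With `r`
  families and `p > r` variables, all variance is carried by the first
  `r − 1` components; variance fractions still sum to one over the
  returned components.
* **Correlations.** Pearson r for all unique pairs, two-sided p from the
  t transform, and an in-package Benjamini–Hochberg step-up (`bh_adjust`)
  applied across all unique pairs. BH is implemented rather than called
  from `stats::p.adjust` so the hand-computed worked example and the
  `p.adjust` cross-check in the tests remain genuinely independent
  routes. Constant columns yield flagged `NA`s, never a fabricated zero
  correlation.

## The synthetic generator: what it emulates, what it does not

The generator reproduces the *statistical structure* the analyses assume,
at the design scale of the motivating experiment (320 seedlings = 5
replicates × 16 families × 2 watering regimes × 2 blocks; 11 weekly
stress cycles; family codes the non-consecutive set 1–22):

* per-trait family baselines (±6% around field-plausible means for beech
  seedlings: net photosynthesis ≈ 9 μmol m⁻² s⁻¹ well-watered, SLA ≈ 25
  m² kg⁻¹, leaf N ≈ 2.2%, δ13C ≈ −28.5‰, basal-area RGR ≈ 0.008–0.012
  day⁻¹), family-varying water-stress effects (the family × treatment
  interaction that makes true PP differ among families), and a shared
  additive block effect;
* the log-linear stomatal response used **generatively**:
  `g_wv = exp(−(α_f + β_f Ψ_pd + ε))` with α_f spread over [0.63, 1.41]
  and β_f over [−1.50, −0.77] (the published coefficient ranges for this
  kind of material) and residual sd 0.53 on the −ln scale — multiplicative
  log-normal noise, which keeps conductance positive and matches the
  model's error term;
* predawn water potential drawn per treatment: well-watered
  Normal(−0.4, 0.1²) MPa truncated above at −0.05 (the literature reports
  the realized stressed range, not the sampling law; well-watered plants
  are assumed well hydrated), water-stressed Uniform(−3.3, −0.8) MPa —
  the uniform spread guarantees slope identifiability in every family;
* recovery as geometric relaxation toward the family's well-watered mean:
  `WW mean + (1 − ρ_f)(stress value − WW mean) + noise`, with recovery
  fractions ρ_f drawn high for photosynthesis and photochemistry
  (0.70–1.00, 0.75–1.00) and low for stomatal conductance (0.25–0.60),
  reproducing the characteristic pattern that assimilation recovers
  faster than conductance, so intrinsic water-use efficiency stays
  elevated after rewatering.

Two pragmatic floors keep the stated world inside the domain of the
index: strictly-positive traits are floored at 10⁻⁶, and RGR is floored
at 10⁻⁴ day⁻¹ (surviving seedlings do not shrink in basal area; without
the floor, near-zero stressed growth plus Gaussian noise produces
mixed-sign values for which the relative-distance index is undefined).

Not emulated: soil-water and ABA dynamics, within-cycle time series,
mortality, measurement-instrument artifacts, or any covariance between
traits beyond what the shared family/treatment/block effects induce. A
green end-to-end test therefore establishes that the pipeline's
statistics behave correctly **given** this structure — not that the
generator's parameter values are field-accurate.

Derived traits are appended by `derive_traits()` exactly as for real
data: `A_mass = A_area × SLA`, `iWUE = A_area / g_wv`,
`PNUE = A_mass / (10 N_m)`. Leaf structure (SLA) and nitrogen are
measured only at the end of stress, so recovery-phase `A_mass` reuses the
seedling's stress-phase SLA and PNUE is stress-only; recovery records are
restricted to the five gas-exchange traits.

## Reproducibility choices

* Every stochastic entry point takes an integer seed and uses
  `withr::with_seed`, so library calls never clobber the caller's RNG
  state; the pipeline derives per-stage seeds from one master seed and
  records them in its manifest.
* The run manifest contains configuration, seeds, package version and MD5
  digests of all outputs but **no timestamps**, so identically-seeded
  runs are byte-identical (verified byte-for-byte in the acceptance
  suite). Timestamped logs go to standard error only.
* Trait tables serialize values with 17 significant digits, making the
  CSV round trip lossless at double precision.
* Configuration and family profiles serialize to JSON (the environment
  provides no YAML parser; the structure is unchanged).

## RGR intervals

The growth measurements span three intervals tied to stress cycles
(cycles 1–5, 5–11, 1–11). Cycle length is one week, so the generator's
defaults correspond to 28, 42 and 70 days; `compute_rgr()` implements the
classical `Δln(basal area)/Δt` with basal area `π(d/2)²`, in which the
constants cancel to `2(ln d_end − ln d_start)/days`. The generator
simulates the RGR traits directly from family profiles (the diameter
series feeds no downstream stage); `compute_rgr()` is the preprocessing
entry point for real caliper data.

## Known limitations

* No whole-plot error stratum, so treatment tests on strongly
  block-structured data are anti-conservative.
* Bootstrap clade support is downward-biased relative to AU p-values;
  thresholds like "support ≥ 0.95" are conservative.
* The permutation test assumes exchangeability of seedlings within
  treatment; systematic within-family heteroscedasticity alters its
  interpretation (level is preserved, the alternative changes).
* The feature matrix for PCA/correlations drops constant or incomplete
  columns rather than imputing; with 16 families the correlation p-values
  rest on n = 16 and should be read through the FDR correction, not
  individually.
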