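---
title: "Line-by-tester combining-ability analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-by-tester combining-ability analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(testcross)
```

This vignette is the package's own account of the statistics it implements:
the mixed models, the combining-ability decomposition, the cross-validation
scheme, the synthetic trial generator, and the numerical and design choices
that were genuinely open.

## The design

A line-by-tester experiment crosses many candidate inbred lines to a few
fixed testers and evaluates the testcross hybrids in replicated multi-
environment trials. The design this package is built around is the
incomplete two-group form used in tropical maize programs: lines belong to
one of two heterotic groups (A or B), testers are single crosses from the
opposite group, and each line meets only the testers of the opposite group.
The reference configuration is 93 group-A plus 172 group-B lines, three
testers per group, and each line crossed to its three opposite-group
testers, giving 265 × 3 = 795 testcrosses. Trials follow an alpha-lattice
layout — incomplete blocks nested in replications nested in environments —
with two replications, three drought-stress environments and four optimum
environments, plus a handful of commercial check hybrids planted alongside
the testcrosses.

One structural property of this design deserves emphasis because it shapes
the estimation machinery: with disjoint tester sets per group, the bipartite
line-tester graph necessarily has **two connected components** (A-lines with
B-testers, B-lines with A-testers). Line GCA contrasts across components are
not estimable from the data alone; see *Constraint system* below for how the
package identifies the decomposition.

## Stage 1: the combined genotype model

Per management regime, every entry (testcross or check) enters

$$y_{ijkb} = \mu + E_j + R(E)_{kj} + B(RE)_{bkj} + G_i + GE_{ij} +
\varepsilon_{ijkb}$$

fitted by REML with environment and replication-within-environment fixed and
block, genotype and genotype-by-environment random. Checks are retained here
— they were grown in the trials and inform the error structure. From the
variance components, broad-sense heritability on an entry-mean basis is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/e +
\sigma^2_\varepsilon/(re)}$$

with $e$ environments and $r$ replications. **Effective environment count:**
$e$ and $r$ are explicit arguments of `heritability_broad()` rather than
being silently derived, because the effective number of environments behind
a printed heritability is not always the number of listed locations (pooled
or cross-regime analyses change it). `run_full_analysis()` defaults to the
environments actually present per regime.

## Stage 2: the line-by-tester variance partition

With checks excluded, testcross plots enter the across-environment model

$$y_{ijdkm} = \mu + E_d + R(E)_{kd} + B(RE)_{mkd} + L_i + T_j + LT_{ij} +
LE_{id} + TE_{jd} + LTE_{ijd} + \varepsilon_{ijdkm}$$

with environment and replication fixed and all genetic terms random:
line GCA, tester GCA, line-by-tester SCA, and their environment
interactions. A single-environment variant drops the interaction terms.
Each variance component is tested by a drop-one likelihood-ratio test; the
null value $\sigma^2 = 0$ sits on the boundary of the parameter space, so
the statistic is referred to the 50:50 mixture of $\chi^2_0$ and $\chi^2_1$.
A corollary worth remembering when reading simulation output: when a true
variance is zero its REML estimate lies *exactly* on the boundary only about
half the time; the rest of the mass sits close above it. From the fitted
components,

$$\text{Baker's ratio} = \frac{2(\sigma^2_{GCA_L} + \sigma^2_{GCA_T})}
{2(\sigma^2_{GCA_L} + \sigma^2_{GCA_T}) + \sigma^2_{SCA}}$$

**Composition of the GCA term.** The ratio is sometimes written with a
single GCA variance; this package sums the line and tester components. That
composition is the one that reproduces the reference drought-regime ratios
from their printed components (e.g. silking date: $2(6.18+0.06)/(2 \cdot
6.24 + 0.09) = 0.99$), and it treats both parents symmetrically.

## Stage 3: GCA and SCA effects

Effects are estimated by the classical two-stage, mean-based procedure
rather than read off BLUPs: stage one produces entry means on a common scale
(`entry_blues()`, sparse least squares with entry, environment, replication
and block fixed; raw means are available as a fallback), and stage two
decomposes them over the realised crosses:

$$\bar y_{ij} = \mu + g_i + g_j + s_{ij}$$

by least squares. This makes standard errors explicit: each effect's SE
comes from the constrained normal-equations covariance evaluated at the
caller-supplied variance of an entry mean (the pipeline uses
$\hat\sigma^2_{ge}/e + \hat\sigma^2_\varepsilon/(re)$ from stage 1), and
$t = \text{effect}/SE$ is referred to a t distribution at the stage-1
residual degrees of freedom. Satterthwaite-type df approximations are out
of scope.

### Constraint system

The additive model matrix over $(\mu, g, t)$ has a null space of dimension
(number of connected components) + 1. A single pair of sum-to-zero
constraints therefore identifies the decomposition only for connected
plans — and the reference two-group design is not connected. The package
identifies the effects with **one sum-to-zero constraint on the line GCA
effects of each component plus one overall sum-to-zero constraint on the
tester effects**: exactly as many constraints as null directions, for any
plan. For a connected plan this reduces to the textbook constraints, and on
a complete factorial the GCA effects equal marginal-mean deviations. The
practical reading for two-group plans: line GCA effects are centred within
their own heterotic group's sub-design, and the mean difference between the
two sub-designs is carried by the tester effects. `estimate_gca_sca()`
emits a message when this per-component centring is in force;
`plan_is_connected()` exposes the connectivity check directly. SCA effects
are the residuals of the additive fit, so they sum to zero over each line's
and each tester's crosses automatically; a cross whose leverage leaves no
residual degree of freedom (for example the single cross of a line) has no
estimable SCA and is flagged rather than reported as a spurious zero.

## Stage 4: GCA-based hybrid prediction

`loo_gca_cv()` implements leave-one-hybrid-out cross-validation: for each
hybrid, the additive decomposition is re-estimated from all other hybrids
and the held-out hybrid is predicted as $\mu + g_i + g_j$ — deliberately
without an SCA term, since the question is how far GCA alone predicts
performance. The summary is the pooled Pearson correlation r(GCA, TCP).
Two design choices:

* **Effects, not variance components, are re-estimated per fold.** The fold
  loop is an exact rank-one downdate of the normal equations, verified in
  the tests against an independent full refit per fold. Re-estimating
  variance components 795 times per trait would add nothing to a
  least-squares predictor.
* **Bridge crosses are skipped, not imputed.** If deleting a cross
  disconnects the design (a bridge of the bipartite graph), the held-out
  hybrid's parents end up in different components and the prediction would
  depend on arbitrary centring; such hybrids are skipped with a warning.

A quantitative note: with entry means carrying error variance $v$ and each
line represented by $k$ remaining crosses after holdout, the attainable
correlation under a purely additive model is approximately
$\sigma^2_{GCA_L} / \sqrt{(\sigma^2_{GCA_L}+v)(\sigma^2_{GCA_L}+v/k)}$.
Under the drought grain-yield regime this package ships
($\sigma^2_{GCA_L} = 0.36$, plot residual $1.01$, $3\times2$ plots per
entry, $k = 2$), that ceiling is about 0.73 — the acceptance suite measures
exactly this, and the shipped regime is not adjusted to raise it.

## The synthetic trial generator

`simulate_trial()` draws every random effect independently from zero-mean
normal distributions at configured variances and assembles plot values with
exactly the additive structure the models assume. What it emulates, and the
defaults:

* **Design dimensions**: the reference configuration above; drought defaults
  to 3 environments, optimum to 4; 2 replications; 6 checks.
* **Variance regimes**: `regime_presets()` carries the drought and optimum
  per-trait components verbatim for both the line-by-tester decomposition
  and the genotype model, plus the regime grand means (drought GY 2.15 t/ha,
  optimum 7.39 t/ha, and so on). Any component can be overridden per trait.
* **Trait coupling**: silking date is generated as SD = AD + ASI, and a
  latent per-line drought-susceptibility factor loads negatively on the GY
  and positively on the ASI line effects (loading 0.5 under drought, 0.3
  under optimum; marginal variances are preserved, induced genetic
  correlation $-\text{loading}^2$). This reproduces the qualitative
  stress signature — positive mean ASI under drought and a negative GY-ASI
  association — without asserting specific correlation values.
* **Layout**: plots are re-randomised per replication and cut into
  consecutive incomplete blocks of `block_size` (default 30) plots, the
  resolvable alpha-lattice structure. No block variance is published for
  the reference trials, so blocks default to 5% of the residual variance —
  small enough not to distort recovery, large enough to exercise the block
  terms. Environment main effects default to one residual-SD of spread;
  replication effects to 5% of residual variance. These are generator
  conveniences, not estimands.
* **Reproducibility**: a single master seed; each component draws from a
  deterministically derived substream, so output is bit-identical for a
  given configuration.

What passing tests on this generator do and do not show: they verify that
the estimation machinery recovers the parameters of data satisfying the
models' own assumptions (independent normal effects, homogeneous residual
variance, no spatial trend, missingness absent). They cannot certify
behaviour under field realities the generator omits — heavy-tailed errors,
spatial autocorrelation, genotype-specific stress-response curves, or
informative missingness. The generator also produces occasional negative
yields under the drought regime (mean 2.15, total SD ≈ 1.2): the package
deliberately validates physical trait ranges with warnings rather than
errors, because truncating at zero would bias the very recovery checks the
generator exists for.

## Numerical choices

* **REML engine**: models are fitted with `lme4::lmer` (REML), which
  profiles out the fixed effects and the residual scale and enforces the
  zero boundary on variance components. Optimiser: BOBYQA with final
  trust-region radius $10^{-13}$, no derivative post-processing.
* **Polish step**: optimiser termination alone leaves variance components
  roughly $10^{-8}$ (relative) from the optimum — at the machine-noise
  floor of the profiled deviance. `fit_reml()` therefore finishes with a
  few Newton iterations on the profiled deviance using central differences
  whose step width shrinks across iterations (the finite-difference
  gradient carries an $O(h^2)$ bias, so shrinking $h$ moves the Newton
  fixed point onto the true optimum). Balanced-design estimates then agree
  with closed-form ANOVA estimators to about $10^{-9}$ relative. The
  polish can be disabled via `reml_control(polish = FALSE)` for large
  simulation studies.
* **Models without random terms** (needed as LRT reference when testing a
  model's only random component) are fitted by ordinary least squares with
  the REML log-likelihood evaluated on lme4's scale, so likelihood ratios
  across the boundary are well defined.
* **Degenerate input**: a constant response returns all components at the
  zero boundary with the residual at the numerical floor, rather than an
  optimiser failure.
* **Determinism**: no randomised initialisation anywhere; estimates are
  invariant to row permutation and factor relabelling up to floating-point
  summation order (~$10^{-9}$).
* **Ranking tie-breaks**: `top_entries()` orders by the target trait, then
  lower ASI (earlier silking relative to anthesis is favourable under
  stress), then entry label, so rankings are stable and reproducible.
* **Reporting precision**: heritability and Baker's ratio are reported to 2
  decimals, effects to full precision with rounding left to serialisation.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen to keep the full suite in the
minutes range while preserving power: balanced-design oracle comparisons at
60–120 plots; the profile-likelihood grid oracle at 20 genotypes × 3
environments × 2 replications; parameter recovery at the full reference
scale (795 testcrosses × 3 environments × 2 replications) over 50 seeds for
the line-by-tester components and 20 seeds for the heritability round trip;
LRT null calibration over 1000 simulated datasets of 30 genotypes × 3
replications; and cross-validation oracles on plans of 15–20 lines.

## Known limitations

* Homogeneous residual variance across environments; no spatial correlation
  structures; no Kenward-Roger or Satterthwaite degrees of freedom.
* Narrow-sense heritability, dominance/epistasis partitions beyond SCA, and
  heterosis estimates are out of scope, as are marker-based prediction and
  AMMI/GGE-style stability analyses.
* The free-text pedigree field is carried but never parsed; no coancestry
  is computed.
* Field-weight measurements are assumed to refer to the full two-row plot
  (no border-row removal), matching the plot-area constant in the yield
  formula.
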