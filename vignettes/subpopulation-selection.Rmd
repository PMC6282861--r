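---
title: "Designing and evaluating trials with subpopulation selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating trials with subpopulation selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichsel)
```

## The problem

A predictive biomarker splits a trial population into `J` disjoint subgroups
with known prevalences $\lambda_1,\dots,\lambda_J$. The treatment may help
only some of them. enrichsel plans and evaluates trials that *select* one
candidate population — a subgroup, a nested union of subgroups, or the full
population $F$ — and then test the treatment effect in the selected
population, controlling the one-sided family-wise error rate (FWER) across
the whole candidate set. Selection by the **maximum test statistic** is used
throughout calibration because it is the worst case for both type-I error
and estimation bias: any less aggressive rule inflates neither.

## Model and conventions

Outcomes are normal with common standard deviation $\sigma$; the effect in
subgroup $j$ is $\theta_j = \mu_{j,T} - \mu_{j,C}$, and a union $L$ of
subgroups has the prevalence-weighted composite effect
$\theta_L = \sum_{j\in L}\lambda_j\theta_j / \sum_{j\in L}\lambda_j$.

**Information.** We write $I = 1/(\sigma\sqrt{1/n_T + 1/n_C})$, the
*reciprocal standard error* of the estimated treatment difference, so each
standardized statistic is $Z \sim N(I\theta, 1)$ and squared information
adds over independent stages, $(I^{1:k})^2 = \sum_{i\le k} (I^{(i)})^2$.
This is the only reading under which the accumulated statistics have unit
variance and the group-sequential recursion below is exact, so it is adopted
everywhere and surfaced as `information_level()`. With 1:1 allocation,
$I = \sqrt{n}/(2\sigma)$.

**Correlation.** With prevalence-proportional recruitment, nested candidate
populations $U \subset V$ have
$\mathrm{corr}(Z_U, Z_V) = \sqrt{\mathrm{prev}(U)/\mathrm{prev}(V)}$ and
disjoint ones are independent (`correlation_matrix()`). Overlapping,
non-nested candidates are rejected: their covariance is not determined by
prevalences alone and no design in this framework uses them.

**Selection density.** The joint density of the selected statistic and the
selection index under the maximum rule is
$$p(z, w;\Theta) = \varphi\!\left(z - \theta_w I_w^{(1)}\right)
\Psi_{S\setminus w}(z,\dots,z;\Theta),$$
where $\Psi$ is the conditional multivariate normal CDF of the remaining
statistics given $Z_w = z$, evaluated at the all-$z$ corner. Everything else
— critical values, stopping probabilities, power, sample sizes — is an
integral of this density, possibly propagated through stages.

## Numerical choices

* Conditional CDFs: dimension 1 uses `pnorm`; dimension 2 (the common
  three-candidate case) uses a fixed 128-node Gauss–Legendre reduction of
  the bivariate normal CDF, accurate to ~1e-12 and fully vectorized;
  dimensions 3+ fall back to the deterministic Miwa algorithm in mvtnorm.
  All paths are deterministic, so densities are reproducible run to run.
* Outer integrals truncate at $\theta_w I_w \pm 8.5$ (mass beyond is below
  1e-16) and use adaptive quadrature with absolute tolerance 1e-10.
* Stage-to-stage propagation uses a 256-node Gauss–Legendre grid per stage
  on the continuation region. This reproduces the classical two-look
  O'Brien–Fleming constant for a single population to 1e-4 against an
  independent fine-grid oracle.
* Critical values are found by bracketed root search between the single-test
  and Bonferroni quantiles (tolerance 1e-8 on the bound, ~1e-6 on the error
  rate); boundary constants likewise.
* Sample-size searches treat subgroup sizes $\lambda_j n$ as continuous
  inside the information formulas and round only the reported
  full-population total upward; searches bisect on a continuous $n$ and then
  refine to the smallest integer meeting the power target. Published totals
  produced the same way can differ by a patient or two depending on where
  rounding is applied, which is why comparisons elsewhere allow ±2.

## Designs

A single-stage design rejects $H_{0w}: \theta_w \le 0$ for the selected $w$
when $Z_w^{(1)} \ge C_\alpha$, with $C_\alpha$ solving
$\sum_w \int_{C}^{\infty} p(z, w;\Theta_0)\,dz = \alpha$. Weak control at
the global null implies strong control for maximum-statistic selection.

Multistage designs select once, at the first interim, and then **enrich**:
all later recruitment is restricted to the selected population (for $F$,
recruitment stays prevalence-proportional), so the deselected subgroups'
sample size is reallocated rather than lost. The selected statistic then
follows the standard independent-increment Gaussian transition
(`transition_density()`): given $Z^{1:k-1} = z$,
$$Z^{1:k} \sim N\!\left(z\,\tfrac{I_{k-1}}{I_k} +
\theta\,\tfrac{I_k^2 - I_{k-1}^2}{I_k},\;
\tfrac{I_k^2 - I_{k-1}^2}{I_k^2}\right),$$
the unique law consistent with unit-variance margins and independent
increments — adopted as the package's transition model since it is forced by
the definition of the accumulated statistic.

Upper (efficacy) bounds follow the O'Brien–Fleming shape
$C_u^{k,\alpha} = C_{OBF}\sqrt{K/k}$, an error-spending schedule, or the
no-stage-1-stopping variant (stage 1 selects only). Futility bounds are
either none or fixed at zero.

**Binding versus nonbinding futility.** The error-rate search can honour the
futility bounds (binding) or replace them by $-\infty$ (nonbinding, the
conservative convention: stopping for futility then only removes rejection
probability). The package's default for the replicated two-stage designs is
*nonbinding calibration with the zero futility bound applied in operation*:
across every published planning number we can recompute (the two-stage
total of 552 in the worked comparison; the two-stage stopping and selection
proportions), this convention reproduces the results, while binding
calibration lands a couple of patients lower and shifts stage-1 stopping
by a few tenths of a percent. Binding calibration remains available via
`binding = TRUE`, and the FWER it certifies is exact rather than
conservative.

Two power definitions are supported: probability of selecting a prespecified
target and rejecting its null (`"select-target-and-reject"`), or of any
correct rejection over an interest set (`"reject-any"`). The second never
needs more patients, since it counts a superset of the powered events.

## The simulator and what it emulates

`simulate_trials()` draws the model's sufficient statistics exactly: the
stage-1 multivariate normal with the nested correlation structure, the
selection rule (maximum, the sequential three-population variant — which
differs from the maximum rule only on measure-zero ties — or a user
callable), stage-wise stopping, and the enrichment transition. Patient-level
mode regenerates trials from per-subgroup, per-arm outcome sums with integer
patient counts (optionally multinomial subgroup counts) and checks that the
MLE equals the difference of arm sample means identically.

One root seed drives a single vectorized draw sequence, so identical seed
and configuration give identical record streams; no chunked or parallel
execution exists that could reorder draws.

The generator emulates exactly the idealized conditions of the planning
model: immediately observed normal endpoints, known prevalences, no time
trends or drift between stages, no overrunning patients while the interim is
read. Passing tests therefore demonstrate internal correctness of the
design arithmetic, not robustness of real trials to violations of those
assumptions — delayed endpoints and prevalence misspecification in
particular are outside what these simulations can show.

Deselected populations are frozen at their stage-1 statistics. In reality an
enriched stage 2 recruited from $S_1$ also adds (non-representative) data to
every population containing $S_1$; the naive pooled estimate for those
populations would then mix two recruitment compositions. The frozen
convention keeps each reported estimator interpretable as an estimate of its
own population effect and matches the published per-population summaries,
which condition either on that population being selected (full enriched
data) or on no selection at all.

## Estimator assessment

The naive MLE of the selected population,
$\hat\theta_w = Z_w^{1:M}/I_w^{1:M}$ at stopping stage $M$, is biased by
selection (only populations that looked good get selected) and further by
reporting (only significant trials get published). `assess_estimates()`
quantifies both on a **standardized scale**: the residual
$r = (\hat\theta_s - \theta_s)\,I_s^{1:M_s}$, i.e. the error in units of the
estimator's nominal standard error at its own information level. Bias/SE is
$\mathrm{mean}(r)$ over a conditioning cell and $\sqrt{MSE}$/SE is
$\sqrt{\mathrm{mean}(r^2)}$. Two facts pin this convention down: the
unconditional single-stage MLE must have bias 0 and root-MSE 1 on this
scale, and stage-wise values must mix into overall values linearly (bias)
and in squares (MSE) with the stopping-stage proportions as weights. Both
identities are verified in the test suite before any table is trusted.

Conditioning cells are `none` (all trials), `selected`, and
`selected+rejected`; family-wise rows use the selected population's residual
in every trial. Empty cells — a population that is never selected under some
configuration — are reported explicitly with proportion 0 and missing
values rather than dropped.

## Worked planning comparison

The two-subgroup planning comparison (effect 0.23 L in FEV$_1$ units,
$\sigma = 0.72$ L, prevalence 0.5, one-sided $\alpha = 0.025$, 80% power,
25 patients recruited per month, endpoint read 3 months after the last
recruit) is reproduced by `compare_strategies(0.23, 0.72)`. Durations use
recruitment time plus the endpoint delay, with the post-interim recruitment
rate scaled by the selected population's prevalence. The two months needed
to conduct the interim analysis are modelled as overlapping continued
conduct — the only reading consistent with all four published durations —
so they do not extend the timeline; separate studies recruit sequentially
from the same 25/month stream.

## Problem sizes used in validation

The bundled tests calibrate the designs exactly as above and validate the
simulation layer at $10^6$ replicates for the headline tables (a few
seconds each in sufficient-statistics mode), $10^5$ replicates for
mode-equivalence and correlation checks, and $2\times10^6$ draws for
Monte-Carlo quantile oracles; these sizes give Monte-Carlo standard errors
comfortably below the differences being tested.

## Known limitations

* Candidate populations must be pairwise nested or disjoint.
* One selection, at the first interim; later stages only stop or continue.
* Threshold-style selection rules are accepted by the simulator as user
  callables but never used for calibration, which assumes the
  maximum-statistic worst case.
* No bias-corrected or conditionally unbiased estimators, and no confidence
  intervals — the assessment layer measures the naive MLE's deficiencies;
  it does not repair them.
* Normal endpoints with common, known $\sigma$; no time-to-event or delayed
  responses.
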