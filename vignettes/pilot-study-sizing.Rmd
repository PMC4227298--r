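---
title: "Sizing external pilot trials: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing external pilot trials: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilotsize)
```

## The question and the model

An external pilot randomised controlled trial is run before a definitive
two-arm superiority trial to estimate the parameters the definitive
sample-size calculation needs: the standard deviation (SD) of a continuous
outcome, or an event rate for a binary one. The pilot's data are set aside
afterwards — its subjects do not contribute to the definitive analysis — so
every subject spent on the pilot buys precision for the design and nothing
else. `pilotsize` puts numbers on that trade-off.

Two generative models are assumed, and everything in the package is
conditional on them:

* **Continuous outcome.** Both arms of the pilot draw i.i.d. normal
  outcomes with a common variance. The pilot is balanced: `n` subjects per
  arm. The analysis is scale- and location-free (precision gains, inflation
  factors and assurance do not change if the outcome is rescaled), so the
  generator's defaults of mean 0 and SD 1 are conventions, not restrictions;
  the scale-equivariance property is asserted in the test suite.
* **Binary outcome.** The event count in a single homogeneous group of size
  `n` is Binomial(`n`, θ). A single arm is modelled directly because event
  rates (consent, recruitment, attrition) are often arm-specific and it is
  generally unsafe to pool arms for a rate that may depend on treatment;
  randomisation bookkeeping would add nothing to the estimands, which depend
  only on the count.

## Continuous pipeline

Each simulated pilot is reduced to the two arms' unbiased sample variances —
the sufficient statistics for everything downstream. The pooled SD is
`SD_p = sqrt((s1² + s2²)/2)` with `df = 2(n − 1)` degrees of freedom. Under
normality `df·SD_p²/σ²` is exactly chi-square, which yields three closed
forms used throughout as deterministic twins of the Monte-Carlo summaries:

* equal-tailed confidence limits `SD_p·sqrt(df/χ²_{hi})` and
  `SD_p·sqrt(df/χ²_{lo})` (`sd_confidence_limits()`);
* the expected estimate `E[SD_p] = σ·sqrt(2/df)·Γ((df+1)/2)/Γ(df/2)`
  (`expected_pooled_sd()`), hence the small-sample bias `E[SD_p] − σ < 0`;
* the expected interval width (`expected_sd_ci_width()`), hence the exact
  precision-gain curve.

The **degrees-of-freedom convention** deserves a note. For a pooled variance
from two arms of `n` the standard df is `2(n − 1)`, and that is what the
package uses everywhere — it is the df under which `df·SD_p²/σ²` is exactly
chi-square. `df` is carried as an explicit field of every estimate rather
than recomputed, so any alternative convention is a one-line change for a
user who needs one. All chi-square quantiles are lower-tail: the `0.975`
quantile caps the *lower* SD limit and the `0.025` quantile the *upper* one.

**Precision gain** is the percentage reduction in mean CI width per grid
step: `100·(W_2n − W_2(n+5))/W_2n` for five subjects added to each group.
Both the simulated mean width and the closed-form width are emitted side by
side in `continuous_precision_table()` (columns `gain_next` and
`gain_next_expected`), because either could reasonably be quoted and their
agreement is itself a useful check; the tests require them to agree within
Monte-Carlo error.

## Planning, inflation, assurance

The definitive trial is sized with the normal-approximation formula
`n/group = ⌈2(z_{1−α/2} + z_P)²·SD²/δ²⌉` and its matching power
`Φ(δ·sqrt(n/2)/σ − z_{1−α/2})`. Two deliberate choices:

* **No noncentral-t variant.** A t-based sample size runs a few subjects
  higher and would break internal consistency with the package's own power
  formula and with the 1,052-subject benchmark (δ = 0.2, σ = 1, 90% power,
  5% two-sided) that anchors the planning tests. One formula, used
  everywhere, was judged better than two subtly different ones behind a
  switch.
* **The omitted tail term.** Exact two-sided power adds
  `Φ(−δ·sqrt(n/2)/σ − z_{1−α/2})`; at the powers studied (≥ 50%) this term
  is below 10⁻⁴ and is dropped so that the power function is the exact
  inverse of the sample-size formula.

**Inflation.** `inflation_factor(df, c) = sqrt(df/χ²_{1−c,df})` multiplies
`SD_p` into its upper one-sided 100·c% confidence limit, so a trial planned
from the inflated estimate reaches its target power with confidence at
least c. Confidence levels below 0.5 are rejected (they would deflate); at
exactly 0.5 the factor is a median-bias correction. The default c = 0.80.

**Assurance** — the probability that the planned trial attains a power
floor — is computed two ways that the tests force to agree: a Monte-Carlo
fraction over simulated pilots, and a closed form. The closed form exploits
that the plan reaches the floor exactly when the planned `n` is at least
the floor's own sample size, which is a threshold event on `SD_p²` and
hence a chi-square tail probability; the `⌈·⌉` rounding enters through a
`> n_floor − 1` threshold (the boundary has probability zero under the
continuous model). Degenerate estimates (`SD_p = 0`) cannot arise under
that model; if handed in they are excluded from planning with a warning and
a count, rather than mapped to the minimum sample size, because they signal
upstream misuse.

Plan distributions are summarised by percentiles (min, 2.5, 25, 50, 75,
97.5, max — enough to reconstruct a box-and-whisker display) using R's
default quantile type 7, linear interpolation between order statistics.

## Binary pipeline

Event-rate precision uses the Wilson score interval, which never leaves
[0, 1]; the normal quantile is kept at full double precision rather than
1.96 so enumeration and simulation stay mutually consistent. At `y = 0` and
`y = n` the score bounds are exactly 0 and 1, and the implementation snaps
away the floating-point residue so boundary cells are exact. Coverage uses
the closed interval (endpoint equality counts as covering); this matters
only at discreteness boundaries.

Every cell summary — mean estimate, bias, mean width, coverage — exists in
two modes. `method = "simulate"` mirrors a Monte-Carlo study: replicates
per cell follow `required_reps_binary(θ, 0.001)` = `⌈θ(1−θ)/SE²⌉` with a
floor of 10,000, which peaks at 250,000 replicates at θ = 0.5 (the ceiling
is taken with a 10⁻¹⁰ relative slack so an exactly attainable target is not
pushed up by floating-point noise). `method = "enumerate"` computes the
same quantities exactly as `Σ_y P(Y = y)·q(y)`; at the sizes studied
(n ≤ 200) this is both faster and exact, and it is the oracle against which
the simulated mode is tested on the full grid.

## Reproducibility and seeding

A single master seed in `study_config()` deterministically derives an
independent sub-stream seed for every grid cell via `cell_seed()` (a small
polynomial hash of the seed and cell labels, kept below 2³¹). Cells can
therefore be recomputed in any order, or singly, and reproduce a full run
bit for bit; `run_study()` is byte-reproducible from its own
`manifest.json`. Each pilot size draws its replicates independently — no
replicate sharing across sizes — which keeps cells exchangeable at the cost
of slightly noisier *differences* between adjacent sizes.

## Study defaults and grids

| Parameter | Default | Rationale |
|---|---|---|
| continuous per-group sizes | 10–80 by 5 | spans "too small to trust" to "clearly adequate" for SD estimation |
| replicates per continuous size | 10,000 | mean-SD summaries stable to ~0.002 |
| binary sizes | 10–200 by 5 (39 sizes) | single-arm rates need larger n; steps of five since one arm grows |
| true rates θ | 0.10–0.50 by 0.05 | symmetric beyond 0.5; 0.5 is the variance worst case |
| binary SE target | 0.001 | fixes mean-rate error to the third decimal |
| effect sizes δ | 0.2, 0.35, 0.5 | small-to-medium standardised differences, the realistic RCT range |
| α, target power | 0.05 two-sided, 0.90 | conventional definitive-trial settings |
| power floor | 0.80 | the lowest power most funders tolerate |
| inflation confidence | 0.80 | illustrative "guarantee power 4 times in 5" |

## What the generator does and does not emulate

The generator reproduces exactly the statistical structure the estimators
assume: normal outcomes with equal variances in balanced arms, and binomial
counts in one arm. Real pilot data depart from this in ways the simulations
do not probe: skewed or heavy-tailed outcomes (the chi-square interval for
an SD is not robust to non-normality), unequal arm variances or sizes,
clustering, dropout, and rates that drift over recruitment time. Passing
tests therefore certify the machinery under its stated model, not the
behaviour of these estimators on arbitrary real data.

## Problem sizes used by the tests

The shipped test suite runs the full grids where computation is exact
(enumeration over all 9 × 39 binary cells) and scales Monte-Carlo sizes to
what the statistical tolerance actually needs: 10,000–200,000 replicates
for continuous-grid checks, a 10⁶-replicate run for the small-bias check at
total size 60, 100,000 pilots for the assurance cross-check, and 4,000
replicates per binary cell for the grid-wide simulation-versus-enumeration
sweep (asserted within 5 Monte-Carlo SEs per cell, with at least 99% of
cells within 4 — across 702 fixed-seed checks a lone ~4-SE excursion is
expected by chance). All tolerances are stated in the tests in
Monte-Carlo-SE units so they scale if replicate counts are changed.

## Known limitations

* Binary-outcome work stops at estimation precision; the package does not
  size a definitive trial for a binary endpoint.
* Only the Wilson interval is offered; Clopper–Pearson, Agresti–Coull or
  Wald comparisons are out of scope.
* The continuous pipeline assumes balanced arms and equal variances;
  Welch/Satterthwaite machinery is deliberately absent.
* Assurance is frequentist (conditional on a known true SD); Bayesian
  assurance with a prior on the effect size is not implemented.
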