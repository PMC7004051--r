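---
title: "Reference-based multiple imputation for cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based multiple imputation for cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcea)
```

## The problem

Cost-effectiveness analyses (CEA) alongside randomised trials almost always
face incomplete follow-up: participants withdraw, skip a quality-of-life
questionnaire, or their resource-use records cannot be retrieved. The primary
analysis typically imputes under *missing at random* (MAR) — missingness is
explained by what was observed. That assumption is untestable, and in many
trials it is suspect: participants doing poorly are plausibly the ones who
stop returning questionnaires, which is *missing not at random* (MNAR).

Reference-based multiple imputation frames MNAR sensitivity analyses
qualitatively instead of through hard-to-elicit numerical offsets: missing
outcomes for a participant who dropped out of the active arm can be imputed
as if that participant's post-dropout distribution *jumped to* the control
("reference") arm, on the reasoning that they likely stopped receiving the
intervention. `refcea` implements this pattern-mixture approach jointly for
a repeated quality-of-life (utility) endpoint and a cost endpoint, with the
downstream economic evaluation (QALYs, Rubin's rules, ICER, CEAC) built in.

## The model and algorithm

Outcomes for each participant are collected in a joint vector ordered as
`[covariates | utility by time | costs by time]` (dimension
`ncov + Je + Jc`). The algorithm is:

1. **Per-arm MAR model.** For each arm separately, fit a multivariate normal
   (MVN) model to the joint vector using the observed data under MAR.
2. **Posterior draw.** Draw a mean vector and covariance matrix from the
   model's posterior.
3. **Pattern-specific joint.** For each participant with missing data, build
   the joint distribution of their observed and missing components under the
   chosen assumption (below).
4. **Conditional imputation.** Draw the missing block from its conditional
   normal given the participant's observed values.
5. **Repeat** steps 2–4 `m` times; analyse each completed dataset and pool
   with Rubin's rules.

### Assumption menu

With `D` the participant's last observed time index within an endpoint,
`mu^rand` / `mu^ref` the arm mean draws, the mean of the pattern-specific
joint at a post-dropout time `j > D` is:

| assumption | post-dropout mean | covariance |
|---|---|---|
| MAR  | `mu^rand_j` | randomised arm |
| J2R  | `mu^ref_j` | composed (below) |
| CIR  | `mu^rand_D + (mu^ref_j - mu^ref_D)` | composed (below) |
| LMCF | `mu^rand_D` | randomised arm |
| BMCF | `mu^rand_baseline` | randomised arm |

For J2R and CIR the covariance keeps the randomised arm's marginal over the
pre-dropout block `P` and takes the conditional law of the post-dropout block
`Q` given `P` from the reference arm. Writing
`B = Sigma^ref_QP (Sigma^ref_PP)^-1`:

```
Sigma~_PP = Sigma^rand_PP
Sigma~_QP = B Sigma^rand_PP
Sigma~_QQ = Sigma^ref_QQ - B (Sigma^ref_PP - Sigma^rand_PP) B'
```

`build_covariance_j2r_cir()` implements this and is property-tested against a
two-stage sampling oracle. For a participant already in the reference arm,
J2R and CIR reduce exactly to MAR; LMCF and BMCF never read the reference arm
at all — they displace the randomised arm's own mean trajectory, so no such
reduction applies to them.

### Joint cost/effectiveness endpoints, differential assumptions, interim gaps

The two endpoints need not share an assessment schedule or a missingness
pattern. Each endpoint gets its own assumption (`endpoint_assumptions()`),
with the restriction — deliberate, mirroring the method's current scope —
that two *different* MNAR families cannot be combined; one endpoint must then
be MAR. A participant's missing variables are split into a MAR block
(endpoints under MAR, plus interim-missing values under the default
`interim = "mar"` policy) and an MNAR block. The joint is composed so that
the marginal over everything except the MNAR block is the randomised-arm
draw and the conditional of the MNAR block given the rest follows the
assumption. Interim-missing values (missing at one visit, observed later)
are MAR by default; under `interim = "dropout"` they obey the same
reference-based rule, anchored at the last observation before the gap.

Two boundary conventions are worth stating. BMCF needs a baseline
measurement; a cost endpoint consisting of a single total-cost variable has
none, so BMCF on such an endpoint falls back to MAR for costs — which is how
the scenario is used in practice when costs are not collected at baseline.
And covariates are pre-randomisation quantities, so no assumption ever
switches their parameters.

## Numerical and sampling choices

* **Sampler.** The per-arm fit is a data-augmentation Gibbs sampler under
  the Jeffreys prior `p(mu, Sigma) ∝ |Sigma|^-(d+1)/2`: impute missing cells
  from their conditional normals, then draw `Sigma` from its inverse-Wishart
  full conditional (`df = n - 1`) and `mu | Sigma ~ N(ybar, Sigma/n)`.
  Participants sharing a missingness pattern are updated in one vectorised
  step, so an iteration costs a handful of small solves regardless of `n`.
  Defaults (`sampler_settings()`): `m = 100` retained draws, burn-in 500,
  thinning 100 — near-independent retained draws at trial scale. The
  original method description fixes none of these; they are package
  defaults, exposed in the settings object. Tests use lighter settings
  (burn-in 50–100, thinning 2–3), adequate because the low-dimensional DA
  chain mixes in a few iterations.
* **Initialisation** is from complete cases; with fewer than `d + 2`
  complete rows, available-case means and a ridge-regularised covariance.
  Whenever a Cholesky factorisation fails, `1e-8 * trace/d` is added to the
  diagonal once; an error follows if that does not repair definiteness.
* **Imputation noise** is one standard-normal deviate per (copy,
  participant, variable), with per-participant substreams derived from the
  master seed and the participant identifier. Results are invariant to row
  order. Missing variables are drawn sequentially from the pattern joint —
  MAR block first (costs before utilities), then the MNAR block. Sequential
  conditionals from a joint MVN are exact in any order; this one guarantees
  that scenarios sharing a seed reuse identical deviates for their common
  MAR components, so, e.g., imputed costs under "J2R-MAR" equal those under
  "MAR" *exactly* and scenario contrasts carry no Monte-Carlo noise.
* **Degenerate inputs.** A variable observed fewer than twice in an arm, a
  singular observed block, and an all-missing baseline are errors; a
  completely observed dataset passes through every stage unchanged.

## The CEA pipeline

QALYs are the trapezoidal area under the utility curve (linear change
between assessments; no discounting over the 1-year horizon). Incremental
QALYs and costs are unadjusted between-arm mean differences; with identical
regressors the seemingly-unrelated-regressions system coincides with
per-outcome least squares, and the coefficient covariance is
`(1/n0 + 1/n1)` times the pooled residual covariance — verified against a
brute-force resimulation oracle. Rubin's rules give
`T = W + (1 + 1/m) B` and Barnard–Rubin-style degrees of freedom
`(m-1)(1 + W/((1+1/m)B))^2`; confidence intervals use the t distribution,
collapsing to the normal when `B = 0`. The CEAC uses the pooled-coefficient
normal approximation `P(lambda) = Phi(INB / sd(INB))` on the pooled 2×2
covariance rather than averaging per-copy probabilities or bootstrapping:
it is deterministic, fast, and matches the SUR-based description of the
analysis; the pooled-coefficient route is a documented choice where both
conventions exist. The default willingness-to-pay grid is 0–50,000 in steps
of 500, with 20,000 per QALY as the reporting threshold.

`run_sensitivity_suite()` fits the posterior once and reuses the draws and
noise streams across scenarios (`MAR`, `J2R`, `J2R-interim`, `J2R-MAR`,
`BMCF` by default, mapping to the endpoint assumptions described above), so
a table of scenarios differs only through the assumptions.

## The synthetic-trial generator

Because individual-level trial data of this kind are not publicly
deposited, `cobalt_preset()` emulates the structure of a two-arm
psychotherapy trial in treatment-resistant depression: arms of 235 and 234
participants; EQ-5D utilities at baseline, 6 and 12 months; one total-cost
variable; baseline age, sex and depression-severity covariates. Utility and
cost means and SDs equal the published arm-level summary statistics of that
trial; the within-arm correlation structure is *not* published and is set
to values typical of repeated utility measures (serial utility correlations
0.5–0.65, utility–severity −0.3 to −0.45, utility–cost −0.15). Missingness
is MAR: a per-visit logistic dropout hazard on the last observed utility
(slope −1.5 per utility unit — poorer health, more dropout), a 1.9% interim
miss rate, and cost missingness coupled to effectiveness status (certain
after dropout, 76% after an interim miss, 5% otherwise). Intercepts
(−1.63, −1.66) were calibrated once, by coarse grid search over replicate
trials, to the published pattern frequencies (≈78.5% completers, ≈9% with
no follow-up data); the mechanism is not uniquely identified by those
frequencies, so the calibration is approximate by design.

What the generator does *not* emulate: utilities are unbounded normals
(clipping to the EQ-5D range is available via `clip_qol` but off by
default so estimator tests stay exact); costs are normal, truncated at zero
(count flagged on the truth object), not skewed; sex is a moment-matched
normal column rather than binary. Passing tests therefore demonstrate
correctness of the algorithmic contracts under an MVN world — the model's
own assumption — not robustness to non-normality.

## Problem sizes used in the test-suite

The shipped tests exercise: exact pattern-percentage arithmetic on the
published count table; conditioning against a precision-matrix oracle on
10³ random 4-dimensional cases; the J2R covariance against a 10⁵-draw
sampling oracle; mean-rule fidelity over 10⁴ imputed copies of one
participant; unbiasedness of the MAR analysis over 200 replicate MCAR
trials of 500 per arm with `m = 20`; and the full five-scenario preset
suite at `m = 100`. These sizes put Monte-Carlo error comfortably below
each asserted tolerance.

## Known limitations

* MVN imputation model throughout; no predictive-mean-matching or other
  non-normal engines.
* Two arms (one reference); continuous endpoints only — no binary or
  time-to-event effectiveness measures.
* No covariate-adjusted CEA, cost-component breakdowns, or discounting.
* Distinct MNAR families on the two endpoints simultaneously are rejected
  by design.
* The information-anchoring behaviour of Rubin's rules under
  reference-based imputation is checked only empirically (a variance-ratio
  surrogate), not proved.

## A worked example

```{r example, eval = FALSE}
cfg <- cobalt_preset()
trial <- generate_trial(cfg, seed = 11)$observed
suite <- run_sensitivity_suite(trial, seed = 5)
suite
```

See the README for the printed output of this exact call and its reading.
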