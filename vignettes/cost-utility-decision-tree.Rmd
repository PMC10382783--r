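---
title: "Decision-tree cost-utility analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-utility analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuatree)
```

## The decision problem

`cuatree` evaluates a two-arm decision tree for a hospital pharmaceutical-care
comparison: a collaborative, pharmacist-led medication reconciliation service
(the intervention arm, displayed as *PACT*) against routine ward-based
clinical pharmacy (the reference arm, *SC*, standard care). The branching
event is discharge medication error. Each patient receives the arm's labour
cost with certainty; with probability $p$ the patient experiences one or more
discharge medication errors and accrues the mean cost of managing the
hypothetical downstream harm plus a loss in health-state utility. Patients
without an error are assumed to have no change in health-related quality of
life, so effects are expressed as QALY *decrements* relative to a zero
no-error baseline — expected effects are non-positive by construction, and
absolute QALYs are out of scope.

Per arm,

$$
E[\text{cost}] = p \cdot c_{\text{error}} + c_{\text{labour}}, \qquad
E[\text{effect}] = p \cdot d,
$$

with $d \le 0$ the utility decrement. The incremental analysis compares the
arms by $\Delta C$, $\Delta E$, the incremental cost-effectiveness ratio
$\mathrm{ICER} = \Delta C / \Delta E$ (defined only when $\Delta E \neq 0$),
and the net monetary benefit $\mathrm{NMB}(\lambda) = \lambda \Delta E -
\Delta C$ at willingness-to-pay $\lambda$ (EUR/QALY). The time horizon is one
year, so no discounting is applied anywhere in the package.

A negative ICER is ambiguous on its own: both "cheaper and better" and
"costlier and worse" produce negative ratios. Dominance is therefore
classified from the sign quadrant of $(\Delta C, \Delta E)$ and always
reported next to the ratio. Boundary pairs with exactly one zero component
are grouped with the adjacent trade-off quadrant (by the sign of $\Delta E$,
then $\Delta C$); the exactly-zero case is labelled `equivalent`. These
boundaries have measure zero under any continuous parameter distribution, so
the grouping is a reporting convention, not a modelling choice.

## Parameters and the base case

The eight stochastic base parameters are, per arm: the error probability
$p$, the error-consequence cost (EUR), the per-patient labour cost (EUR) and
the utility decrement (QALY). `base_case_config()` packages the published
evaluation's inputs; the same structure can be read from YAML/JSON with
`load_config()`, which rejects unknown keys and enforces all invariants at
load time (probabilities in $[0,1]$, non-negative costs, non-positive
decrements, a strictly increasing willingness-to-pay grid).

Two deliberate precision choices:

* the utility decrements are carried at full precision
  ($-0.02906349626$ and $-0.023469269$) rather than the 3-decimal values
  shown in summary tables — only the full-precision values reproduce the
  published expected effects to 9 decimals;
* all computation is done in full precision, with rounding to cents
  (monetary) and 9 decimals (effects) applied only in reporting functions
  such as `base_case_table()`.

The default willingness-to-pay grid is 0–50,000 EUR/QALY in steps of 1,000,
spanning the 45,000 EUR/QALY threshold conventionally used for
pharmaceutical reimbursement in Ireland.

## Labour costing

Pharmacist cost per minute is derived from the salary mid-point and three
flat on-cost rates (employer PRSI 10.75%, imputed pension 13.10%, overheads
40%), divided by productive hours. The productive year is modelled as a
365.25-day year with a 5/7 working-day fraction, minus 24 leave days and 9
public holidays, at 37 contracted hours per week less a one-hour daily
break:

```{r labour}
labour_cost_table(base_case_config()$labour)
```

This calendar convention reproduces the published per-hour figures
(55.00183 and 72.44773 EUR) to four significant figures; every element of
the calendar is configurable, so an alternative convention is one config
edit. One known discrepancy is documented rather than patched: the mean
intervention contact time of 72.8 minutes times 1.2074622 EUR/min gives
87.90 EUR where the published text prints 87.91 EUR — consistent with an
underlying mean time less rounded than "72.8". The salary mid-points are
inputs, not computed from pay-scale tables, which are external documents.

## Bootstrap stage

Cost estimates in the evaluation are bootstrap means: `bootstrap_mean_ci()`
resamples with replacement (1000 replications by default) and summarises the
replicate means with their mean, their standard deviation, and a
*percentile* confidence interval. The percentile method is an assumption —
the original macro-based analysis does not state its CI method — but it is
consistent with the printed asymmetric intervals. The replicate-mean SD is
exposed because the PSA's gamma hyperparameters are parameterised from it
(below).

## One-way deterministic sensitivity analysis

Each of the eight parameters is varied one at a time: over its 95% CI when
one is available (the cost parameters), otherwise by $\pm 20\%$ of the mean
(probabilities, decrements), with explicit per-parameter overrides possible.
For a negative decrement, "mean $\times (1 \pm 0.2)$" scales the magnitude
with the sign, so the `low` bound is the smaller-magnitude one; results are
keyed by bound value, never by column position. Probability bounds escaping
$[0,1]$ are clipped with a warning rather than rejected, since generic
configurations may place $p$ near 1. `tornado_order()` sorts by the absolute
ICER range, breaking ties lexicographically by parameter id.

## Probabilistic sensitivity analysis

Parameters are sampled independently (the source analysis specifies no
correlation structure): beta for probabilities, gamma (shape/scale, so
shape × scale = mean) for costs, and a shifted-and-flipped gamma for the
decrements — a gamma is moment-matched to $1 + |d|$ and draws are returned
as $1 - X$, giving mean $d$. Method-of-moments fits:

$$
\text{beta: } \alpha + \beta = \frac{m(1-m)}{SE^2} - 1,\;
\alpha = m(\alpha+\beta); \qquad
\text{gamma: } \alpha = \frac{m^2}{SE^2},\; \beta = \frac{SE^2}{m}.
$$

The standard-error conventions behind the published hyperparameters are the
largest gap in the source material, so the package separates two documented
modes:

* **Reproduction mode** (the default; the packaged base case): the published
  hyperparameters are used verbatim as overrides. This is the faithful way
  to re-run the published PSA.
* **Derivation mode**: hyperparameters are rebuilt from the point estimates
  under reconstructed conventions — probabilities use $SE = 0.2/\sqrt{n}$
  with $n$ the sample size behind the estimate (101 and 108, reconstructed
  from the 66 and 15 error cases at the observed prevalences); bootstrap
  costs use $SE = \text{replicate-mean SD}/\sqrt{1000}$; decrements use
  $SE = \text{SD}/\sqrt{n}$ with $n$ the arm's error-case count. The first
  two conventions reproduce every verifiable published beta/gamma pair to
  within 0.1%. The decrement convention is principled but does *not*
  reproduce the published decrement hyperparameters, which back-solve to
  mutually inconsistent conventions across the two arms
  ($\approx \mathrm{SD}/\sqrt{65}$ for one, $\approx 0.2/\sqrt{108}$ for the
  other); derivation mode is therefore flagged as a methodological
  reconstruction, and reproduction mode is used wherever fidelity matters.

Two numerical notes. First, the published decrement hyperparameters are
printed with few significant digits (e.g. a gamma scale of 0.00008), so the
implied decrement means in reproduction mode differ visibly from the point
estimates; this does not affect any qualitative result — the intervention
dominates in every draw regardless. Second, the fitted decrement gammas
place non-trivial mass on *positive* "decrements" (utility gains): about
5×10⁻⁴ for the reference arm and, under the printed-convention SE for the
intervention arm, about 0.11. That is a property of the moment-matched
distributions at these means and SEs, not an implementation artefact; draws
are deliberately not truncated, which would bias the mean.

The PSA records one $(\Delta C, \Delta E)$ pair per iteration (1000 by
default, seed always recorded); ICERs are computed lazily from the pairs so
zero-effect draws are kept, never dropped. The cost-effectiveness
acceptability curve reports, at each $\lambda$ on the grid, the fraction of
draws with strictly positive NMB — a draw with NMB exactly zero counts as
not cost-effective.

```{r psa}
fit <- cua()
draws <- simulate(fit, nsim = 1000, seed = 1)
summary(draws)
head(ceac(draws), 3)
```

## Synthetic cohorts

`generate_cohort()` emulates the patient-level structure the analysis
assumes so the bootstrap and estimation stages run end-to-end without
external data: contact minutes and per-error-patient costs use gamma
marginals moment-matched to the requested mean/SD (non-negative,
right-skewed; the source states no patient-level distributions, so this is
the package's stand-in structure), the error flag is Bernoulli, and
decrements use the one-minus-gamma construction. Error costs are generated
per patient, matching the model's per-patient payoff. Defaults follow the
study's summary statistics: arm sizes 101/108, prevalences 0.653/0.139,
contact minutes 40.6 (SD 29.17) and 72.8 (SD 52.47). The per-patient
dispersion of error costs is not recoverable from the published summaries
(the printed SDs are bootstrap replicate-mean SDs), so the generator
defaults to a coefficient of variation of 1 — a typical order for
right-skewed healthcare cost data — and exposes it as a free knob.

What passing tests on synthetic cohorts show is internal consistency:
parameters fed into the generator are recovered by the estimation pathway,
and the full synthetic pipeline agrees with the deterministic base case up
to sampling error. They do not validate the distributional assumptions
against real patient-level data, nor the within-patient multiple-error
structure (203 errors across 81 cases in the source study is summarised,
not modelled).

## Problem sizes and reproducibility

The test suite sizes its simulations to keep the full run under a minute on
one CPU while leaving comfortable statistical margins: 1000-iteration PSAs,
bootstrap-coverage checks over 500 samples of size 30 with 400 replications,
and parameter-recovery checks over 100 replicate cohorts of 2000 patients
per arm. One recovery tolerance deserves a note: at that problem size the
Monte-Carlo SE of the pooled intervention-arm decrement is about 2% of its
mean, so that single parameter is checked against 3 Monte-Carlo SEs where
the others are checked at 1% relative error — a tighter bound would test the
random number generator, not the generator's bias. All stochastic stages
take explicit seeds, per-stage seeds in the pipeline are derived from one
master seed, and two runs with identical configuration and seed produce
byte-identical CSV outputs.

## Limitations

* Two arms only; no Markov/state-transition extension, microsimulation,
  discounting, or budget-impact / expected-value-of-perfect-information
  analysis.
* Parameter independence in the PSA; no copulas or correlation structure.
* The decision tree prices *intercepted* errors via elicited hypothetical
  consequences; the package inherits that framing through its inputs.
* Derivation mode is a reconstruction of undocumented conventions; where it
  conflicts with the published hyperparameters (the decrements), the
  published values win via reproduction mode.
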