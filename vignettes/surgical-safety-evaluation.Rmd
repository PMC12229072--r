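---
title: "Evaluating an AI surgical-safety system: incident statistics, simulation and economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an AI surgical-safety system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgsafe)
```

## The problem

An AI authentication system checks three things before an ophthalmic
operation starts: that the patient is who the record says (facial
recognition), that the prepared side matches the planned laterality, and
that the prepared intraocular lens (IOL) is the one selected for this
patient. A before/after implementation cohort of such a system poses three
statistical questions, and this package answers each with a dedicated
module:

1. Did detected incidents change? (rates, confidence intervals, odds
   ratios, exact tests on two-period counts);
2. What generative process is consistent with the observed counts? (a
   synthetic case-log simulator, which also makes every downstream
   statistic testable without patient data);
3. Is the system worth its cost? (a five-year cost–benefit /
   cost-effectiveness model with sensitivity analysis).

## The authentication outcome taxonomy

Every checkpoint of every operation resolves to exactly one of five
outcomes: **not performed** (authentication never attempted — e.g. during
the adoption ramp), **successful**, **near miss** (a mismatched
preparation was flagged and corrected before surgery), **error** (surgery
proceeded wrong: the mismatch was missed, the stage was skipped, or the
alert was not acted on), and **authentication failure** (no capture met
the image-quality standard and surgery proceeded at the surgeon's
discretion). `classify_outcome()` is the pure, total implementation of
this taxonomy, with precedence *not performed* → *authentication
failure* → *near miss* → *error* → *successful*. One wording note: we
read "the AI incorrectly identifies a case" in the near-miss definition
as "the AI identifies an incorrectly prepared (mismatched) case" — i.e.
a true alert, corrected in time — which is the only reading consistent
with near misses being a detection success.

## Incident statistics and the choice of interval

The confidence-interval method behind published incident rates is often
unnamed. Reproduction pins it down here: the two-period cohort rates
(5/18 762, 1/18 767, 30/18 762, 9/18 767) match the exact
**Clopper–Pearson** interval at printed rounding, while the
per-checkpoint rates (7/18 762 laterality, 28/9 713 IOL) match the
**Wilson score** interval — Clopper–Pearson would give a laterality lower
bound of 0.015%, not the published 0.018%. Both methods are implemented
(`proportion_ci_cp()`, `proportion_ci_wilson()`) and the defaults follow
that mapping; `rate_table()` reports both side by side.

Association uses the sample odds ratio with the **Woolf logit** interval
(`odds_ratio_woolf()`). Zero cells are a hard error asking for an
explicit continuity correction — a silent +0.5 would change reported
values. The published near-miss interval (1.59–7.01) differs from the
Woolf bounds (1.584–7.032) by up to 0.03, so those two bounds are
compared with that tolerance rather than at printed rounding; the
published interval's exact method is unknowable from the text.

`fisher_exact_two_sided()` is self-contained: with margins fixed the
first cell is hypergeometric, and the two-sided p sums the probabilities
of all tables no more probable than the observed one (the "small-p"
convention, with a `1 + 1e-7` relative guard on ties — the same guard
base R uses — so floating-point noise cannot drop a tied table). This
convention reproduces both published p-values (0.00067 for near misses,
0.125 for errors); tests verify it against exhaustive enumeration and
against `stats::fisher.test`.

## The synthetic cohort generator

`simulate_cohort(sim_config(...))` draws a full two-period case log. Its
defaults *are* the study conditions: 18 767 pre / 18 762 post surgeries,
51.8% of cases with IOL implantation, 7.3% of IOL cases involving a lens
model the system has not learned (never flaggable), a monthly adoption
ramp `c(0.845, 0.93, 0.99, 0.994, ...)` over 25 post-implementation
months anchored to the two published rates (84.5% initial vs 99.4%
steady-state; the ramp is only available graphically, so the first three
months interpolate), per-stage quality-failure rates 0.25% / 0.24% /
0.66%, and shifted-geometric attempts (means 1.13 / 1.05 / 1.15) with
log-normal durations (means 11.8 s / 3.10 s / 8.57 s, `sdlog` 0.5) —
the simplest non-negative families matching the published means, which
are given without dispersion.

Choices the data do not fix, made once and documented here:

* **Latent preparation-error rates** default to 4.0 × 10⁻⁴ per case
  (laterality) and 3.1 × 10⁻³ per IOL case — round values chosen so that
  the expected *flagged* counts at the default adoption, quality and
  detection parameters land near the observed 7 laterality and ~28 IOL
  flags per study period (the latent rate must exceed the flag rate
  because unlearned and unauthenticated preparations are never flagged).
* **Detection and correction** given a quality-passing authentication of
  a learned item default to 1 — pre-implementation bench testing showed
  100% accuracy and all flagged cases in the study were corrected.
  `p_correction < 1` models an ignored alert (one such case occurred).
* **Pre-implementation reporting**: a latent error is caught by staff and
  reported as a near miss with probability `p_human_report` (default 0.3,
  a free under-reporting parameter, not an estimated quantity). An
  uncaught latent error proceeds to surgery; we mark it `final_error` and
  `reported = TRUE`, on the reasoning that completed wrong-site/wrong-IOL
  surgeries surface clinically even where near misses go unreported. This
  makes the simulated pre-period *error* count track the latent rate, not
  the (likely under-counted) published single error — deliberately so,
  since the study itself argues its baseline error rate was
  under-reported.
* **Month granularity** for the ramp, matching the published monthly
  implementation-rate axis; cases are spread uniformly over months.

The generator is vectorised and draws every stochastic variable once, in
a fixed order, for all cases. Two consequences matter: identical seeds
give identical case logs, and two runs differing only in a probability
parameter are coupled by common random numbers — which is how the test
suite verifies, exactly rather than statistically, that raising
`p_detect_given_auth` never decreases near misses and never increases
final errors.

What the simulator does **not** emulate: real seasonal case-mix,
per-surgeon clustering, correlation between stages within a case beyond
shared latent errors, severity grades of errors, and any image-level
mechanism. Passing tests therefore demonstrate the *statistical* pipeline
on a faithful generative skeleton, not the behaviour of recognition
models on real images.

## The economic model

`econ_config()` holds the published inputs: a five-year horizon, 3%
annual discounting, and present-value totals of US\$461 426.49 (AI) vs
US\$125 872.46 (traditional safety measures). Numerical conventions:

* **Cost timing.** A scalar cost is a present-value total and enters the
  ICER as-is — the published ICER arithmetic
  ((461 426.49 − 125 872.46)/18 = 18 641.89 to the cent) shows the totals
  were used directly. A per-year schedule, if supplied, is discounted
  end-of-year (year 0 undiscounted).
* **Effectiveness.** `Effect_AI(π) = 4 + π × 30` (directly attributable
  preventable errors plus the fraction π of intercepted near misses that
  would have progressed), `Effect_trad = 1`. The incremental effect of 18
  at π = 0.5 is a *reconstruction*: it is the only value consistent with
  the published costs and ICER, and it equals 4 + 15 − 1.
* **Benefits.** Per-error benefit = treatment cost + legal compensation +
  reputation-driven revenue loss, spread evenly over years 1..horizon and
  discounted. The study's component values live in its cost supplement;
  the package defaults are round placeholders (15 000 / 80 000 / 25 000
  USD) and `calibrate_benefit()` rescales them in closed form (NPV is
  affine in the per-error benefit) so the intermediate-scenario NPV
  matches any externally supplied figure. The published NPV point value
  and benefit range are therefore *inputs to calibration*, never computed
  claims of this package.
* **Two NPVs, labelled.** Whether a published NPV is incremental to the
  comparator or absolute for the AI system is ambiguous; `npv()` returns
  both: `npv` (incremental effect × benefit − cost difference) and
  `npv_absolute` (AI-prevented errors × benefit − full AI cost).
* **Undefined ICERs** (zero incremental effect) return `NA` with a
  `dominance` label instead of a division error; negative ICERs are
  labelled dominant.

`one_way_sensitivity()` perturbs each of the seven levers (two costs,
three benefit components, the near-miss count, the direct-error count) by
±20% and orders the results by range — the tornado. With the benefit
calibrated to the published intermediate NPV, every single perturbation
keeps the NPV positive and the scenario NPVs order conservative <
intermediate < high-risk, which is the robustness claim the tests assert.

`monte_carlo_psa()` draws costs from uniform(±20%) and benefit components
from gamma distributions (mean at the point value, coefficient of
variation 0.2) — uniform for bounded accounting totals, gamma for
non-negative loss components; both are configurable and collapse to
degenerate points at zero spread, which the tests exploit: zero-variance
runs must reproduce the deterministic NPV to 10⁻⁹ relative, a fixed seed
must reproduce draws byte-exactly, and a single-uniform-parameter
configuration must match the analytic uniform quantiles within Monte
Carlo error. The 95% interval is the non-parametric 2.5/97.5 percentile
pair (the published CI's method is unnamed; percentiles make the fewest
assumptions).

## Problem sizes and determinism

The test suite runs the simulator at up to 25 000 + 25 000 cases across
20 seeds for parameter recovery (pooled estimates within 3 pooled
standard errors of the configured probabilities), 200 full-scale
post-period replicates for the analytic flagged-count check, 500 random
small tables for Fisher enumeration equivalence, and 10 000-iteration
PSAs — sizes chosen so the whole suite completes in well under a minute
of simulation time while leaving the statistical assertions
well-powered. Every stochastic test fixes its seed; `run_pipeline()`
writes reports without timestamps so identical configurations produce
byte-identical files.

## Known limitations

Single-centre, before/after structure is inherited: nothing here adjusts
for temporal confounding or case-mix drift between periods (the published
age difference between periods is real but unmodelled). The Fisher test
enumerates the first-cell support, which is exact but not meant for
tables with events in the thousands. The economic model is a
decision-analytic projection, not a trial-based costing: its absolute
NPVs are only as good as the benefit components supplied to
`calibrate_benefit()`, and no QALY weighting or currency conversion is
attempted.
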