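---
title: "A Markov cohort cost-utility model for bipolar disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for bipolar disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmarkov)
```

## The model

bdmarkov implements a decision-analytic Markov cohort model for estimating
the long-term cost-effectiveness of relapse-prevention interventions in
bipolar disorder. A cohort is followed in quarterly (three-month) cycles
through four health states: **remission**, **depression**, a **mood
episode** — mania for bipolar-I, hypomania for bipolar-II — and **death**,
which is absorbing. Because the two subtypes differ in disease course
(relapse destination mix, time spent manic vs hypomanic) and in quality of
life during an episode, the model runs *two separate traces*, one per
subtype, and combines their incremental costs and effects with the subtype
prevalence weights 0.600 (BD-I) / 0.400 (BD-II) before forming a single
incremental cost-effectiveness ratio (ICER). Weighting is applied to the
incremental costs and QALYs, never to per-subtype ICERs: ratios do not
average.

Each cycle the alive-state occupancy vector is advanced by a 3×3
row-stochastic matrix (the standard-of-care transition probabilities), after
background mortality has been embedded by competing risks: the death
probability of the origin state is removed first and the alive destinations
are scaled by the survivor fraction. Age-specific general-population
mortality is inflated by a mortality rate ratio of 2.06 in every alive state
(comorbidity and lifestyle excess) and, in the depression state only, by an
additional suicide mortality rate ratio of 9.66, combined multiplicatively
on the hazard scale by default (an additive-on-rate alternative is
provided, since the evidence base reports only "an additional" ratio without
a combination rule).

An intervention is described by four quantities: relative risks for entering
depression and for entering the mood episode state, a per-cycle cost, and
two durations — how many cycles the effect persists and how many cycles the
cost is incurred. By default the relative risks scale only the relapse
transitions out of remission (`scope = "relapse_only"`); the alternative
`"all_entries"` scope additionally scales the switch transitions between
depression and the episode state. The conservative default reflects that
relapse-prevention trials measure recurrence from remission. The packaged
default intervention is a mindfulness-based cognitive therapy added to the
standard of care: relative risks 0.81 (depression) and 1.32 ((hypo)mania)
over four cycles, at 291 euro for a single cycle.

## Deriving cycle-level probabilities

Published evidence arrives on annual or study-specific time scales; the
model includes the calculus to move it onto the quarterly cycle:

* `convert_probability_period(p, f)` converts probabilities between periods
  under a constant-hazard assumption, `1 - (1 - p)^f`. The 21.9% annual
  any-relapse recurrence becomes the quarterly 5.99%. This is the standard
  actuarial conversion; it also reproduces the packaged relative risks from
  the underlying trial's 12-month recurrence rates (0.81 and 1.32), which is
  why it was adopted.
* `split_relapse_probability(p, ratio)` divides a total relapse probability
  between depression and (hypo)mania in proportion to a depression/mania
  time ratio (defaults 4.7 for BD-I, 10.7 for BD-II). The packaged
  transition rows are shipped as literals rather than recomputed from this
  split: the published calibration that produced them is not fully
  specified, and re-splitting 0.120 by 4.7 gives (0.0989, 0.0211) rather
  than the literal (0.094, 0.026). The split is therefore used only for
  scenario construction, where holding each subtype's *total* remission-exit
  probability fixed keeps the validated overall relapse frequency while
  varying its destination mix.
* `fit_exponential_recovery()` turns published survival quantiles (fraction
  still in an episode after so many weeks) into a constant weekly recovery
  rate — closed form for one quantile, least squares of `-log(S)` on time
  through the origin for several; `survival_probability()` evaluates the
  implied probability of remaining in the episode at the 13-week cycle
  boundary. The packaged remaining-in-episode probabilities are again
  literals: a pure exponential through the single published quantiles gives
  54.8/30.1/5.0% where the source reports 56.1/29.8/4.8% from an unstated
  multi-quantile fit, so the published values are taken as authoritative.

## Valuation

Per-cycle costs are attached to states as component tables (2021 euros):
drugs, medical services, psychological treatment, home-based treatment,
indirect medical costs, productivity losses, patient-and-family (informal
care) costs and admission costs. Two perspectives are supported: the
**healthcare** perspective excludes productivity losses and informal-care
costs, making it a strict subset of the **societal** perspective.
Productivity losses are zeroed from the first cycle whose starting age has
reached the retirement age of 67 (integer-age granularity). The per-state
amounts already aggregate the standard-of-care treatment-intensity mix
(85/15% outpatient low/high in remission; 90/7/3% and 30/40/30% adding
inpatient care in depression and mania); `blend_intensity_costs()` rebuilds
such aggregates when users supply costs per intensity category instead. The
intervention's cost is added uniformly across alive states in the
intervention arm during its cost window starting at cycle 0; whether a
relapse-prevention course should be billed only to patients in remission is
not settled, so the placement is deliberately simple and the cost window is
a parameter.

Life years, QALYs and costs are accumulated per cycle with a **half-cycle
correction**: the effective occupancy of a cycle is the trapezoid mean of
its start and end occupancy, crediting transitions as if they occur
mid-cycle. Discounting uses annual rates (defaults 4% costs, 1.5% effects)
applied as `(1 + r)^(-years elapsed)` with cycle 0 undiscounted. Discounted
totals therefore never exceed undiscounted ones, and QALYs never exceed life
years while utilities are at most 1. Utilities are 0.80 in remission, 0.29
in depression and 0.54 in mania, with hypomania (BD-II) valued at the
remission level 0.80 — hypomania is not associated with the severe
functional impairment of mania.

The default horizon is lifetime, implemented as running until the cohort
reaches the lifetable's terminal age (110 for the synthetic table), where
death is certain; a fixed horizon in cycles (20 cycles = 5 years) is the
alternative. The start of the cohort is configurable and defaults to age 40
with 100% of the cohort in remission: the evidence base does not state a
start age or start distribution, and a relapse-prevention case implies a
remitted cohort; 40 sits in the middle of the adult treatment population.

## Background mortality

Age-dependent general-population mortality comes from a CSV lifetable
(`age,qx`) or, so the model runs with no external data, from a synthetic
Gompertz–Makeham generator: `q(age) = 1 - exp(-(a + b·c^age))` with defaults
`a = 5e-5`, `b = 3e-5`, `c = 1.094`, terminal age 110. These values were
chosen once to give a life expectancy at birth of about 83 years,
representative of a modern Western European population; the suite checks
only a broad 75–90 sanity band so the generator is a stand-in, not a claim
about any national table. Within a quarterly cycle the annual probability of
the cohort's integer age at cycle start is used. Headline epidemiology
checks avoid depending on the synthetic table: the stationary shares below
are mortality-free properties of the transition matrices.

## What the deterministic run produces

```{r deterministic}
params <- default_parameters()
lifetable <- synthesize_lifetable()
result <- run_ce_analysis(params, lifetable)
result
glance(result)
stationary_epidemiology(params)
```

The stationary distribution of each subtype's alive-state chain (solved from
`pi P = pi`) is the model's long-run epidemiology among live patients; the
prevalence-weighted shares round to 78% remission, 19% depression and 4%
(hypo)mania. The depression share computes to 18.8%. These figures validate
the transition parameterization against observed time-in-state data, and the
suite cross-checks the linear solve against 10,000-cycle power iteration.

Incremental results are classified from the signs of the discounted
increments: QALY gain at lower cost is *dominant*, QALY loss at higher cost
*dominated*, and otherwise the ICER ΔC/ΔQ is reported (never when ΔQ = 0).
Dominance is judged on discounted totals, the conventional basis.

## Probabilistic sensitivity analysis

`run_psa()` propagates parameter uncertainty by Monte Carlo. Distribution
families follow the usual assignments — Dirichlet for transition rows
(concentration = mean row × effective sample size, so rows sum to 1 and
structural zeros stay zero), beta for utilities (matched to mean and
standard error), gamma for costs (matched to mean and coefficient of
variation), lognormal for relative risks and mortality rate ratios
(median-preserving), and beta-PERT (`rpert()`) for quantities bounded by a
minimum, mode and maximum such as guideline session counts. The evidence
base names the families but no dispersion magnitudes, so the defaults —
effective sample size 100, cost CV 0.2, utility SE 0.05, log-SD 0.1 — are
package choices, echoed into the PSA metadata and all overridable; PSA
probabilities under them are consequently indicative rather than
reproductions of any published percentage.

Each iteration uses a fixed documented draw order (per subtype: transition
rows then utilities; then costs column by column; then mortality ratios;
then intervention relative risks) so seeded runs are reproducible draw for
draw. The default iteration count is 5,000. The acceptability curve applies
the net-monetary-benefit rule at each willingness-to-pay threshold λ:
the probability that `λ·ΔQALY − ΔCost > 0`, with ties counted as not
cost-effective — coherent even for draws with negative QALY differences.
The default threshold grid spans 0–150,000 euro and includes both the
50,000 euro threshold used for severe disease burden and the
GDP-based 147,300 euro (3 × 49,100).

```{r psa}
psa <- run_psa(params, lifetable, n = 100, seed = 42)
glance(psa)
```

(100 iterations keep this vignette quick; analyses should use the 5,000
default.)

## Scenario analysis

Reported depression/mania time ratios differ considerably between cohort
studies; `scenario_ratio_analysis()` re-splits each subtype's total
remission-exit probability by alternative ratios — the defaults are the
literature pairs (6, 14) and (3.6, 38.7) — rebuilds the matrices and reruns
both arms:

```{r scenario}
scenarios <- scenario_ratio_analysis(params, lifetable)
scenarios[scenarios$subtype == "weighted",
          c("scenario", "delta_cost", "delta_qaly", "decision")]
```

## What the synthetic setup does and does not show

The packaged defaults reproduce the published parameterization of the
standard of care, and the property suite exercises the machinery on them:
mass conservation, exact null-intervention invariance, discounting and
perspective orderings, stationary-distribution agreement between two
independent computations, and distribution-domain respect in the PSA. Two
published headline quantities are *not* reproduced by design: per-patient
QALY gains and cost savings depend on the start age, start distribution and
the national lifetable, none of which are published, and published PSA
percentages additionally depend on unpublished dispersions. The numbers the
package prints for those quantities under its own defaults (a dominant
intervention with a QALY gain of the order of 0.02 and cost savings of some
hundreds of euros per patient) are consistent in direction and magnitude
with the published case but are properties of this configuration, not
replications. Results on real populations further depend on everything a
four-state cohort model abstracts away: episode-severity heterogeneity,
memory of prior course, treatment discontinuation (deliberately excluded)
and time-varying transition probabilities.

## Numerical notes

* Transition-row validation uses a 1e-9 tolerance; traces conserve mass to
  1e-12 per cycle.
* Residual transition entries (remaining in remission; returning to
  remission from an episode) are always recomputed as 1 minus the exits, so
  edited exits either rebuild a stochastic row or raise an explicit
  infeasibility error naming the row.
* Death probabilities are computed with `log1p`/`expm1` for accuracy at
  small hazards and capped at 1; an annual probability of 1 maps to 1 for
  any cycle length.
* The stationary solve uses the QR decomposition of the overdetermined
  system `t(P − I); 1` and errors on reducible or degenerate chains rather
  than returning an arbitrary eigenvector.
* Problem sizes in the test suite: lifetime traces run 285 quarterly cycles
  (age 40 to 111); property loops use dozens of random cases under fixed
  seeds; Monte Carlo moment checks use 1e5 draws; PSA reproducibility
  checks use small iteration counts with short fixed horizons, which
  exercise every code path of the full-size run.
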