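---
title: "Model and methods behind markovcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind markovcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`markovcea` implements a monthly-cycle Markov cohort state-transition model
comparing first-line cetuximab plus platinum-based chemotherapy ("arm C")
against platinum-based chemotherapy alone ("arm P") in recurrent or
metastatic head and neck squamous cell carcinoma (HNSCC), from a Canadian
public-payer perspective with all costs in 2011 CAD. This vignette is the
package's own account of the model, its conventions, and what the synthetic
survival inputs can and cannot support.

## The state-transition model

Arm P has three states — Stable, Progression, Dead — with Dead absorbing.
Arm C has eleven: stable with no adverse event (AE), stable with a mild AE
(grade 1–2 infusion reactions and skin rash), one stable state per severe
(grade 3–4) AE — allergy/anaphylaxis, dyspnea, hypotension, skin reactions,
anorexia, hypomagnesemia, sepsis — plus Progression and Dead. Cetuximab is
received only in the stable no-AE and mild-AE states; a severe AE or
progression stops cetuximab permanently.

AE timing follows the clinical pattern of cetuximab toxicity. Infusion-type
reactions and severe skin reactions are triggered by the initial exposure,
so transitions into the mild-AE state and the four first-month severe
states are open only in cycle 1. Anorexia, hypomagnesemia and sepsis can
begin in any month while cetuximab continues (0.61%/month each). Within a
cycle, AE moves are resolved first at their marginal probabilities, then
progression, then background death, combined multiplicatively. Because the
first-month marginal AE probabilities sum to about 0.42 (< 1), no
renormalisation is needed. A consequence of resolving AEs first is that a
patient who develops an AE and progresses in the same month is counted as
a progression, not as an AE case; at these probabilities the understatement
of AE costs is negligible.

All stable states share the cycle's stable-to-progression probability and
the background death probability: the data provide no AE-specific
progression hazard, and disease mortality is routed entirely through
progression, with stable-to-death reserved for other-cause (life-table)
mortality.

## From survival curves to transition probabilities

The monthly stable-exit probability is read off the progression-free
survival (PFS) curve as the conditional event probability
`1 - S(t)/S(t-1)`, and the other-cause component is split out
multiplicatively, `p_prog = 1 - (1 - p_pfs)/(1 - q_bg)`, floored at zero.
The background monthly probability comes from a flat sex-mixed annual life
table, `q_bg = 1 - (1 - q_annual)^(1/12)`; at a 36-month horizon an
age-advancing table changes the mixed monthly probability in the fourth
decimal and is not implemented.

Progression-to-death probabilities are calibrated sequentially: the
three-state chain is simulated forward one cycle at a time, and each
cycle's probability is the closed-form solution making total simulated
survival equal the overall-survival (OS) curve at that cycle, clipped to
[0, 1]. Two timing conventions matter and are fixed as follows:

* deaths from progression draw on the *previous* cycle's progression
  occupancy — same-cycle progressors cannot die in their entry cycle; and
* the clock is calendar model time, not time since progression (a
  cohort-level construction; the source data cannot identify the latter).

A corollary is that the model cannot match an OS curve that falls faster
than background mortality in month 1 — there is no progression pool to
supply those deaths yet. Such infeasible cycles (in practice cycle 1, and
occasionally cycle 2 in arm C) are recorded in the schedule's `clipped`
and `residual` fields; from the first feasible cycle onwards the simulated
survival tracks the OS curve to numerical precision, which the test suite
asserts at 1e-9.

The observed follow-up window is 24 months. Beyond it, each probability
stream continues at the arithmetic mean of its cycles 13–24 (the second
year), both for the year-3 extrapolation of the 36-month base case and for
longer horizon variants (up to 60 months). Horizons below 24 months are
refused rather than truncating the calibration window.

## Synthetic survival inputs

The trial's Kaplan-Meier curves are not published as data, so the package
generates parametric stand-ins calibrated to printed anchors:

* OS, arm P: Weibull through median 7.4 months and S(24) = 0.16
  (fitted shape 0.826, scale 11.53);
* OS, arm C: Weibull through median 10.1 months and S(24) = 0.18
  (fitted shape 1.047, scale 14.34);
* PFS medians 3.3 months (arm P; configurable) and 3.3 + 2.3 months
  (arm C), the 2.3-month gap being the printed PFS benefit.

The two-anchor Weibull fit is closed-form: `shape =
log(log(1/s24)/log 2) / log(24/median)`, `scale = median /
(log 2)^(1/shape)`; the exponential family is the `shape = 1` special
case. PFS curves use the *same shape parameter as the arm's fitted OS
curve*, rescaled to the PFS median. This was chosen once, on the grounds
that a memoryless exponential PFS leaves an implausibly heavy
progression-free tail at two years relative to the shape of survival in
this disease; an explicit numeric `pfs_shape` (e.g. 1) overrides it. PFS
is clipped below OS pointwise after generation.

What the stand-ins do *not* emulate: digitized trial curves fall to
roughly 0–0.5% survival by 36 months, whereas any smooth two-anchor curve
through (median, 24-month survival) retains about 7% at 36 months in both
arms here, and the arm-C curve crosses slightly below arm P in the tail.
Base-case increments that weight the first year heavily (incremental cost,
incremental life-years, the cost-per-life-year ratio, expected cetuximab
cost) reproduce the published analysis closely; tail-sensitive quantities
(incremental QALYs, hence the ICER, and the direction of the 24-month
horizon variant) land within roughly 20% but not closer. Passing tests on
this fixture therefore validate the machinery and the cost/utility
accounting, not the exact published ICER.

The life table defaults are flat annual mortality 0.010 (male) and 0.006
(female) with a 90% male cohort — Ontario magnitudes around age 60 and the
trial's sex mix; all three are configurable.

## Valuation conventions

* Utilities: stable (with no or mild AE) 0.65, progression 0.52, dead 0.
  A severe AE multiplies the stable utility by one minus its utility
  reduction — e.g. severe skin reactions give 0.65 × (1 − 0.657) = 0.223 —
  for the AE's disutility duration (1 month for infusion-type reactions,
  2 months for skin, 20 months for anorexia and hypomagnesemia, lifetime
  for sepsis), measured from state entry per entry cohort, then reverts
  to 0.65.
* Half-cycle correction: state-occupancy quantities (QALYs, life-years,
  recurring costs) accrue on the trapezoid — the mean of start- and
  end-of-cycle occupancy. One-time costs (severe-AE hospitalisations, the
  mild-AE consultation fee) are charged to state entrants at the entry
  cycle without half-cycle correction: they are events, not occupancies.
* Discounting: 5%/year applied per monthly cycle as `(1+r)^(-t/12)`.
  Per-cycle compounding of r/12 differs by under 0.15% over 36 months.
  Life-years are discounted on the same basis as costs and QALYs.
* Duration rules: chemotherapy ($4,293/month) accrues to all stable-state
  occupancy during calendar cycles 1–5 in both arms; cetuximab dosing
  ($6,706.80 in month 1, $5,832 after — recomputed from 400/250 mg/m²
  dosing, 1.8 m² body surface area and $3.24/mg), infusion chair time
  ($518.20 / $414.56) and pharmacy preparation ($160) accrue to
  cetuximab-receiving occupancy; progression occupancy accrues inpatient
  hospice care at $25,333/month.

On the cetuximab unit price: the cost table and the 75% price-reduction
threshold are internally consistent at $3.24/mg, while narrative sources
also quote $3.46/mg; the package defaults to $3.24 and exposes
`costs$unit_price_per_mg`. Note the table's later-month chair time prints
414.5 where the hourly arithmetic gives 414.56 (truncation), and severe
skin reactions carry base cost 2,912 with a resampling mean of 2,919 —
both kept as printed.

## Sensitivity and probabilistic analyses

One-way and two-way sweeps re-run the full pipeline per grid point.
"Risk of progression reduced by x" multiplies every arm-C monthly
stable-to-progression probability by (1 − x); a hazard-scale multiplier
differs negligibly at these magnitudes. Threshold analysis bisects the
reduction until the ICER is within 0.1% of the willingness-to-pay or the
bracket is below 1e-4; dominant outcomes count as arbitrarily favourable
for bracketing.

The PSA jointly resamples every parameter with a declared distribution:
probabilities and utility reductions as Beta(n, N − n) (so the mean n/N
reproduces each base value), costs as lognormals with the stated mean and
median (`mu = log(median)`, `sigma = sqrt(2 log(mean/median))`). Sampled
utility reductions pass through the same 0.65 × (1 − r) decrement.
Transition schedules are *not* resampled — no distribution is declared for
them — so the PSA understates survival uncertainty; this is the package's
main known limitation alongside the stand-in tails. The progression
utility draw is capped at the stable draw to preserve the ordering, and
the mild-AE consultation fee has no declared distribution and stays fixed.
Each parameter owns a random substream seeded from the master seed and the
parameter's name, so adding a parameter leaves the others' draws
unchanged. Arm P's trace is draw-invariant and reused; arm C is re-run per
replicate because AE probabilities alter its trace.

The headline PSA uses 10,000 replicates (about 1–2 minutes on one CPU);
the cost-effectiveness acceptability curve reports the fraction of
replicates with positive incremental net monetary benefit (ties count
half), and the per-person expected value of perfect information is
`mean(pmax(INMB, 0)) - max(mean(INMB), 0)`.

## Worked example

```{r}
library(markovcea)
m <- cea_model()          # base case, 36 months
summary(m)
icer(m)                   # CAD per QALY gained
threshold_search(m, "price_reduction", wtp = 1e5)
psa <- simulate(m, nsim = 10000, seed = 1)
ceac(psa, 1e5)            # P(cetuximab optimal at $100,000/QALY)
evpi(psa, 1e5)            # CAD per person
```

Problem sizes used throughout the package's own checks: 36 monthly cycles
(24–60 in horizon variants), 10,000 PSA replicates, 1e5-draw sampler
moment checks — the full analysis, not a reduced surrogate.

## Degenerate inputs and tie-breaks

Empty progression pools during calibration saturate the solved probability
(and are logged) rather than erroring; a PFS curve touching zero switches
the conditional event probability to 1 by convention; Beta specs with
n = N and lognormals with mean = median collapse to point masses; exact
net-benefit ties split half-and-half in the CEAC; ICERs are undefined
(flagged, not divided) when the QALY increment is zero, and dominance is
flagged instead of a ratio when cost and effect increments disagree in
sign.
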