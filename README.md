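# markovcea

A Markov cohort state-transition model of the cost-effectiveness of adding
cetuximab to first-line platinum-based chemotherapy in recurrent or
metastatic head and neck squamous cell carcinoma (HNSCC), from the
perspective of a Canadian public payer (2011 CAD). It is written for health
economists and methodologists who want a fully scripted, testable
re-implementation of this class of oncology decision model: deterministic
base case, one-way/two-way/threshold and horizon sensitivity analyses,
probabilistic sensitivity analysis (PSA) with cost-effectiveness
acceptability curves (CEAC), and expected value of perfect information
(EVPI).

## The model

Two cohorts start stable on treatment and move monthly for 36 cycles.
The chemotherapy-alone arm has states {Stable, Progression, Dead}; the
cetuximab arm adds a mild adverse-event (AE) state and seven severe-AE
stable states (allergy/anaphylaxis, dyspnea, hypotension, skin reactions,
anorexia, hypomagnesemia, sepsis), with infusion-type and skin events
confined to the first month on cetuximab and the ongoing three possible in
any month on cetuximab. Severe AEs and progression stop cetuximab.

Time-dependent transition probabilities are derived from survival curves:
stable→progression from PFS as `p_t = 1 − S(t)/S(t−1)` with life-table
background mortality split out; stable→dead is other-cause only;
progression→dead is calibrated cycle by cycle so simulated survival
matches the OS curve; cycles 25–36 continue at the year-2 average. The
trial Kaplan–Meier curves are not published as data, so the package
generates Weibull stand-ins through the printed anchors (OS medians
7.4/10.1 months, 24-month OS 16%/18%, PFS medians 3.3/5.6 months).

Valuation: utilities 0.65 stable, 0.52 progression, severe-AE states at
`0.65·(1 − r)` for the event's disutility duration; costs cover
chemotherapy (first 5 months), cetuximab dosing/infusion/preparation while
on cetuximab, AE management, and inpatient hospice care during
progression; half-cycle (trapezoidal) correction and 5%/year discounting
as `(1+r)^(−t/12)`. The headline statistic is the incremental
cost-effectiveness ratio,

    ICER = (C_cetux − C_chemo) / (E_cetux − E_chemo)   [CAD per QALY],

with net monetary benefit `NMB = λ·E − C` behind the CEAC and
`EVPI = E[max(INMB, 0)] − max(E[INMB], 0)` per person.

See `vignettes/markovcea-methods.Rmd` for conventions, calibration
details, and the known limitations of the synthetic survival inputs.

## Worked example

```r
library(markovcea)
m <- cea_model()   # base case on the calibrated survival stand-ins
print(m)
```

```
Markov cohort cost-effectiveness model, cetuximab + platinum chemotherapy
vs platinum chemotherapy (recurrent/metastatic HNSCC)
  horizon 36 months, discount 5%/yr
  arm P: cost $149,878, 0.5319 QALY, 0.9084 LY
  arm C: cost $184,753, 0.6066 QALY, 1.0427 LY
incremental: cost $34,875, 0.0746 QALY, 0.1342 LY
ICER: $467,384/QALY, $259,787/LY
```

Adding cetuximab costs an extra $34,875 per person for 0.075 additional
QALYs (0.134 life-years) — far above conventional willingness-to-pay
thresholds. The price cut needed to reach $100,000/QALY, and the decision
uncertainty:

```r
threshold_search(m, "price_reduction", wtp = 1e5)
#> [1] 0.774          # a ~77% cut in the $3.24/mg cetuximab price

psa <- simulate(m, nsim = 2000, seed = 1)
print(psa)
#> PSA: 2000 replicates (seed 1)
#>   mean increment: cost $34,706, 0.0746 QALY
#>   P(cetuximab cost-effective at $1e+05/QALY) = 0.010
evpi(psa, 1e5)
#> [1] 51.1           # CAD per person: essentially no value of information
```

So at $100,000/QALY the cetuximab strategy is preferred in about 1% of
replicates and resolving all parameter uncertainty is worth ~$51 per
person: the conclusion is driven by the drug price, not by uncertainty.

Other entry points: `load_parameters()` / `write_parameters()` for YAML or
JSON configurations, `sensitivity_one_way()` / `sensitivity_two_way()`,
`horizon_variant()`, `write_base_case()` / `write_psa()` for report
bundles, and a command-line driver at `inst/cli/markovcea.R` with
`init-config`, `base-case`, `sensitivity` and `psa` subcommands.

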