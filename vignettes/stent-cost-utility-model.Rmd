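---
title: "A Markov cost-utility model of metallic versus polyurethane ureteral stents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of metallic versus polyurethane ureteral stents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentcua)
```

## The decision problem

Malignant ureteric obstruction (MUO) is managed palliatively with
ureteral stents. Standard polyurethane double-J (JJ) stents are cheap
but fail often from compression and encrustation, each failure costing
an unplanned theatre visit; metallic double-pigtail stents (Resonance)
resist compression and are exchanged less often, but cost far more per
device. `stentcua` implements a cost-utility model that weighs these
forces from a UK NHS provider perspective: monthly cycles over a
five-year horizon, costs in GBP, benefits in quality-adjusted life
years (QALYs), both discounted at 3.5% per year.

## Model structure

The cohort moves through four mutually exclusive health states:
**Patent** (working stent), **PatentUTI** (working stent with a
urinary tract infection), **Failed** (stent failure, prompting
like-for-like replacement) and **Dead** (absorbing). Everyone starts
Patent at cycle 0 with a freshly inserted stent.

Monthly probabilities: stent failure `p_fail` (strategy-specific,
applying in every alive state), new infection `p_uti`
(strategy-specific), all-cause death `p_death`, and infection
resolution `p_uti_resolve`. All are derived on a constant-hazard
assumption (`rate_to_probability()`, `km_constant_hazard()`,
`pooled_incidence_probability()`, `blend_mortality()`).

### Within-cycle composition

Competing monthly risks can be composed several ways: sequentially
(death first, then failure, then infection, each acting on the
survivors of the previous) or marginally (each probability entering
the transition row directly, with the remainder staying put). We
calibrated both compositions, together with every combination of
event-counting and planned-exchange convention, against the published
base-case table of total stents used at 1, 2, 3 and 5 years in both
arms. Sequential composition underestimates late-horizon stent use by
about 4%; **marginal composition reproduces all eight counts to within
0.15%**, so it is the package default:

* Patent: `-> Dead` with `p_death`, `-> Failed` with `p_fail`,
  `-> PatentUTI` with `p_uti`, remainder stays Patent.
* PatentUTI: death and failure as above; the infection resolves with
  `p_uti_resolve` (back to Patent) or persists.
* Failed: replacement completes within the cycle, so the row equals
  the Patent row (fresh stent of the same type).

Marginal composition requires `p_fail + p_uti + p_death <= 1`;
`build_transition_matrix()` enforces this, and probabilistic
sensitivity draws that breach it are rejected and redrawn (counted,
never silently renormalised).

### Exchanges and the reporting convention

Two event streams drive costs:

* **Unplanned exchanges** -- expected entries into Failed. A failure
  during month *t* is exchanged at the start of month *t + 1*, so a
  reporting horizon of *m* months counts failure events at cycles
  `1 .. m - 1`. This one-month performance lag is the convention that
  reproduces the published counts; it also reads naturally -- the
  insertion month itself cannot already contain a replacement of the
  new stent.
* **Planned exchanges** -- at every completed interval (12 months for
  the metallic stent, 6 for JJ), patients alive with a working stent
  (Patent + PatentUTI occupancy) whose stent survived the whole
  interval unchanged -- probability `(1 - p_fail)^interval` -- receive
  a scheduled change. Under the performance-lag convention the
  metallic stent's month-12 change falls just outside a 12-month
  report. The Patent + PatentUTI occupancy basis calibrated fractionally
  better than Patent alone; both are within tolerance.

Total stents used = 1 (initial insertion) + unplanned + planned. The
`(1 - p_fail)^interval` survivor factor is the model's own rule, so
the microsimulation oracle implements it as a per-patient Bernoulli
draw at each interval rather than tracking stent age; the two engines
therefore estimate the same quantity by construction.

## Economics

* **Discounting**: `(1 + r)^(-cycle/12)` -- a smooth per-cycle
  exponent rather than annual steps; the difference is far below the
  model's precision.
* **State accrual** (QALYs, life years): trapezoidal half-cycle
  correction by default -- weights 1/2, 1, ..., 1, 1/2 over trace rows
  -- reflecting transitions occurring mid-cycle. With correction off,
  accrual uses the start-of-cycle convention. Utilities are annual
  values divided by 12 per cycle; the Failed month retains the
  failed-stent utility, Dead contributes nothing.
* **Event costs** are instantaneous and not half-cycle corrected:
  exchange procedures are costed at their performance cycle, infection
  episodes (a GP visit plus an antibiotic course) at onset. An
  unplanned exchange additionally incurs an unplanned oncology
  outpatient visit.
* **Procedure costing** is bottom-up: procedure minutes times (theatre
  running + surgeon rates), consumables, the stent itself, imaging,
  and recovery -- a 4-hour day-case bed stay with 30 minutes of
  one-to-one band-6 nursing and 240 minutes of band-5 nursing shared
  across four patients. A configurable share of procedures
  (`settings.daycase_fraction`, lower bound 75%) instead incurs an
  overnight stay; this mix is swept in deterministic sensitivity
  analysis only, as a bound rather than a distribution.
* Replacement procedures take the insertion time plus 10 minutes
  (21 -> 31 minutes for the metallic stent, 20.6 -> 30.6 for JJ).

Incremental results (intervention minus comparator) are summarised as
incremental cost, incremental QALYs, the ICER with dominance
classification, and net monetary benefit `wtp * dQ - dC` at a
willingness to pay of 20,000 GBP/QALY.

## Parameters

Clinical base case (monthly probabilities, with published bounds):
all-cause mortality 0.0505 (0.0404-0.0606); stent failure 0.1502
(0.1202-0.1802) metallic, 0.3648 (0.2918-0.4378) JJ; infection 0.0205
(0.0018-0.0547) metallic, 0.0085 (0.0068-0.0102) JJ. Infections
resolve within one cycle; the base resolution probability is set to
1/1.1 = 0.9091 so that its +10% sensitivity bound is exactly 1.

The unit costs and state utilities live in source appendices that are
not machine-readable. The fixture ships **round-number placeholders**
(PSSRU-style staff rates, NHS-tariff-style visit costs; utilities
0.80/0.70/0.75 per year for Patent/UTI/Failed), every one tagged
`provenance = "placeholder"`, logged by the pipeline, and overridable
from a YAML/JSON document. Consequently the package reproduces the
published *stent counts* exactly from in-paper inputs, while monetary
and QALY outputs have the right structure, signs and ordering but not
the published magnitudes until a user supplies the appendix values.

### Sensitivity distributions

Probabilities and utilities are drawn from beta distributions, costs
and resource-use minutes from gamma distributions, both moment-matched
(`fit_beta()`, `fit_gamma()`). Published bounds are interpreted as a
central 95% interval, `sd = (high - low)/3.92` -- standard practice
when only plausible ranges are reported -- with `spread = "range2"`
available as an alternative. Mortality defaults to its printed +-20%
bounds; a `death_pm10` preset narrows them to +-10% (both variation
statements appear in the source material). A `uti_shared` preset
equates the comparator's infection probability with the
intervention's, the assumption variant of the base case. Parameters
are drawn independently; no correlation structure is published, and
this is a documented limitation.

## Synthetic data

The generators exist so every stage is testable without downloads:

* `synthesize_km_series()` emulates coordinates digitised off a
  published Kaplan-Meier curve: a geometric survival series with
  multiplicative log-normal noise, clamped to remain a valid survival
  function. It exercises parameter recovery in
  `km_constant_hazard()`. It does **not** emulate censoring, risk-set
  step structure, or digitisation bias that correlates across points.
* `synthesize_economic_inputs()` draws schema-valid cost/utility
  blocks (gamma-distributed costs, ordered utilities
  `u_patent >= u_uti >= u_failed`) to exercise the economics and
  sensitivity layers across many input sets. The draws are plausible
  magnitudes, not estimates of the appendix values.
* `synthetic_life_table()` is a round-number, life-table-shaped
  mortality table; `calibrated_study_mortality()` back-solves the
  study mortality component so the blended monthly probability equals
  the base-case 0.0505 exactly -- a structural demonstration of the
  blending arithmetic, not a reconstruction of the published sources.

Passing tests on synthetic inputs therefore demonstrate correctness of
the *arithmetic and its conventions*, not agreement with unpublished
data.

## Numerical choices and degenerate inputs

* Probability/rate round trips are exact to double precision over the
  rates the model uses; `probability_to_rate()` rejects `p = 1`.
* `fit_beta()` rejects standard deviations with
  `sd^2 >= mean(1 - mean)`, naming the bound; degenerate parameters
  (`low == high`) become point masses rather than ill-defined fits.
* Zero-probability inputs are valid: an event-free cohort stays
  Patent and uses exactly one stent.
* Trace occupancies are validated to sum to 1 within 1e-12 every
  cycle; dominance ties (`dQ = 0`) yield an explicit `"undefined"`
  ICER label rather than a division.
* Tornado entries sort by descending incremental-cost swing with an
  alphabetical tie-break, so output order is deterministic.

## Validation strategy and problem sizes

The deterministic engine is checked against (a) closed forms -- in the
no-UTI, no-planned-change limit, expected unplanned exchanges are
`p_fail * sum((1 - p_death)^t)` over the counted transitions -- and
(b) an independent patient-level microsimulation
(`microsim_oracle()`) that re-implements the state rules with
per-cycle Bernoulli draws and accrues per-patient discounted costs and
QALYs. The shipped test suite compares the two at 200,000 patients for
five random parameter sets (3 Monte-Carlo SEs on occupancies at the
reporting horizons, stent tallies, infection and death counts),
verifies occupancy conservation and absorbing death on 10,000 random
parameter sets, and runs the probabilistic sensitivity analysis at the
published 1,000 iterations. These sizes keep the full suite under a
few minutes on a single core while leaving Monte-Carlo tolerances
tight enough to detect convention mismatches (the one-month reporting
lag, for instance, shifts counts by several SEs).

## Known limitations

* Appendix-held unit costs, utilities and life-table values are
  placeholders (flagged and overridable); monetary outputs are
  structural until replaced.
* No tunnel states: stent age affects nothing beyond the
  planned-exchange survivor factor, and the planned-change clock is
  not reset by unplanned replacements (the literal reading of the
  source's "previous unchanged stents").
* PSA draws are independent across parameters.
* No patient-level covariates or time-varying hazards; the
  constant-hazard assumption is inherited from the evidence base.
* NHS provider perspective only: no societal costs or productivity
  losses.

## A worked run

```{r, eval = FALSE}
inputs <- base_case_fixture()
outcomes <- compare_strategies(inputs)
outcomes

tornado <- dsa_univariate(inputs)
psa <- psa_run(inputs, n = 1000, seed = 1)
ceac(psa, seq(0, 50000, 1000))

run_pipeline(inputs, "results/full", psa_iterations = 1000, seed = 1)
```
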