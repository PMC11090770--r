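# stentcua

Cost-utility Markov modelling of metallic (Resonance) versus standard
polyurethane double-J (JJ) ureteral stents for malignant ureteric
obstruction (MUO), from a UK NHS provider perspective.

MUO patients are palliated with ureteral stents. Polyurethane JJ
stents are cheap but fail frequently, each failure costing an
unplanned theatre visit; metallic stents resist compression, fail less
and are exchanged yearly instead of six-monthly, but cost far more per
device. `stentcua` implements the full decision model that weighs
these forces, for health economists and urology service planners who
want to reproduce, stress or re-parameterise the analysis.

## The model

A four-state Markov cohort model -- Patent, Patent with urinary tract
infection (UTI), Failed, Dead -- run in monthly cycles over a 5-year
horizon with half-cycle correction and 3.5% annual discounting of
costs and QALYs. Monthly transition probabilities are derived under a
constant-hazard assumption (p = 1 − e^(−λt)), including Kaplan–Meier
constant-hazard fitting, pooled incidence per patient-month, and
life-table mortality blending on the hazard scale. A failed stent is
replaced like-for-like the following month; planned exchanges occur
after every completed interval (12 months metallic / 6 months JJ) for
stents that survived the whole interval, with probability
(1 − p_fail)^interval. Comparative results are reported as
incremental cost ΔC, incremental QALYs ΔQ, the ICER ΔC/ΔQ with
dominance classification, and net monetary benefit
NMB = λ·ΔQ − ΔC at λ = £20,000/QALY.

Sensitivity machinery: univariate deterministic sweeps with tornado
ordering, probabilistic sensitivity analysis (moment-matched beta and
gamma distributions, independent draws, invalid joint draws rejected
and redrawn), cost-effectiveness acceptability curves, scenario
analysis, and a patient-level microsimulation oracle that validates
the cohort engine to Monte-Carlo precision.

Clinical inputs ship at their published base-case values. Unit costs
and utilities live in non-machine-readable source appendices and ship
as flagged round-number placeholders (`provenance = "placeholder"`,
logged on every run, overridable from YAML/JSON); monetary outputs are
therefore structurally correct but not the published magnitudes until
those values are supplied. See the methods vignette
(`vignettes/stent-cost-utility-model.Rmd`) for conventions and
calibration decisions.

## Worked example

```r
library(stentcua)

inputs <- base_case_fixture()
for (arm in c("JJ", "Resonance")) {
  tr <- run_cohort(inputs, arm)
  cat(arm, "stents used, year 1 and 5:",
      round(stents_used(tr, 12)$total, 3),
      round(stents_used(tr, 60)$total, 3), "\n")
}
#> JJ stents used, year 1 and 5: 4.168 7.988
#> Resonance stents used, year 1 and 5: 2.292 3.961
```

Per patient, the model expects ~4.17 stents in the JJ arm over the
first year (the initial insertion plus ~3.2 failure-driven exchanges,
plus scheduled changes) against ~2.29 for the metallic stent: about
two fewer theatre visits in year 1 and four fewer by year 5.

```r
compare_strategies(inputs)
#> <cua_outcomes: Resonance vs JJ, WTP 20,000/QALY>
#>   horizon cost_Resonance qalys_Resonance ... delta_cost delta_qalys icer_label
#> 1      12       3990.229           0.580 ...   -564.208       0.007   dominant
#> 2      24       5539.892           0.880 ...  -1230.444       0.011   dominant
#> 3      36       6343.855           1.036 ...  -1576.086       0.013   dominant
#> 4      60       6977.340           1.159 ...  -1848.435       0.014   dominant
```

With the placeholder economics the metallic stent is cheaper and more
effective ("dominant") at every horizon -- the fewer-reinterventions
mechanism -- with the caveat that the monetary magnitudes reflect
placeholder unit costs. The full pipeline (tables, figures, run log):

```r
run_pipeline(inputs, "results/full", psa_iterations = 1000, seed = 1)
```

or from a shell:

```sh
Rscript inst/cli/stentcua.R fixture --out model.yaml
Rscript inst/cli/stentcua.R validate --input model.yaml
Rscript inst/cli/stentcua.R run --input model.yaml --out results/ --seed 1
```

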