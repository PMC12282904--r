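# htnscreen

**Cost-effectiveness modelling of population blood-pressure screening with a
lifetime Markov cohort model.**

`htnscreen` is for health economists and epidemiologists evaluating when and
how often to screen adults for hypertension. It implements a decision-analytic
model of the Iranian screening programme: ten mutually exclusive health states
— healthy, hypertension off/on treatment, five post-cardiovascular-event
states (myocardial infarction, stroke, stable angina, unstable angina,
transient ischaemic attack) and two absorbing death states — propagated in
annual cycles from age 30 for 70 cycles. Nine screening strategies (annual,
biennial or triennial rounds starting at 30, 40 or 50, stopping at 70) are
compared with no screening.

## The model

Each cycle, other-cause mortality competes first; survivors face
age-dependent coronary heart disease (CHD) and stroke event risks. Treated
hypertensives have their untreated risks scaled by relative risks
(RR<sub>CHD</sub> = 0.675, RR<sub>stroke</sub> = 0.622); post-event states
carry recurrence (CHD × 2.4 on the healthy risk; stroke 0.0485/yr) and
state-specific cardiovascular mortality. Events resolve through within-cycle
chance nodes with fatal/non-fatal decompositions (proportionally renormalized
to sum to one). A screening round splits the healthy and untreated states by
participation (0.563 / 0.673) and test accuracy (sensitivity = specificity =
0.746); a perfect confirmatory test returns false positives to the healthy
path, true positives start treatment with probability 0.9, and false
negatives stay undiagnosed until the next round. Costs (PPP international $,
2020) and utilities accrue per cycle and are discounted at 5%/yr:

- lifetime discounted cost and QALYs per strategy;
- incremental analysis versus no screening, with ICER = ΔC/ΔE;
- dominance classification (absolute and extended) and the efficiency
  frontier with step ICERs;
- net monetary benefit NMB = λ·ΔE − ΔC and the optimal strategy at a
  willingness-to-pay λ (the published threshold is 1.35 × GDP per capita,
  $PPP 20,652.44/QALY);
- one-way deterministic sensitivity analysis (tornado data) and
  probabilistic sensitivity analysis (beta/gamma parameter distributions,
  cost-effectiveness acceptability curves, CE-plane scatter).

The age-indexed inputs (hypertension and CVD incidence, background treatment
uptake, mortality) are not publicly deposited; a seedable synthetic generator
(`default_schedule_set()`) supplies demographically shaped stand-ins
(logistic incidence, Gompertz mortality), so the whole pipeline runs with no
external data. An individual-level microsimulation oracle cross-checks the
cohort engine.

## Worked example

```r
library(htnscreen)
library(dplyr)

params  <- load_parameters(schedules = default_schedule_set(seed = 1))
results <- run_strategies(params)
incremental_vs_baseline(results, "No screening") %>%
  select(strategy, cost, qaly, inc_cost, icer, status)
#> # A tibble: 10 × 6
#>    strategy                                        cost  qaly inc_cost   icer status
#>  1 No screening                                   6175.  17.2     0       NA  undominated
#>  2 Annual screening from the age of 30            6716.  17.2   542.   14515. absolutely_domin…
#>  3 Annual screening from the age of 40            6348.  17.2   173.    3834. undominated
#>  4 Annual screening from the age of 50            6213.  17.2    38.4   1497. extended_dominat…
#>  5 Screening every two years from the age of 30   6446.  17.2   271.    5764. undominated
#>  6 Screening every two years from the age of 40   6253.  17.2    78.9   1873. undominated
#>  7 Screening every two years from the age of 50   6187.  17.2    12.2    550. undominated
#>  8 Screening every three years from the age of 30 6358.  17.2   184.    4200. absolutely_domin…
#>  9 Screening every three years from the age of 40 6225.  17.2    50.0   1340. undominated
#> 10 Screening every three years from the age of 50 6180.  17.2     5.37   285. undominated
```

Every screening strategy costs more than no screening (here $5–542 per
person) and gains QALYs; the `icer` column is each strategy's cost per QALY
gained versus no screening, and `status` is its dominance label. The frontier
ladder then ranks the undominated strategies by effectiveness with step
ICERs versus the previous frontier strategy:

```r
fr <- frontier_analysis(results)
step_icers(fr)
#> # A tibble: 6 × 4
#>   strategy                                       inc_cost inc_effect   icer
#> 1 Screening every three years from the age of 50     5.37    0.0189    285.
#> 2 Screening every two years from the age of 50       6.79    0.00327  2075.
#> 3 Screening every three years from the age of 40    37.8     0.0152   2490.
#> 4 Screening every two years from the age of 40      28.8     0.00477  6046.
#> 5 Annual screening from the age of 40               94.1     0.00301 31251.
#> 6 Screening every two years from the age of 30      98.4     0.00196 50109.

optimal_at_wtp(fr, 20652.44)
#> [1] "Screening every two years from the age of 40"
```

(These numbers come from the synthetic schedules with seed 1; the exact
frontier composition varies with the generated age curves, while the
qualitative structure — screening costs more, gains health, and more frequent
rounds cost more — is stable.)

`autoplot(fr, wtp = 20652.44)` draws the cost-effectiveness plane with the
frontier and the WTP tangent; `run_psa()`, `ceac()` and `autoplot()` on the
PSA object produce acceptability curves; `run_owsa()` and `plot_tornado()`
produce one-way sensitivity (tornado) output; `run_pipeline()` writes all
tables as CSV with a reproducibility manifest.

## Package layout

- `R/parameters.R` — parameter loading, validation, CI orientation, branch
  renormalization, serialization
- `R/synthetic.R` — synthetic age-schedule generator and parameter
  perturbation
- `R/screening.R` — strategy roster and screening-round mechanics
- `R/engine.R`, `R/microsim.R` — cohort engine and microsimulation oracle
- `R/cea.R` — incremental analysis, dominance, frontier, NMB
- `R/sensitivity.R` — OWSA, distribution fitting, PSA, CEAC
- `R/pipeline.R`, `R/plots.R` — artifact writers and ggplot2 figures
- `vignettes/hypertension-screening-model.Rmd` — methods and modelling
  choices
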