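---
title: "A lifetime Markov cohort model for hypertension screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cohort model for hypertension screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Population screening for high blood pressure trades a certain, recurring
outlay — screening contacts, confirmatory work-ups for everyone who tests
positive, and earlier treatment — against a reduction in downstream
cardiovascular events whose costs and quality-of-life losses are large but
probabilistic and often decades away. `htnscreen` models this trade-off for a
cohort entering at age 30 and followed for 70 annual cycles, comparing nine
screening strategies (every 1, 2 or 3 years, starting at 30, 40 or 50,
stopping at 70) against no systematic screening.

## States and dynamics

The state space has ten mutually exclusive states: `HEALTHY`, `HTN_OFF_TX`
(hypertensive, undiagnosed or untreated), `HTN_ON_TX` (on antihypertensive
treatment), five post-event states (`POST_MI`, `POST_STROKE`, `POST_SA`,
`POST_UA`, `POST_TIA`) and two absorbing states (`DEAD_CVD`,
`DEAD_NON_CVD`). Coronary heart disease (CHD) and stroke events are not
persistent states but within-cycle chance nodes: an event fires, is
immediately decomposed into a fatal branch and non-fatal branches (CHD →
death / MI / stable angina / unstable angina; stroke → death / non-fatal
stroke / TIA), and survivors occupy the corresponding post state from the
next cycle. Event-year costs and the death-year treatment costs attach to
these branches in the event cycle.

Within a cycle the ordering is fixed and documented rather than estimated,
because an annual-cycle model must impose one:

1. **Screening** (on qualifying cycles) splits the healthy and untreated
   states into outcome sub-populations at the start of the cycle, so
   screen-detected treatment already lowers that year's event risk.
2. **Other-cause death** competes first; all remaining risks act on the
   survivors.
3. **Events** fire and decompose; post-event states face state-specific
   cardiovascular death and recurrence (CHD recurrence multiplies the
   healthy CHD risk by 2.4; stroke recurrence is a constant 0.0485/yr).
   A recurrent event re-enters the same decomposition, so an individual
   holds only the most recent event's post state.
4. **Progression**: event-free healthy survivors develop hypertension at the
   age-indexed incidence (entering `HTN_OFF_TX`); untreated survivors start
   treatment at the age-indexed background uptake rate in *every* strategy
   (routine diagnosis continues between and without screening rounds);
   screen-detected true positives start treatment with probability 0.9.

QALYs for a cycle are the end-of-cycle occupancy weighted by state
utilities; anyone dying within the cycle accrues nothing that year, and no
half-cycle correction is applied. Cycle *t* (0-based) contributions are
divided by $(1+r)^t$ with $r = 5\%$ for both costs and outcomes, so a cohort
frozen in full health accrues exactly $\sum_{t=0}^{69} 1.05^{-t} = 20.31$
discounted QALYs — one of the closed-form checks in the test suite.

## Screening mechanics

Participation is 0.563 (healthy) and 0.673 (untreated), independent across
rounds — the data behind these are single campaign-derived probabilities, so
no never-attender memory is modelled. The screening test has sensitivity =
specificity = 0.746; the confirmatory test is assumed perfect, so the 25.4%
of participating healthy people who screen false-positive are recognised as
healthy after the work-up (at $212.57 each — applied to every
screen-positive, true or false), and false negatives remain undiagnosed
until the next round.

Two printed inputs needed interpretation:

* **False negatives carry untreated risks.** The source tables print
  screening-cycle event probabilities for true positives, false positives
  and false negatives — with the false-negative rows identical to the
  true-positive rows (CHD 0.014, stroke 0.006), i.e. both are simply the
  untreated event probabilities. The engine therefore applies the printed
  constants to the true-positive and false-positive sub-populations (whose
  screening-cycle management differs) but keeps false negatives on the
  untreated age schedule. This also preserves two structural properties: a
  test with zero sensitivity and perfect specificity leaves the state
  dynamics identical to no screening, and false negatives face exactly the
  untreated state's risks until the next round.
* **Treatment initiation costs.** Routinely detected new cases cost $137.85
  in their first treated year, screen-detected ones $139.41, and every
  subsequent treated year $57.56. The $1.56 difference equals the screening
  contact cost, and the source does not say whether the $139.41 already
  contains it; both are charged as printed (the contact to every
  participant), accepting a possible $1.56 double count per screen-detected
  starter — about 1% of the initiation cost.
* **The two identical relative-risk rows.** The source prints two rows both
  labelled as the treated-to-stroke relative risk (0.675 and 0.622); one
  almost certainly concerns CHD. The parameter set assigns 0.675 to CHD and
  0.622 to stroke; swapping them is a one-line change via
  `set_parameter()`.

## Parameters

All scalar inputs ship as a JSON fixture (`base_case_parameters.json`) with
point estimates, 95% CIs where published, a kind tag (probability, cost,
utility, relative risk) and a source note; monetary values are PPP
international dollars, 2020. Three transcription artefacts are handled on
load:

* CIs printed high-to-low (several utilities) are re-oriented; the point
  estimate is never touched.
* The CHD event decomposition sums to 1.043 and the stroke decomposition to
  0.8495 as printed; both are proportionally renormalized (as is the initial
  distribution, printed sum 0.999) because a row-stochastic model is
  impossible otherwise. `renormalize = FALSE` preserves the raw values for
  sensitivity exploration, and `validate_parameters()` then reports the
  branch sums.
* Parameters without a published CI are flagged `fixed` and excluded from
  probabilistic sampling — there is no defensible uncertainty width to
  assign them.

## The synthetic age schedules

Eight inputs are age-indexed (healthy and untreated CHD/stroke incidence,
hypertension incidence, background treatment uptake, cardiovascular and
other-cause mortality) and published only in an appendix that is not
publicly deposited. `default_schedule_set(seed)` generates stand-ins from
two-anchor closed forms: log-odds-linear (logistic) curves for
incidence-type probabilities and Gompertz curves for mortality, one value
per integer age 30–100, non-decreasing by construction.

Anchor levels are the package's one-time calibration choice, made for
internal coherence with the printed screening-cycle constants rather than
fitted to any survey: healthy CHD risk near 0.010 and stroke near 0.003
across the screened ages (the printed false-positive rows, which are healthy
people), untreated risks a constant multiple above them reaching about 0.014
and 0.006 (the printed true-positive rows), hypertension incidence rising
from 1.5% to 4.5% per year, background uptake from 8% to 15% per year
(brisk, reflecting a setting with an active national detection campaign),
and Gompertz other-cause mortality from about 0.0015 at 30. The seed jitters
anchors by roughly ±10% on the log scale, so replicate schedule sets differ
while the qualitative constraints hold for every seed: untreated risk above
healthy risk at all ages, non-decreasing mortality, and a lifetime
cardiovascular event risk from age 30 of roughly 0.3 (checked against a
0.2–0.6 plausibility band in the tests).

What the generator does **not** emulate: sex stratification (the main model
is unstratified), cohort effects, any fit to Iranian STEPs or GBD extracts,
and correlation between schedules beyond the built-in untreated/healthy
multiplier. Consequently, passing tests demonstrate that the machinery is
correct and that the published *qualitative* structure (screening costs
more, gains QALYs, more frequent screening costs more) emerges under
plausible inputs — not that the published ICERs are reproduced. The headline
cost-effectiveness ratios depend on the unpublished schedules and are out of
the verification surface; the published incremental tables are instead
recomputed exactly from their printed per-strategy costs and QALYs, shipped
as a labelled reference fixture.

## Decision analysis

`frontier_analysis()` classifies strategies by the standard two-stage rule:
absolute dominance (another strategy strictly cheaper and at least as
effective; weak dominance and exact ties fold in, ties keeping the
earlier-listed strategy) followed by extended dominance via iterative
ICER-monotonicity repair — removing any strategy whose step ICER exceeds the
next step's until the ladder is non-decreasing. The tests verify this
against an independent oracle that finds the frontier as the set of net
monetary benefit maximizers over all willingness-to-pay breakpoints, on a
thousand random instances. ICERs are reported as undefined (`NA`) rather
than infinite when the incremental effect is non-positive.

`optimal_at_wtp()` walks the ladder to the most effective strategy whose
step ICER is below the threshold — equivalently the NMB argmax, with ties to
the cheaper strategy. It also accepts a published ladder with given step
ICERs, which is how the package reproduces the published
optimal-strategy-at-threshold result from printed (rounded) tables whose
recomputed frontier would otherwise be distorted by rounding — the printed
rounded QALYs tie two frontier strategies at two decimals, so the frontier
is not recomputable from the rounded table and is not asserted as such.

## Sensitivity analysis

One-way analysis re-evaluates the model at each parameter's published low
and high bound (`owsa_default_specs()` carries the published ranges,
including both discount rates at 0.03–0.07), reporting tornado-ordered
outcome bars for a user-chosen outcome — NMB at the configured threshold by
default, since the source does not state which outcome its tornado ranks.

The PSA assigns beta distributions to probabilities and utilities and gamma
distributions to costs, fitted by the method of moments with the standard
deviation inferred from the CI width under a normal approximation
(width/3.92). The source does not name its families; beta/gamma is the
standard choice for these supports. Relative risks are consequently held
fixed in the PSA (a lognormal would be conventional but is outside the
assigned family set); they still vary in the one-way analysis. Parameters
are sampled independently — no correlation structure is published. Because
each fitted distribution is centered on its point estimate, PSA means
converge to the neighbourhood of the base case; the tests check this at
reduced scale with a statistical tolerance, alongside seed determinism,
CEAC normalization at every threshold, and the degenerate all-fixed PSA
reproducing the base case exactly.

## Numerical choices and degenerate inputs

* Occupancy rows are checked to sum to one within 1e-12 every cycle;
  negative occupancy aborts propagation.
* Branch renormalization requires a positive branch sum; an all-zero branch
  is a degenerate-branch error.
* Beta fits with infeasible moments (variance at least mean×(1−mean)) fall
  back to fixed with a warning.
* An empty frontier ladder, a single-strategy frontier, zero masses in a
  screening round and zero-width sensitivity ranges are all defined no-op
  cases, exercised in the tests.
* Problem sizes used by the test and verification runs are chosen to keep a
  complete run light: the full base case is 10 strategies × 70 cycles; the
  microsimulation cross-check uses 200,000 individuals on a 10-cycle
  truncation (agreement within three standard errors); PSA checks run a few
  hundred iterations on the truncated model.

## Limitations

Treated individuals cannot revert to untreated (no non-adherence arrow
exists in the model structure); the event-year utility is the post-state
utility (no separate acute disutility is published); the cohort is
unstratified by sex; budget impact, return on investment and
population-level aggregation are out of scope. The synthetic schedules make
absolute results illustrative; analyses of a real setting should supply
measured schedules via `load_parameters(schedule_dir = ...)` in the same
`age,value` CSV dialect the generator writes.
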