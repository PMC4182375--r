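---
title: "A Markov cohort model of the societal value of hip fracture surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of the societal value of hip fracture surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipcea)
```

## The question the model answers

Displaced hip fractures in patients 65 and older are almost always treated
surgically — hemiarthroplasty or total hip arthroplasty (THA) for displaced
intracapsular (femoral-neck) fractures, a sliding hip screw or
intramedullary (Gamma) nail for extracapsular (trochanteric) fractures.
Surgery restores mobility for many patients; nonoperative care leaves
roughly half of survivors unable to walk, and immobility drives permanent
nursing-home placement. `hipcea` asks whether the *societal* savings that
surgery generates — lower long-term medical spending, avoided custodial
nursing-home care, avoided home modification — offset its higher direct
medical cost, and by how much, per patient and for the annual US fracture
cohort.

## Model structure

The engine (`run_cohort()`) is an annual-cycle Markov cohort model. A unit
cohort of a given age at fracture is propagated until extinction.

**Surgical, intracapsular.** States: *well*, *post aseptic revision*,
*post infection revision*, *dead*. In cycle 1 the cohort either dies or
enters *well*. From cycle 2 onward, patients in *well* can die, stay, or
undergo one revision arthroplasty (aseptic 0.034/yr, infection 0.0053/yr
after hemiarthroplasty; 0.0067/0.0033 after THA). The revising mass
additionally faces the operative mortality of the revision (1.2% aseptic,
1.93% infection). Revision states exit only to death: at most one revision
per patient, by construction.

**Surgical, extracapsular.** Adds a *post conversion* state. A fraction of
cycle-1 survivors (4% sliding hip screw, 6% Gamma nail) undergoes
conversion to arthroplasty within the first year; the fixed-implant *well*
state has no later revision exits, and revisions occur only from
*post conversion*, at the THA revision rates.

**Nonoperative (either fracture type).** Cycle-1 survivors split once:
with probability 0.5 they regain mobility (*mobile*), otherwise they are
permanently *immobile*; thereafter they only die or stay.

**Mortality.** Every arm scales the natural annual death probability
`qx(age)` from a period life table: 3.07x in the first year after
fracture, 1.87x in the second, natural thereafter; nonoperative arms carry
an additional 1.33x factor in the first two years. Scenario analysis can
extend the excess window (cycles 3..`excess_years` at `rr_beyond`, e.g.
1.7x). Products are clamped to 1. Competing risks within a cycle are
sequential — death first, then revision/conversion or the mobility split
among survivors — matching the branch order of the clinical pathway.

Cycle length is one year with full-cycle accounting and no half-cycle
correction: occupancy recorded at the end of a cycle is the state occupied
during that year, and deaths during a year contribute no utility or
accrual for it. This convention makes a ten-year immortal nonoperative
cohort accumulate exactly `10 x (0.5 x 0.39) = 1.95` QALYs, which is the
identity the unit tests pin.

## Utilities and QALYs

Annual utilities: well 0.66 (hemiarthroplasty) / 0.70 (THA) / 0.54
(extracapsular), post-conversion and post-aseptic-revision equal to the
well-state utility of their branch, post-infection-revision 0.39 / 0.38
(intra/extra), mobile 0.39 / 0.38, immobile 0, dead 0. One-time
disutilities: -0.15 for the index operation (whole entering cohort,
cycle 1), -0.2 for each revision or conversion (posted on the transiting
mass, whether or not the patient survives the operation — the operation
happened). `accumulate_qalys()` sums utility-weighted occupancy plus these
one-time terms.

## Cost accounting

`accumulate_costs()` accrues four categories (2009 USD):

* **Direct medical** — the acute index episode (hospitalization through
  6 months: 52,126 hemiarthroplasty, 49,207 THA, 54,054 internal fixation,
  40,795 / 34,509 nonoperative intra/extra) posted once for the whole
  cohort, plus 44,784 per revision or conversion episode.
* **Long-term medical** — 12,941/yr (surgical) or 14,790/yr
  (nonoperative) per alive person-year, with cycle 1 at half weight
  because its first six months sit inside the acute window.
* **Nursing home** — 74,498/yr for the fraction designated long-term
  users. Designation rates are 0.16 / 0.243 / 0.481 by age band at
  fracture (65-74 / 75-84 / 85+) for surgically treated and mobile
  nonoperative patients, 0.9 for immobile nonoperative patients. The band
  is fixed at the age at fracture.
* **Home modification** — 349 once, paid at the end of cycle 1 by
  survivors not designated nursing-home users.

At base values the nonoperative arm's overall designation rate is the
mobility mixture `0.5 x band + 0.5 x 0.9`, i.e. 53% / 57% / 69% across the
three bands — the reconciliation `overall_nonop_nh_rate()` exposes.

**The surgical nursing-home convention.** For the nonoperative arm,
institutionalization is caused by post-fracture immobility — a model state
— so nursing-home cost accrues on the mobility trace, every alive cycle.
For the surgical arm the band rates describe lifetime institutionalization
of the general elderly population, not a consequence of the fracture, and
surgical long-run survival is close to natural. The package therefore
values the surgical arm's custodial exposure *actuarially*: band rate x
annual cost x general-population complete remaining life expectancy at the
age at fracture, applied to the whole entering cohort. This keeps the
comparator's nursing-home cost independent of the transient post-fracture
excess mortality, and it is the convention under which the model's
sensitivity structure — the savings slope of about 229,000 USD per unit
immobile-designation rate at age 80, and a breakeven overall nonoperative
rate of 37-39% against the 24.3% surgical comparator — reproduces the
published decision-model results this package re-implements. A pure
trace-based alternative (`nh_surgical_accrual = "trace"`) is provided; it
lowers surgical nursing-home cost by roughly the excess-mortality deficit
in person-years and pushes the breakeven overall rate near 0.31.
Substitution between nursing-home and long-term medical cost is off by
default (`nh_replaces_longterm = FALSE`); the categories are accounted
separately.

No discounting is applied in the base case (`discount = 0`), which is the
accounting under which total savings are exactly affine in each cost
parameter; a positive rate is available on every accounting function.

## Incremental results

`incremental()` reports savings as nonoperative minus surgical cost per
category (positive = surgery saves money) and the QALY difference as
surgical minus nonoperative. Surgery *dominates* when both are positive;
when surgery costs more but gains QALYs — which happens in extreme old age
— the ICER (extra cost per QALY gained) is reported instead.

```{r base-case}
lt <- us2009_life_table()
pair <- strategy_pair("hemiarthroplasty")
run_incremental(pair, lt, start_age = 80)
```

## Sensitivity, breakeven, scenarios

`one_way_sweep()` re-runs the model over a grid for one dotted parameter
path; `scenario_run()` applies several overrides jointly; `breakeven()`
bisects total savings to zero (default tolerance 1 USD, at most 200
iterations) and, for the immobile designation rate, also reports the
implied overall nonoperative rate. Total savings are affine in every cost
parameter and in the designation rates, so the bisection root coincides
with the closed-form root of the two-point interpolant — an identity the
test suite checks against an independent affine oracle. Cost-only
parameters cannot move the QALY delta (asserted bit-identical), and pure
utility parameters cannot move costs.

```{r breakeven}
suppressWarnings(
  breakeven(pair, lt, "nh_rates.rate_immobile", bracket = c(0.05, 1))
)
```

## National extrapolation

`cohort_counts()` sizes the annual US cohorts from 307,538 discharges
(90% aged 65+, half extracapsular, 85% of intracapsular fractures
displaced): 117,633 displaced intracapsular and 138,392 extracapsular
surgical patients. `national_rollup()` scales the age-weighted per-patient
results linearly, splitting them into *benefits* (long-term medical +
nursing home + home modification savings) and the *direct cost increase*
of surgery.

## Synthetic inputs and what they do (and do not) emulate

`make_synthetic_inputs()` generates both model inputs deterministically:

* **Life table** — a Gompertz-Makeham hazard
  `lambda + exp(beta (age - modal))` with `lambda = 0.0043424`,
  `beta = 0.115`, `modal = 106.52`, fitted to published 2009 US
  total-population period life-table death probabilities at ages 65-95.
  The bundled fixture `us2009_life_table()` is this same table written to
  CSV; it is a synthetic, smooth stand-in calibrated to the real 2009
  table (remaining life expectancy at 80 of 9.0 years), not a
  transcription. Tables end in an absorbing `qx = 1` at age 110.
* **Age at fracture** — a discretized truncated-normal distribution over
  65-98 with mean 84 and SD 7, chosen to match the old-skewed age profile
  of elderly surgical hip-fracture patients in US claims studies (mean age
  about 83-84, over a third aged 85+). The real Medicare age weights
  behind published pooled results are unprinted, so any pooled or national
  figure computed here carries this assumption on top of the life-table
  vintage; single-age results at 80 do not.

The synthetic population reproduces mortality *levels* and the age mix; it
does not emulate sex differences, secular mortality improvement,
comorbidity-dependent frailty, or regional cost variation. Passing tests
therefore validate the model mechanics and its calibration at the
reference ages, not patient-level realism.

## The microsimulation oracle

`microsim_oracle()` simulates individual annual trajectories with the same
transition probabilities, utilities and cost rules, sharing no aggregation
code with the cohort engine, and returns Monte-Carlo means with standard
errors. The suite requires engine-oracle agreement within 3 SE at
n = 200,000 for survival (cycle by cycle, where at least 25 simulated
survivors support the normal approximation), state-years, revisions,
QALYs and every cost category, for surgical and nonoperative arms of both
fracture types. One master seed drives all streams through a
counter-based splitter (`split_seed()`), so every stochastic result is
reproducible from a single integer.

## Numerical choices and edge cases

* Probabilities produced by relative-risk scaling are clamped to 1 (a
  3.07x or 4.08x multiplier exceeds 1 at extreme ages).
* Cohorts run until the dead mass is within `1e-9` of 1 or the absorbing
  cap ends the horizon; occupancy sums to 1 within `1e-9` every cycle and
  the dead mass is monotone (property-tested over random bundles).
* Life tables must cover a contiguous integer age range; a last row with
  `qx < 1` gets an absorbing row appended one year later.
* Revision and conversion events are dated to the cycle in which they
  occur; their episode cost and disutility post in that cycle, and
  first-cycle conversions are not exposed to revision in the same year.
* Parameter overrides re-validate the whole bundle; an immobile
  designation rate below a band rate is allowed but warns, since it
  inverts the clinical expectation.
* The bisection tolerance is absolute (1 USD on total savings) because the
  quantity crossing zero is a dollar difference.

## Problem sizes

The default analyses are small: a cohort run is at most 61 annual cycles,
a full age profile is 34 cohort runs, and the validation microsimulation
uses 200,000 patients (about a second per arm). The acceptance script
re-runs the base cases, both breakevens, the age-weighted profiles and the
national rollup in well under a minute.

## Known limitations

* The source model's printed sensitivity rows are not mutually consistent
  at the few-percent level (its implied surgical nursing-home
  person-years differ between rows and fracture types), so no single
  accounting can reproduce every printed number; this package's
  conventions reproduce the base case, the nursing-home sensitivity
  structure and the breakeven, and document the rest as irreducible
  source ambiguity.
* Pooled age-group and national dollar figures depend on unprinted age
  weights; with the synthetic age distribution the package's national net
  savings are smaller than the published headline, while the per-patient
  QALY gains and the benefit composition (>95% nursing home) match.
* No probabilistic sensitivity analysis: the source analysis is
  deterministic one-way and scenario sweeps, and the package mirrors that
  scope. Re-fracture, second revisions, sex-specific mortality and
  productivity effects are out of scope.
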