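# hipcea

An annual-cycle Markov cohort model of the societal value of surgery for
displaced hip fractures in patients 65 and older.

## The problem

Surgical repair of a displaced hip fracture (hemiarthroplasty or total hip
arthroplasty for intracapsular fractures; a sliding hip screw or Gamma nail
for extracapsular fractures) costs more up front than nonoperative care, but
nonoperative care leaves about half of survivors permanently immobile, and
immobility drives long-term nursing-home placement. `hipcea` quantifies, for
health economists and policy analysts, whether the downstream societal
savings of surgery — lower long-term medical spending, avoided custodial
nursing-home care, avoided home modification — offset its direct medical
cost, per patient and for the annual US fracture cohort.

## The model

A unit cohort of age *a* at fracture moves through health states in one-year
cycles until extinction. Natural mortality *q(a)* from a period life table
is scaled by post-fracture relative risks (3.07 in year 1, 1.87 in year 2,
natural thereafter; an extra 1.33 factor in years 1–2 for nonoperative
care). Surgical cohorts occupy {well, post-conversion, post-revision, dead}
with at most one revision arthroplasty per patient; nonoperative cohorts
split once into {mobile, immobile} and then only die or stay. Lifetime
results per strategy are

* QALYs = Σ cycles Σ states occupancy × utility + one-time disutilities
  (−0.15 index surgery, −0.2 per revision/conversion),
* costs by category: acute episode + 44,784 USD per revision/conversion;
  long-term annual medical cost per alive year (half-weight in cycle 1);
  74,498 USD/yr nursing-home cost for the designated fraction (age-band
  rates 0.16/0.243/0.481 for surgical and mobile patients, 0.9 for immobile
  patients); a one-time 349 USD home modification. All in 2009 USD,
  undiscounted by default.

Incremental results are reported as savings (nonoperative − surgical cost)
and ΔQALY (surgical − nonoperative), with dominance/ICER classification,
one-way sweeps, a bisection breakeven solver on the nursing-home
designation rate, and a linear national rollup over 117,633 displaced
intracapsular + 138,392 extracapsular patients per year. An independent
individual-level microsimulation validates the cohort engine to Monte-Carlo
precision. The accounting conventions — including the actuarial valuation
of the surgical arm's nursing-home exposure — are documented in the
vignette (`vignettes/hip-fracture-markov-model.Rmd`).

## Worked example

```r
library(hipcea)
lt <- us2009_life_table()                  # bundled 2009-calibrated table
pair <- strategy_pair("hemiarthroplasty")  # vs nonoperative intracapsular
run_incremental(pair, lt, start_age = 80)
```

```
<incremental_result> surgery vs nonoperative
  savings direct_medical         -20586 USD
  savings longterm_medical         3316 USD
  savings nursing_home           116312 USD
  savings home_modification        -105 USD
  savings total                   98938 USD
  delta QALY                3.24
  dominant
```

For an 80-year-old with a displaced intracapsular fracture,
hemiarthroplasty costs 20,586 USD more in direct medical care than
nonoperative treatment, but avoided nursing-home use (116,312 USD) and
lower long-term medical spending more than offset it: surgery saves
society 98,938 USD over the patient's lifetime *and* adds 3.2
quality-adjusted life years — it dominates. The threshold at which the
verdict flips:

```r
breakeven(pair, lt, "nh_rates.rate_immobile", bracket = c(0.05, 1))
```

```
<breakeven_result> nh_rates.rate_immobile = 0.495117 (|savings| <= 0.32 USD, 16 iter)
  implied overall nonoperative nursing-home rate: 0.3691
```

Savings vanish only if fewer than about 37% of nonoperatively treated
patients (overall) would need long-term nursing-home care, versus 24.3%
of surgical patients at the same age.

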