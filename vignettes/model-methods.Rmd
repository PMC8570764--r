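---
title: "Model and methods: diabetes care and HEF financing in Cambodia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: diabetes care and HEF financing in Cambodia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hefsim` is a discrete-time Markov microsimulation of the diabetes care
cascade in Cambodia, built to evaluate benefit packages of the Health Equity
Funds (HEF) — the national fee-exemption scheme for the poor — in terms of
societal costs, disability-adjusted life-years (DALYs), and financial risk
protection. This vignette documents the model, its assumptions, the places
where the design was genuinely open and what we chose, and what the test
suite does and does not demonstrate.

## The population

Individuals enter at ages 25–69 with a binary sex and an annual household
income drawn from Gamma(shape 0.5, scale 11,566.32) USD (mean $5,783). HEF
eligibility is an income below the analytic 20th (or 30th) percentile of
that gamma — about $371 for the 20th — and 75% of the eligible are enrolled.
At baseline, 6.2% of the cohort is diabetic; 37% of diabetics already carry
a diagnosis, and diagnosed individuals are assigned oral anti-diabetic (OAD)
therapy (p = 0.224), insulin (0.017), combination therapy (0.07), or
diet-only management otherwise. The population is closed: nobody enters
after baseline, and the simulation follows everyone for 45 annual cycles.

Open choices made here:

* **Age distribution.** The source surveys' age pyramid is not published
  with the parameter set, so baseline ages are uniform on [25, 69] and the
  range is configurable.
* **Sex ratio** is 0.5 (not published; configurable).
* **Eligibility from the analytic quantile**, not the empirical cohort
  quantile: stable across cohort sizes and seeds. The published threshold of
  "approximately $377" differs from the analytic $371 by 1.6%, presumably
  because it came from an empirical survey distribution.
* **Baseline complication burden is zero.** The model has no
  prevalent-complication entry state; complications accrue only during
  simulation. Early-cycle complication prevalence is therefore understated.
* **Background mortality schedule.** The published model cites a five-year
  abridged WHO life table that is not printed; we ship a synthetic
  Gompertz-shaped schedule (relative hazard `exp(0.08 (age - 25))`) rescaled
  so its mean over the uniform baseline ages equals the published mean
  all-cause mortality of 0.046/yr. The schedule is swappable via the config.
* **Gini.** The configured gamma implies a Gini of ≈0.64, not the ≈0.36 the
  income sources report; the shape/scale pair is kept verbatim as the model
  parameter of record.

## One annual cycle

Events fire in a fixed order per cycle:

1. **Background mortality** from the age-scaled schedule.
2. **Diabetes onset** among non-diabetics (0.001/yr).
3. **Screening and diagnosis** among undiagnosed diabetics: an outpatient
   visit occurs with probability 0.117 (0.172 for HEF enrollees), the
   provider level is drawn from the renormalized public-facility shares,
   and — conditional on the visit — diagnosis occurs with probability
   0.370. The visit costs the facility outpatient fee plus the FPG test
   ($1.10), laboratory ($1.41), and outpatient transport ($0.92).
4. **Therapy**: existing OAD users switch to insulin at 0.04/yr; the newly
   diagnosed are assigned a regimen (or diet counselling); every treated
   person-year draws adherence (0.125 baseline, replaced by 0.40 for
   enrollees under drug coverage). Drug costs (OAD $27.86/yr, insulin
   $125.80/yr, combination their sum) accrue in **adherent** person-years
   only — a non-adherent patient is one who did not obtain/take the
   prescription, so no spending occurs. This reading is forced by the
   published incrementals: drug coverage raises total spending slightly,
   which can only happen if higher adherence means more drug purchases.
5. **Complication incidence**: eight complications (nephropathy,
   retinopathy, neuropathy, angina, peripheral vascular disease, myocardial
   infarction, stroke, heart failure), each an independent annual Bernoulli
   with hazard `incidence × m`, where `m` is the complication-specific
   therapy relative risk for adherent treated person-years, 0.90 for
   diet-managed (diagnosed untreated) person-years, and 1 otherwise.
   Complications are comorbid flags and persist for life.
6. **Complication care**: one outpatient care-seeking draw (0.117/0.172,
   doubled for enrollees under complication coverage) prices a treated year
   of every active outpatient-setting complication (per-day drug costs
   annualized ×365, per-year costs as printed; e.g. a treated nephropathy
   year is $6,358) plus outpatient transport. One inpatient draw (0.015)
   prices an episode at (facility per-day + complication drug per-day) ×
   5 days + inpatient transport $11.65. The published episode description
   mentions only the facility cost, but the MI/stroke/heart-failure drugs
   are priced per inpatient day and would otherwise never enter; we charge
   them alongside the facility cost.
7. **Mortality**: acute complications (MI 0.707, stroke 0.693) apply case
   fatality in the event year only; chronic fatal states (nephropathy
   0.311/yr, PVD 0.002/yr, heart failure configurable, default 0) apply it
   annually while active. Diabetes-related mortality (0.030/yr) applies to
   diabetic person-years *without* adherent drug therapy — the mechanism by
   which drug coverage averts diabetes deaths; the published model does not
   state the pathway, and this is our documented choice. Care seeking for
   complications does not modify complication mortality (explicitly outside
   the published model).
8. **Accrual**: survivors accrue a year at the combined disability weight
   `1 − (1 − w_base) ∏ (1 − w_i)` over active complications, where
   `w_base = 0.049` once diabetic; whether *undiagnosed* diabetics carry
   that weight is a config switch (`dw_undiagnosed_counts`, default on,
   following the parameter table; the published prose instead incurs it
   upon diagnosis). Person-years of death accrue no disability (no
   half-cycle correction). Costs are logged undiscounted in the ledger.

Common random numbers: each cycle draws a fixed-length, fixed-order set of
uniforms for the whole cohort, so two strategies run with the same seed
share every stochastic decision that their probabilities do not change. A
strategy that modifies nothing reproduces the comparator ledger bit for
bit, and incremental outcomes carry far less Monte Carlo noise than
independent runs would.

## Strategies and money flows

Seven strategies: the current standard (no financial coverage) and six
packages covering subsets of {diagnostics, drugs, complications}. Coverage
affects only enrolled beneficiaries: diagnostics coverage applies RR 1.5 to
diagnosis and RR 2.0 to care seeking; drug coverage replaces adherence with
0.40; complication coverage applies RR 2.0 to both outpatient and inpatient
complication care seeking (the published impact is stated for "care
utilization" without restriction). The adherence effect is an absolute
replacement, not a multiplier, following its publication as "p = 0.40".

For a covered segment and an enrolled beneficiary, the fund pays
`subsidy × utilization × cost` (subsidy 0.80 or 1.00; point-of-service
utilization 1.00 per the parameter table, though 88% appears in the source
prose) and the patient pays the rest; uncovered costs are fully
out-of-pocket, and transport is always out-of-pocket. Government plus
out-of-pocket equals the direct medical cost identically. The screening
visit fee is treated as part of the diagnostic service package.

## Outcomes

* **Costs** are discounted at 3%/yr by cycle index and reported by payer.
* **DALYs = YLL + YLD**, undiscounted. YLL per death is remaining life
  expectancy (67 men / 71 women) at the age of death, floored at zero, for
  diabetes-related and complication deaths only — background deaths are not
  part of the diabetes burden. YLD sums the ledger's disability years.
* **Catastrophic health expenditure (CHE)**: diabetic person-years whose
  undiscounted annual OOP (medical + transport) strictly exceeds 10/25/40%
  of the person's annual household income. Assessed per person-year — the
  published case counts (hundreds of thousands against 3.2 million people
  over 45 years) are only consistent with person-year counting.
* **Impoverishment**: person-years pushed from at-or-above to below the
  $1.90/day line by OOP spending.
* **ICERs** are incremental cost per DALY or CHE case averted, rounded to
  the dollar; cost-saving strategies are flagged dominant but keep their
  signed ratio, matching the published tables' convention.
* Extensive quantities scale by persons-represented-per-simulated-person
  (20 for 160,000 standing for the ~3.2 million HEF-eligible).

## Uncertainty analysis

Two crossed layers, mirroring the published 50 × 100 design: parameter sets
drawn from the registry's distributions (lognormal costs, beta
probabilities; entries without a distribution stay at their point values;
strategy effects Normal(base, σ² = 0.1) truncated at 0, adherence capped at
1), and bootstrap populations resampled with replacement (40,000 by
default). Every cell simulates all strategies and the comparator with one
seed (common random numbers); whether the published analysis crossed the
layers fully or marginally is not stated, and the full cross is the
default. Results are 2.5/97.5 percentile ranges per strategy plus the
fraction of cells with no DALY gain.

## Numerical and engineering choices

* Seeds pin the Mersenne-Twister generator; cohorts, ledgers, and PSA draws
  are bit-reproducible.
* Probabilities composed with relative risks are clamped at 1.
* Provider shares are renormalized to a conditional distribution over the
  four public levels (the printed shares are population proportions).
* Per-day drug cost distributions are specified on the annualized ×365
  scale (their lognormal means match 365 × the printed per-day points);
  draws are rescaled back to per-day.
* The registry ships with a consistency audit (`consistency_report()`):
  the two outpatient care-seeking betas appear swapped relative to their
  point values, and the provider-share beta means sit below the printed
  shares; the audit reports, the base case uses the printed point values.
* The MI incidence is stored verbatim (0.174/yr) although it is an order of
  magnitude above the other cardiovascular incidences and its trial source;
  it is a named config key and can be overridden.
* The heart-failure case fatality is blank in the source table; it defaults
  to 0, like the other complications assumed non-fatal, and is a config key.

## Problem sizes

The packaged analyses run at three scales, chosen as the package's standard
workflows: unit and property tests use hundreds to a few thousand
individuals (seconds); the reproduction test uses 16,000 eligible
individuals at scale factor 200 — one tenth of the published scale with
identical expected values for all intensive quantities; and
`scripts/acceptance.R` runs the published scale, 160,000 eligible
individuals × 45 cycles × three strategies (about a minute). The
uncertainty smoke design is 2 parameter sets × 2 bootstrap populations of
4,000.

## What the tests do and do not show

The generator emulates the *assumed* population (uniform ages, gamma
income, binomial disease states), so green tests demonstrate internal
correctness — conservation identities, published unit values, closed-form
distribution agreement, ICER arithmetic on the published incremental
columns — and order-of-magnitude agreement with the published headline
results, not calibration to Cambodian microdata. Three published headline
values are not reproduced within tolerance and are deliberately left
unmatched rather than fitted: the mean annual direct medical cost per
diabetic (~$62 published vs ~$90–100 here), the CHE case count under the
current standard (~676,000 published vs ~130,000–150,000 here), and the
36% death share of averted DALYs (~100% here). All three trace to
under-specification or internal inconsistency of the source: the published
CHE count implies catastrophic spending in roughly 45% of diabetic
person-years, unreachable with the printed annual care-seeking
probabilities, while matching the published per-diabetic cost would require
*less* care contact, not more; and with the verbatim MI incidence,
complication deaths dominate the averted-DALY mix. The model keeps the
printed parameters and documents the gaps.
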