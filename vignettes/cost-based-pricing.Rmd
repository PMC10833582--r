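---
title: "Cost-based pricing of drugs with expanding indications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-based pricing of drugs with expanding indications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpricer)
```

## The model

Cost-based pricing (CBP) builds a drug price from its production-side
inputs rather than from assessed therapeutic value. The original
single-indication form amortizes the initial research and development
outlay over every patient expected to be treated before the patent
expires:

$$C_{tx} = \left(\frac{C_{rd}}{N_p} + C_{man}\right)(1 + M_p)$$

where $C_{rd}$ is capitalized, risk-adjusted R&D cost, $N_p$ the eligible
patient population over the remaining patent period, $C_{man}$ the
manufacturing cost per treatment, and $M_p$ a profit margin.

Modern immuno-oncology drugs rarely stay in one indication, so `cbpricer`
implements the time-dependent extension: at evaluation year $t$ the price
per treatment is

$$C_{tx}(t) = \left(
  \frac{C_{rd} + N_{ind}(t)\,C_{ex}}{\sum N_p(t)}
  + \bar{D}(t)\, C_{man}\right)(1 + M_p + M_{sm})$$

with $N_{ind}(t)$ the number of post-launch indications approved by $t$,
$C_{ex}$ the incremental R&D cost per new indication, $\bar D(t)$ the
patient-weighted mean dose (grams per treatment) across the active
indications, $C_{man}$ now per gram of antibody, and $M_{sm}$ a sales &
marketing margin. Per-vial prices allocate the R&D share per gram and
scale to the vial content, so they compare directly with list prices.

Three evaluation modes share this engine:

* **cumulative by year** — one price per calendar year from launch to
  patent expiry;
* **cumulative by indication** — one price after each label expansion
  (identical to the yearly price at that indication's approval year);
* **indication-based (IBP)** — non-cumulative: indication 1 carries all of
  $C_{rd}$ and only its own patients; indication $k \ge 2$ carries only
  $C_{ex}$ and its own patients.

### The patient denominator

The single biggest interpretive choice is what $\sum N_p(t)$ means while
the label is still growing. `cbpricer` lets every indication approved by
$t$ contribute its projected eligible patients for *every* year from its
approval through `patent_expiry − 1`: each indication is amortized over
its own full remaining window, and the remaining patent time shrinks for
indications approved late. Prices therefore fall as big indications
accrue, and can step upward when a late indication brings incremental R&D
but few remaining patient-years. Within a fixed indication set the yearly
price is constant — the model varies by indication arrivals, not by
calendar drift. This reading is isolated in `cumulative_np()` /
`patient_pool()` so an alternative (e.g. only future patient-years at
$t$) can be swapped in without touching the pricing algebra.

A related algebraic point: summing each indication's dose times $C_{man}$
literally would charge every treatment the manufacturing cost of all
indications' schedules at once. The engine instead uses the
patient-weighted mean dose, which reproduces the published per-vial
decompositions and keeps the manufacturing term a per-treatment quantity.

### From incidence to eligible patients

Each indication converts incident cases into drug-buying patients
multiplicatively:

```
persons(year) × incidence/100k × subtype × stage × line × symptomatic
  × eligible × (1 − untreated) × (1 − trial) × market_share(year)
```

Market share is a step function of the competitor count: 1 with no
competitor, 0.5 with one, 0.33 (the conventional printed value, not 1/3)
with two or more. Patient counts stay real-valued — the denominator is an
amortization base, not a census. Population years missing from the table
are linearly interpolated; extrapolation beyond it is off by default and,
when enabled, follows the last five-year linear trend.

## Parameters that matter

| parameter | meaning | packaged default | why |
|---|---|---|---|
| `crd_adjusted` | initial R&D, launch-year EUR | 3,795,249,282 (2015) / 3,165,890,999 (2014) | published mean for antineoplastic agents, capitalized at 10.5%, converted to launch-year euros |
| `cex_adjusted` | R&D per new indication | 267,020,244 / 222,740,834 | published repurposing-cost estimate, converted |
| `cman_per_gram_adjusted` | mAb manufacturing EUR/g | 42.61 / 35.55 | adjusted bioprocessing estimate; the low/high literature bounds are scenarios 5–6 |
| `mp` | profit margin | 0.20 | published base case; 0 and 0.765 are scenarios 7–8 |
| `msm` | sales & marketing margin | 0.30 | not printed anywhere; the 76.5%-margin scenario prices pin it: 43,972/31,941 = (1+0.765+x)/(1+0.2+x) gives x ≈ 0.30, confirmed independently by 1,219/885 |
| `patent_expiry` | recoup horizon | 2025 / 2028 | published conservative estimates; 2035/2036 via scenario 9 |
| `vial_grams` | active ingredient per vial | 1.8 g / 0.1 g | marketed presentations |

All money is in launch-year euros. Source-currency inputs are converted by
a single multiplicative factor per (cost source, target year); the factor
table is derived from published unadjusted/adjusted input pairs, since the
underlying inflation/PPP series are not published. Two internal
consistency properties are testable and tested: factors within a source
are identical across magnitudes, and the 2014-to-2015 euro ratio
(≈ 0.8342) is the same for every source.

## The packaged case studies

Profiles for daratumumab (multiple myeloma, launch 2015, expiry 2025, no
competitor) and pembrolizumab (seven tumour types here, launch 2014,
expiry 2028, nivolumab-based competition per indication) ship as YAML
fixtures. Their cost inputs, incidence rates, patent years, vial contents,
margins and competitor entries are published figures. Their per-indication
eligibility cascades and weighted doses are **reconstructions**: the
clinical-opinion tables behind the original study are not public. Two
constants per drug (the launch indication's `eligible_share` and a shared
post-launch `eligible_share`) were calibrated — closed form for the launch
anchor, root-finding for the minimum — so that against the packaged
population table the launch-year per-vial price and the minimum yearly
price equal the published 31,941/823 EUR (daratumumab) and 885/52 EUR
(pembrolizumab). Everything downstream (sensitivity transforms, scenario
prices, indication-based prices) is then genuine model output, not
calibration.

```{r case-study}
fit <- cbp(cbp_case_study("daratumumab"))
summary(fit)
```

## Sensitivity and scenario analysis

`dsa()` recomputes the whole schedule with one input scaled over
0.7–1.3 in steps of 0.1: the patient projection (`np`), initial R&D
(`crd`), the profit-margin *value* (`mp`; 0.20 becomes 0.26 at +30% — the
step scales the margin, not the whole multiplier) or the per-gram
manufacturing cost (`cman`). At step 1.0 the base case is reproduced bit
for bit because the same code path runs with a neutral scale.

One caveat surfaced by first-principles recomputation: the published
manufacturing-cost range duplicates the profit-margin range exactly,
which margin algebra cannot produce (a ±30% margin step changes the
multiplier to 1.44/1.56, while a ±30% manufacturing step moves a term
that is two orders of magnitude smaller than the launch-year R&D share).
The engine computes the manufacturing DSA honestly (≈ 31,976 EUR launch
maximum for daratumumab) and the duplicated figure is treated as a
transcription artefact, not a target.

`run_scenario()` applies the ten predefined alternative-input scenarios
(R&D bounds, uncapitalized R&D, 10%-of-initial incremental R&D,
manufacturing bounds, margins 0%/76.5%, extended patent, indication-based
pricing). Scenario 7 zeroes the profit margin only — the published
first-year scenario-7 values are absent so both variants exist, with
`zero_msm = TRUE` as the option. Scenario 3 replaces initial R&D only
(`uncapitalized_cex = TRUE` extends it to the incremental cost; the
launch-year price is insensitive to the choice).

```{r scenario}
round(run_scenario(cbp_case_study("daratumumab"), 8)$schedule$per_vial[1])
```

## The synthetic generator

`synthetic_profile(seed, ...)` draws internally consistent profiles:
staggered approvals (1–3 year gaps), oncology-range incidence
(2.5–142/100k), uniform cascade fractions, 8–14 year patent windows,
doses of 2–50 g with a vial strictly smaller than any dose, and an
occasional competitor. It is a pure function of the seed (the caller's RNG
state is restored), which makes property sweeps reproducible. It emulates
the *structure* of real multi-indication profiles, not their joint
distributions: real cascades are correlated with tumour biology and real
approval sequences with trial read-outs, so passing property tests on
synthetic profiles demonstrates algebraic correctness (monotonicity,
scaling, mode identities, oracle equality), not epidemiological realism.

## Numerical choices and degenerate inputs

* All internal arithmetic is full double precision; prices are rounded to
  whole euros only for display, and to cents in default CSV exports
  (`full_precision = TRUE` round-trips exactly).
* Published price anchors are asserted at ±0.25% to absorb the euro
  rounding of the printed bases.
* A zero patient pool (e.g. an absorbing cascade) raises a domain error by
  default; `allow_unpriceable = TRUE` returns a flagged `NA` record
  instead, so batch runs can keep going.
* Evaluation uses integer calendar years from launch to `patent_expiry −
  1`; there are no sub-year intervals. Pricing at or past expiry is an
  error ("patent expired"), matching the model's assumption that revenue
  stops at expiry.
* Validation is eager and cumulative: profile loading reports every
  violated invariant with its field path, rather than stopping at the
  first.

## Known limitations

* The reconstructed cascades are calibrated, not sourced; per-indication
  prices between the two pinned anchors (e.g. the middle of the
  pembrolizumab IBP curve) are plausible but not authoritative.
* The packaged population series is an approximate reconstruction of the
  more-developed-regions aggregate; because the profiles are calibrated
  against it, the pinned prices are unaffected, but absolute patient
  counts inherit its level.
* No prevalence pool, no country stratification, no post-expiry revenue
  decay, no value-based (clinical-benefit-linked) margins — all outside
  the model's scope.

## Problem sizes

The shipped analyses are desk-scale by nature: case-study grids are 10–14
years × ≤ 7 indications, DSA tables a few hundred cells, and the property
sweeps use 100 seeded synthetic profiles with ≤ 4 indications. The full
test suite and the reproduction script run in seconds.
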