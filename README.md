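# cbpricer

Cost-based pricing of drugs with expanding indications.

Health-technology-assessment and pricing analysts increasingly discuss
cost-based prices (CBP) — prices built from what a drug costs to develop
and make, rather than from assessed therapeutic value — as a transparency
instrument for expensive oncology drugs. For a drug whose label keeps
expanding (pembrolizumab gained dozens of indications after its melanoma
launch; daratumumab went from fourth-line to first-line multiple
myeloma), a single static CBP is meaningless: the eligible population,
the cumulative R&D outlay and the remaining patent time all change with
every approval. `cbpricer` implements the time- and
indication-dependent CBP model for exactly this situation.

## The model

At evaluation year *t*, the price per treatment is

```
C_tx(t) = ( (C_rd + N_ind(t) · C_ex) / Σ N_p(t)  +  D̄(t) · C_man ) · (1 + M_p + M_sm)
```

* `C_rd` — initial R&D cost (capitalized, risk-adjusted), launch-year EUR
* `C_ex` — incremental R&D per new indication; `N_ind(t)` post-launch
  indications approved by *t*
* `Σ N_p(t)` — eligible patients: for every active indication, incident
  cases (incidence × region population) filtered through a multiplicative
  eligibility cascade (subtype, stage, line, symptomatic status, untreated
  and trial fractions) and a competitor-dependent market share (1 / 0.5 /
  0.33), summed from its approval year to patent expiry
* `D̄(t)` — patient-weighted mean dose (g); `C_man` — manufacturing cost
  per gram of antibody
* `M_p`, `M_sm` — profit and sales & marketing margins

Per-vial prices allocate the R&D share per gram and scale to the vial
content. Three modes share the engine: cumulative per year, cumulative
per indication, and non-cumulative indication-based pricing (IBP), plus a
stepwise one-way deterministic sensitivity analysis (±30% in 10% steps)
and a ten-scenario engine (R&D bounds, uncapitalized R&D, manufacturing
bounds, margins 0%/76.5%, extended patent, IBP).

## Worked example

```r
library(cbpricer)
fit <- cbp(cbp_case_study("daratumumab"))
print(fit)
#> Cost-based prices for daratumumab (cumulative year mode)
#>  year per_treatment per_vial patients
#>  2015        734643    31941     7777
#>  2016         34433     1382   193034
#>  2017         34433     1382   193034
#>  2018         23966      893   311056
#>  2019         21728      823   368874
#>  ...
#>  2024         21728      823   368874
```

At launch (2015) daratumumab has one indication — heavily pre-treated
multiple myeloma, about 7,800 eligible patients over the ten patent
years — so the entire initial R&D burden lands on them: 31,941 EUR per
1.8 g vial. The 2016 combination-therapy approval multiplies the
amortization base by ~25× and the price collapses to 1,382 EUR; the
first-line approvals push it to its 823 EUR floor. (The 2019 row shows
the late-indication effect: new incremental R&D with only six remaining
patent years.)

```r
summary(fit)
#> Cost-based pricing summary: daratumumab (year mode, 10 points)
#>   per-vial price range : 823 – 31,941 EUR
#>   launch/first price   : 31,941 EUR per vial
#>   margin multiplier    : 1.500

dsa_range(dsa(cbp_case_study("pembrolizumab"), "np"))
#>        min        max
#>   41.23058 1262.00036
```

The patient projection is the most influential input: scaling
pembrolizumab's eligible patients by 0.7–1.3 spans 41–1,262 EUR per
0.1 g vial across the patent life.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","cbp-cli.R",package="cbpricer"))')" \
  price --drug daratumumab --out prices.csv
```

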