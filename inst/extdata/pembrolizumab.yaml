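# Reconstructed case-study profile: pembrolizumab (anti-PD-1 mAb, multiple
# tumour types). Pinned published quantities: launch-year euro cost inputs,
# margins, patent years, vial content, disease incidence rates, competitor
# entry (nivolumab monotherapy / nivolumab + ipilimumab), launch-year and
# minimum yearly per-vial prices. The eligible_share constants marked
# CALIBRATED were solved so that, against the packaged UN-MDR population
# table, the launch-year per-vial price is 885 EUR and the minimum yearly
# price is 52 EUR.
schema_version: 1
name: pembrolizumab
region: UN-MDR
launch_year: 2014
patent_expiry: 2028
alt_patent_expiry: 2036          # US patent estimate (scenario use)
vial_grams: 0.1                  # 4 ml vial at 25 mg/ml
conversion_factor: 0.709650093921 # USD -> EUR(2014), derived from cost-input pairs
cost_basis_year: 2014
cost:
  crd_adjusted: 3165890999       # initial R&D, EUR(2014)
  cex_adjusted: 222740834        # R&D per new indication, EUR(2014)
  cman_per_gram_adjusted: 35.55  # mAb manufacturing, EUR(2014)/g
  mp: 0.20
  msm: 0.30
indications:
  - label: "melanoma, unresectable/metastatic"
    approval_year: 2014
    incidence_per_100k: 21.7
    grams_per_treatment: 4.2     # ~21 x 200 mg cycles weighted for duration
    cascade:
      stage_share: 0.20
      eligible_share: 0.632234016932   # CALIBRATED (launch-year price anchor)
      untreated_fraction: 0.25
      trial_fraction: 0.10
    competitors:                 # nivolumab 2015; nivolumab + ipilimumab 2016
      - {year: 2015, count: 1}
      - {year: 2016, count: 2}
  - label: "NSCLC, advanced"
    approval_year: 2015
    incidence_per_100k: 69.5
    grams_per_treatment: 4.2
    cascade:
      stage_share: 0.55
      eligible_share: 0.672904892131   # CALIBRATED (minimum yearly price anchor)
      untreated_fraction: 0.25
      trial_fraction: 0.10
    competitors:
      - {year: 2015, count: 1}
  - label: "HNSCC, recurrent/metastatic"
    approval_year: 2016
    incidence_per_100k: 21.8
    grams_per_treatment: 3.6
    cascade:
      stage_share: 0.60
      eligible_share: 0.672904892131   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.25
      trial_fraction: 0.10
    competitors:
      - {year: 2016, count: 1}
  - label: "classical Hodgkin lymphoma, refractory"
    approval_year: 2017
    incidence_per_100k: 2.5
    grams_per_treatment: 3.6
    cascade:
      line_share: 0.15
      eligible_share: 0.672904892131   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.25
      trial_fraction: 0.10
    competitors:
      - {year: 2016, count: 1}
  - label: "urothelial carcinoma, advanced"
    approval_year: 2017
    incidence_per_100k: 26.3
    grams_per_treatment: 3.6
    cascade:
      stage_share: 0.50
      eligible_share: 0.672904892131   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.25
      trial_fraction: 0.10
    competitors:
      - {year: 2017, count: 1}
  - label: "gastric/oesophageal cancer, advanced"
    approval_year: 2018
    incidence_per_100k: 32.1
    grams_per_treatment: 3.6
    cascade:
      stage_share: 0.60
      eligible_share: 0.672904892131   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.25
      trial_fraction: 0.10
  - label: "renal cell carcinoma, advanced"
    approval_year: 2019
    incidence_per_100k: 19.3
    grams_per_treatment: 3.6
    cascade:
      stage_share: 0.40
      eligible_share: 0.672904892131   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.25
      trial_fraction: 0.10
    competitors:
      - {year: 2018, count: 2}
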