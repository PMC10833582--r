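# Reconstructed case-study profile: daratumumab (anti-CD38 mAb, multiple
# myeloma). Pinned published quantities: launch-year euro cost inputs,
# margins, patent years, vial content, disease incidence, launch-year and
# minimum yearly per-vial prices. The per-indication cascades and weighted
# doses are reconstructions: the two eligible_share constants marked
# CALIBRATED were solved so that, against the packaged UN-MDR population
# table, the launch-year per-vial price is 31,941 EUR and the minimum
# yearly price is 823 EUR.
schema_version: 1
name: daratumumab
region: UN-MDR
launch_year: 2015
patent_expiry: 2025
alt_patent_expiry: 2035          # less conservative patent estimate (scenario use)
vial_grams: 1.8                  # 1,800 mg subcutaneous presentation
conversion_factor: 0.8507238595  # USD -> EUR(2015), derived from cost-input pairs
cost_basis_year: 2015
cost:
  crd_adjusted: 3795249282       # initial R&D, EUR(2015)
  cex_adjusted: 267020244        # R&D per new indication, EUR(2015)
  cman_per_gram_adjusted: 42.61  # mAb manufacturing, EUR(2015)/g
  mp: 0.20                       # profit margin
  msm: 0.30                      # sales & marketing margin
indications:
  - label: "multiple myeloma, >=3 prior lines (monotherapy)"
    approval_year: 2015
    incidence_per_100k: 7.6
    grams_per_treatment: 41.4    # ~23 x 1.8 g over the dosing schedule
    cascade:
      line_share: 0.05           # reaching 4th-line systemic therapy
      symptomatic_share: 0.9
      eligible_share: 0.209137426983   # CALIBRATED (launch-year price anchor)
      untreated_fraction: 0.05
      trial_fraction: 0.10
  - label: "multiple myeloma, >=1 prior line (combination)"
    approval_year: 2016
    incidence_per_100k: 7.6
    grams_per_treatment: 45.0
    cascade:
      line_share: 0.45
      symptomatic_share: 0.9
      eligible_share: 0.614875854949   # CALIBRATED (minimum yearly price anchor)
      untreated_fraction: 0.05
      trial_fraction: 0.10
  - label: "multiple myeloma, first line, transplant-ineligible"
    approval_year: 2018
    incidence_per_100k: 7.6
    grams_per_treatment: 54.0    # longer frontline exposure
    cascade:
      line_share: 0.35
      symptomatic_share: 0.9
      eligible_share: 0.614875854949   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.0
      trial_fraction: 0.10
  - label: "multiple myeloma, first line, transplant-eligible"
    approval_year: 2019
    incidence_per_100k: 7.6
    grams_per_treatment: 43.2
    cascade:
      line_share: 0.20
      symptomatic_share: 0.9
      eligible_share: 0.614875854949   # CALIBRATED (shared with indication 2)
      untreated_fraction: 0.0
      trial_fraction: 0.10
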