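# Shared builders and independent oracles for the test suite.

# Flat population: `persons` people in every year of [2010, 2040].
flat_population <- function(persons = 1e6) {
  population_table(2010:2040, rep(persons, 31), region = "flat")
}

# Minimal single-indication profile with an all-ones cascade.
simple_profile <- function(crd = 1e9, cex = 1e8, cman = 50, mp = 0.2,
                           msm = 0.3, launch = 2015, expiry = 2020,
                           incidence = 10, dose = 10, vial = 1,
                           cascade = eligibility_cascade(),
                           extra_indications = list()) {
  drug_profile(
    name = "test-drug", launch_year = launch, patent_expiry = expiry,
    vial_grams = vial,
    cost = cost_structure(crd, cex, cman, mp, msm),
    indications = c(list(indication("ind-1", launch, incidence, cascade,
                                    dose)),
                    extra_indications),
    region = "flat"
  )
}

# --- independent oracles: plain-loop enumeration of patient-years ----------

oracle_cascade <- function(c) {
  c$subtype_share * c$stage_share * c$line_share * c$symptomatic_share *
    c$eligible_share * (1 - c$untreated_fraction) * (1 - c$trial_fraction)
}

oracle_patients_one_year <- function(ind, y, pop) {
  cnt <- 0
  if (!is.null(ind$competitors)) {
    for (r in seq_len(nrow(ind$competitors))) {
      if (ind$competitors$year[r] <= y) cnt <- max(cnt, ind$competitors$count[r])
    }
  }
  share <- if (cnt == 0) 1 else if (cnt == 1) 0.5 else 0.33
  persons <- stats::approx(pop$years, pop$persons, xout = y)$y
  persons * ind$incidence_per_100k / 1e5 * oracle_cascade(ind$cascade) * share
}

# Cumulative-year price by brute-force enumeration over (indication, year).
oracle_price_year <- function(profile, t, pop) {
  rd <- profile$cost$crd_adjusted
  npts <- 0; grams <- 0
  for (ind in profile$indications) {
    if (ind$approval_year > t) next
    if (ind$approval_year > profile$launch_year) {
      rd <- rd + profile$cost$cex_adjusted
    }
    for (y in ind$approval_year:(profile$patent_expiry - 1)) {
      n <- oracle_patients_one_year(ind, y, pop)
      npts <- npts + n
      grams <- grams + n * ind$grams_per_treatment
    }
  }
  mult <- 1 + profile$cost$mp + profile$cost$msm
  cman <- profile$cost$cman_per_gram_adjusted
  dw <- grams / npts
  vial <- profile$vial_grams
  list(
    np = npts,
    per_treatment = (rd / npts + dw * cman) * mult,
    per_vial = (rd / npts / (dw / vial) + vial * cman) * mult
  )
}
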