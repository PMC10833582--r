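test_that("per-treatment price follows the amortization formula", {
  # zero R&D: pure manufacturing plus margin
  expect_equal(price_per_treatment(0, 10, 100, 0.2), 120)
  # pure amortization, no margin
  expect_equal(price_per_treatment(100, 4, 0, 0), 25)
  # hand arithmetic at realistic magnitudes
  expect_equal(price_per_treatment(4937400000, 1e6, 100, 0.2), 6044.88)
  expect_error(price_per_treatment(1e9, 0, 100, 0.2), "np")
  expect_error(price_per_treatment(1e9, -5, 100, 0.2), "np")
})

test_that("per-vial composition allocates R&D per gram and scales to vials", {
  # one vial per treatment: per-vial equals per-treatment
  expect_equal(per_vial_price(21217.3, 42.61, 1.8, 1.8, 1.5),
               (21217.3 + 1.8 * 42.61) * 1.5)
  expect_equal(per_vial_price(21217.3, 42.61, 1.8, 1.8, 1.5), 31941,
               tolerance = 1 / 31941)
  # doubling the dose halves the R&D share per vial
  one <- per_vial_price(1000, 0, 10, 1, 1)
  two <- per_vial_price(1000, 0, 20, 1, 1)
  expect_equal(two, one / 2)
  expect_error(per_vial_price(1000, 50, 0.5, 1, 1.5), "vial")
  expect_error(per_vial_price(1000, 50, -1, 1, 1.5), "> 0")
})

test_that("price decomposition inverts the per-vial composition", {
  d <- decompose_price(31941, 1.8, 42.61, 0.2, 0.3)
  expect_equal(unname(d["rd_component"]), 31941 / 1.5 - 1.8 * 42.61)
  expect_equal(unname(d["rd_component"]), 21217.3, tolerance = 1e-4)
  expect_equal(unname(d["manuf_component"]), 76.698)

  d2 <- decompose_price(885, 0.1, 35.55, 0.2, 0.3)
  expect_equal(unname(d2["rd_component"]), 586.445)
  expect_equal(unname(d2["manuf_component"]), 3.555)

  # round trip at arbitrary components
  for (a in c(0.5, 123.4, 9e4)) {
    for (b in c(0.1, 77, 1500)) {
      dd <- decompose_price((a + b) * 1.5, 1, b, 0.2, 0.3)
      expect_equal(unname(dd["rd_component"]), a, tolerance = 1e-9)
      expect_equal(unname(dd["manuf_component"]), b, tolerance = 1e-9)
    }
  }
  expect_error(decompose_price(10, 1.8, 42.61, 0.2, 0.3),
               "manufacturing floor")
})

test_that("cumulative model with one indication and one-year window reduces
           to the original per-treatment formula", {
  pop <- flat_population(1e6)
  prof <- simple_profile(crd = 5e8, cman = 40, mp = 0.25, msm = 0,
                         launch = 2015, expiry = 2016, incidence = 20,
                         dose = 5, vial = 1)
  row <- cumulative_price_by_year(prof, 2015, pop)
  np <- 1e6 * 20 / 1e5   # one year, all-ones cascade
  expect_equal(row$total_patients, np)
  expect_equal(row$per_treatment,
               price_per_treatment(5e8, np, 5 * 40, 0.25))
})

test_that("cumulative prices match the brute-force patient-year oracle", {
  pop <- flat_population(2.5e6)
  cases <- list(c(11, 1), c(23, 2), c(57, 3), c(91, 3))
  for (case in cases) {
    seed <- case[1]
    prof <- synthetic_profile(seed, n_indications = case[2])
    fit <- cbp(prof, pop)
    for (i in seq_len(nrow(fit$schedule))) {
      t <- fit$schedule$index[i]
      o <- oracle_price_year(prof, t, pop)
      expect_equal(fit$schedule$per_treatment[i], o$per_treatment,
                   tolerance = 1e-9)
      expect_equal(fit$schedule$per_vial[i], o$per_vial, tolerance = 1e-9)
      expect_equal(fit$schedule$total_patients[i], o$np, tolerance = 1e-9)
    }
  }
})

test_that("price is monotone in every cost input and in the patient pool", {
  pop <- flat_population(1e6)
  ind2 <- indication("ind-2", 2017, 30, eligibility_cascade(), 12)
  base <- simple_profile(extra_indications = list(ind2))
  p0 <- cbp(base, pop)$schedule$per_treatment

  pw <- getFromNamespace("profile_with", "cbpricer")
  expect_true(all(cbp(pw(base, crd = base$cost$crd_adjusted * 1.5),
                      pop)$schedule$per_treatment > p0))
  expect_true(all(cbp(pw(base, cman = base$cost$cman_per_gram_adjusted * 2),
                      pop)$schedule$per_treatment > p0))
  expect_true(all(cbp(pw(base, mp = 0.35), pop)$schedule$per_treatment > p0))
  expect_true(all(cbp(pw(base, msm = 0.5), pop)$schedule$per_treatment > p0))
  # cex only bites once a second indication is on board (k >= 2)
  cex_up <- cbp(pw(base, cex = base$cost$cex_adjusted * 3), pop)$schedule
  expect_equal(cex_up$per_treatment[1:2], p0[1:2])   # 2015, 2016: 1 indication
  expect_true(all(cex_up$per_treatment[3:5] > p0[3:5]))
  # more patients -> strictly cheaper
  expect_true(all(cbp(base, pop, np_scale = 2)$schedule$per_treatment < p0))
})

test_that("scaling every year's patients by s divides the R&D component by s", {
  pop <- flat_population(1e6)
  prof <- simple_profile()
  base <- cbp(prof, pop)$schedule
  for (s in c(0.25, 2, 7.5)) {
    scaled <- cbp(prof, pop, np_scale = s)$schedule
    expect_equal(scaled$rd_component, base$rd_component / s,
                 tolerance = 1e-12)
    expect_equal(scaled$manuf_component, base$manuf_component)
  }
})

test_that("the three modes coincide on their launch-indication rows", {
  pop <- flat_population(1e6)
  prof <- cbp_case_study("daratumumab")
  by_year <- cumulative_price_by_year(prof, prof$launch_year)
  by_ind <- cumulative_price_by_indication(prof, 1)
  ibp <- indication_based_price(prof, 1)
  expect_equal(by_ind$per_vial, by_year$per_vial)
  expect_equal(ibp$per_vial, by_ind$per_vial)
  expect_equal(ibp$per_treatment, by_year$per_treatment)

  # single-indication profile: all modes agree everywhere at launch
  p1 <- simple_profile()
  expect_equal(indication_based_price(p1, 1, pop)$per_vial,
               cumulative_price_by_year(p1, 2015, pop)$per_vial)
})

test_that("breakdown rows satisfy the margin identity", {
  pop <- flat_population(1e6)
  for (seed in c(3, 44)) {
    fit <- cbp(synthetic_profile(seed), pop)
    s <- fit$schedule
    expect_equal(s$per_treatment,
                 (s$rd_component + s$manuf_component) * s$multiplier,
                 tolerance = 1e-9)
    expect_true(all(s$rd_component >= 0 & s$manuf_component >= 0))
  }
})

test_that("indication-based pricing amortizes only incremental R&D after
           the launch indication", {
  pop <- flat_population(1e6)
  ind2 <- indication("ind-2", 2017, 30, eligibility_cascade(), 12)
  prof <- simple_profile(cex = 0, cman = 0, extra_indications = list(ind2))
  row <- indication_based_price(prof, 2, pop)
  expect_equal(row$per_treatment, 0)
  expect_equal(row$per_vial, 0)
})

test_that("degenerate patient pools raise by default, flag when permitted", {
  pop <- flat_population(1e6)
  dead <- indication("ind-dead", 2017, 30,
                     eligibility_cascade(untreated_fraction = 1), 12)
  prof <- simple_profile(extra_indications = list(dead))
  expect_error(indication_based_price(prof, 2, pop), "unpriceable")
  row <- indication_based_price(prof, 2, pop, allow_unpriceable = TRUE)
  expect_true(row$unpriceable)
  expect_true(is.na(row$per_vial))
  # absorbing cascade kills the patient projection entirely
  expect_equal(eligible_patients(dead, 2018, pop), 0)
})

test_that("evaluation outside the patent window is rejected", {
  prof <- simple_profile()
  pop <- flat_population(1e6)
  expect_error(cumulative_price_by_year(prof, 2020, pop), "expired")
  expect_error(cumulative_price_by_year(prof, 2030, pop), "expired")
  expect_error(cumulative_price_by_indication(prof, 0, pop), "1..1")
  expect_error(cumulative_price_by_indication(prof, 2, pop), "1..1")
  expect_error(indication_based_price(prof, 1.5, pop), "integer")
})

test_that("fitted model methods expose the schedule coherently", {
  fit <- cbp(cbp_case_study("daratumumab"))
  expect_s3_class(fit, "cbp")
  expect_output(print(fit), "daratumumab")
  s <- summary(fit)
  expect_equal(round(s$launch_per_vial), 31941)
  expect_equal(unname(round(predict(fit, 2015))), 31941)
  expect_error(predict(fit, 1999), "grid")
  df <- as.data.frame(fit)
  expect_identical(names(df)[1:3], c("drug", "mode", "index"))
})
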