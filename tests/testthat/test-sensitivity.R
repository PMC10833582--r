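test_that("DSA at step 1 reproduces the base case bit for bit", {
  pop <- flat_population(1e6)
  prof <- simple_profile(extra_indications = list(
    indication("ind-2", 2017, 30, eligibility_cascade(), 12)))
  base <- cbp(prof, pop)$schedule
  for (input in c("np", "crd", "mp", "cman")) {
    tab <- dsa(prof, input, pop)
    at1 <- tab[tab$step == 1, ]
    expect_identical(at1$per_vial, base$per_vial, info = input)
    expect_identical(at1$per_treatment, base$per_treatment, info = input)
  }
})

test_that("DSA is monotone in the step for every year", {
  pop <- flat_population(1e6)
  prof <- simple_profile(extra_indications = list(
    indication("ind-2", 2017, 30, eligibility_cascade(), 12)))
  for (input in c("crd", "mp", "cman")) {
    tab <- dsa(prof, input, pop)
    for (ix in unique(tab$index)) {
      pv <- tab$per_vial[tab$index == ix][order(tab$step[tab$index == ix])]
      expect_true(all(diff(pv) >= 0), info = input)
    }
  }
  tab <- dsa(prof, "np", pop)
  for (ix in unique(tab$index)) {
    pv <- tab$per_vial[tab$index == ix][order(tab$step[tab$index == ix])]
    expect_true(all(diff(pv) <= 0))
  }
  expect_error(dsa(prof, "nonsense", pop))
  expect_error(dsa(prof, "np", pop, steps = c(0.5, -1)), "> 0")
})

test_that("profit-margin steps commute with price decomposition", {
  # scaling mp alone must equal recomposing the base pre-margin cost with
  # the new multiplier 1 + mp*s + msm
  prof <- cbp_case_study("daratumumab")
  pop <- un_mdr_population()
  base <- cbp(prof, pop)$schedule
  tab <- dsa(prof, "mp", pop)
  for (s in c(0.7, 1.2)) {
    got <- tab$per_vial[tab$step == s]
    mult_s <- 1 + prof$cost$mp * s + prof$cost$msm
    want <- vapply(seq_len(nrow(base)), function(i) {
      d <- decompose_price(base$per_vial[i], prof$vial_grams,
                           prof$cost$cman_per_gram_adjusted,
                           prof$cost$mp, prof$cost$msm)
      unname((d["rd_component"] + d["manuf_component"]) * mult_s)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("case-study DSA reproduces the published launch-year transforms", {
  prof <- cbp_case_study("daratumumab")
  tab_np <- dsa(prof, "np")
  expect_equal(tab_np$per_vial[tab_np$step == 0.7 & tab_np$index == 2015],
               45581, tolerance = 0.0025)
  tab_crd <- dsa(prof, "crd")
  expect_equal(tab_crd$per_vial[tab_crd$step == 1.3 & tab_crd$index == 2015],
               41489, tolerance = 0.0025)
  expect_equal(unname(dsa_range(dsa(prof, "mp"))),
               c(790, 33219), tolerance = 0.0025)

  pem <- cbp_case_study("pembrolizumab")
  expect_equal(unname(dsa_range(dsa(pem, "np"))["max"]), 1262,
               tolerance = 0.0025)
  expect_equal(unname(dsa_range(dsa(pem, "mp"))["min"]), 50,
               tolerance = 1 / 50)
})

test_that("the range helper scans all cells and rejects empty tables", {
  tab <- data.frame(index = 1:3, step = 1, per_vial = c(5, 2, 9))
  expect_equal(unname(dsa_range(tab)), c(2, 9))
  const <- data.frame(index = 1:3, step = 1, per_vial = rep(4, 3))
  r <- dsa_range(const)
  expect_equal(r[["min"]], r[["max"]])
  expect_error(dsa_range(tab[0, ]), "empty")
})

test_that("scenario definitions override exactly the advertised inputs", {
  prof <- cbp_case_study("daratumumab")
  pop <- un_mdr_population()
  base <- cbp(prof, pop)$schedule

  # margin-only scenarios rescale every year by multiplier algebra
  s7 <- run_scenario(prof, 7, pop)$schedule
  expect_equal(s7$per_vial / base$per_vial, rep(1.3 / 1.5, nrow(base)),
               tolerance = 1e-12)
  s8 <- run_scenario(prof, 8, pop)$schedule
  expect_equal(s8$per_vial / base$per_vial,
               rep(2.065 / 1.5, nrow(base)), tolerance = 1e-12)

  # uncapitalized R&D replaces the initial cost only
  sp3 <- scenario_spec(3, prof)
  expect_named(sp3$overrides, "crd")
  expect_lt(sp3$overrides$crd, prof$cost$crd_adjusted)
  sp3b <- scenario_spec(3, prof, uncapitalized_cex = TRUE)
  expect_true(all(c("crd", "cex") %in% names(sp3b$overrides)))

  # per-indication R&D from the 10%-of-initial rule
  sp4 <- scenario_spec(4, prof)
  expect_equal(sp4$overrides$cex, 379524928, tolerance = 1e-5)

  # manufacturing bounds
  expect_equal(scenario_spec(5, prof)$overrides$cman, 25.89,
               tolerance = 1e-4)
  expect_equal(scenario_spec(6, prof)$overrides$cman, 133.43,
               tolerance = 1e-4)

  # longer patent never raises the launch-year price
  s9 <- run_scenario(prof, 9, pop)$schedule
  expect_lte(s9$per_vial[1], base$per_vial[1])

  # indication-based mode switch
  s10 <- run_scenario(prof, 10, pop)
  expect_identical(s10$mode, "ibp")
  expect_equal(s10$schedule$per_vial[1], base$per_vial[1])

  expect_error(run_scenario(prof, 11, pop), "1..10")
  expect_error(run_scenario(prof, 0, pop), "1..10")
})

test_that("published scenario-8 prices are reproduced at launch", {
  dara <- run_scenario(cbp_case_study("daratumumab"), 8)
  expect_equal(dara$schedule$per_vial[1], 43972, tolerance = 0.0025)
  pem <- run_scenario(cbp_case_study("pembrolizumab"), 8)
  expect_equal(pem$schedule$per_vial[1], 1219, tolerance = 0.0025)
})

test_that("scenario engine resolves costs for profiles without a basis year", {
  # conversion falls back to the profile's own factor
  prof <- synthetic_profile(5, n_indications = 2)
  expect_null(prof$cost_basis_year)
  sp <- scenario_spec(1, prof)
  expect_equal(sp$overrides$crd, 3114000000 * prof$conversion_factor)
  # scenario 9 requires an alternative expiry on record
  prof$alt_patent_expiry <- NULL
  expect_error(scenario_spec(9, prof), "alt_patent_expiry")
})
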