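#' Packaged case-study drug profiles
#'
#' Reconstructed profiles for the two case-study monoclonal antibodies:
#' daratumumab (multiple myeloma; launch 2015, patent expiry 2025, 1.8 g
#' vial, no competitor) and pembrolizumab (multiple solid/haematological
#' tumours; launch 2014, patent expiry 2028, 0.1 g vial, competitor entry
#' per indication). Cost inputs, incidence rates, patent years, vial
#' contents and margins are the published figures; the per-indication
#' eligibility cascades and weighted doses are reconstructions (the original
#' clinical-opinion tables are not public) calibrated so that the
#' launch-year per-vial price and the minimum yearly price of each profile
#' match the published values against the packaged population table. The
#' calibrated constants are flagged in the YAML fixtures.
#'
#' @param name `"daratumumab"` or `"pembrolizumab"`.
#' @return `cbp_case_study()`: one validated [drug_profile()];
#'   `packaged_profiles()`: a named list with both.
#' @examples
#' prof <- cbp_case_study("pembrolizumab")
#' prof$launch_year
#' @export
cbp_case_study <- function(name = c("daratumumab", "pembrolizumab")) {
  name <- match.arg(name)
  read_profile(system.file("extdata", paste0(name, ".yaml"),
                           package = "cbpricer", mustWork = TRUE))
}

#' @rdname cbp_case_study
#' @export
packaged_profiles <- function() {
  list(daratumumab = cbp_case_study("daratumumab"),
       pembrolizumab = cbp_case_study("pembrolizumab"))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic drug profile
#'
#' Draws a random but internally consistent multi-indication drug profile:
#' staggered approval years, incidence rates in a plausible oncology range,
#' uniform eligibility-cascade fractions, an optional competitor entering a
#' couple of years after each indication, and weighted doses of at least one
#' vial. Generation is a pure function of `seed`: the global RNG state is
#' saved and restored, and the same seed always yields the same profile.
#'
#' @param seed Integer seed.
#' @param n_indications Number of indications (>= 1).
#' @param incidence_range Annual incidence per 100,000, `(low, high)`.
#' @param approval_spacing_years Range of gaps (years) between consecutive
#'   indication approvals.
#' @param patent_window_years Range of patent life lengths (years from
#'   launch to expiry).
#' @param dose_range_grams Range of weighted doses per treatment (grams).
#' @param competitor_prob Probability that an indication faces a competitor.
#' @return A validated [drug_profile()].
#' @examples
#' p1 <- synthetic_profile(42, n_indications = 3)
#' identical(p1, synthetic_profile(42, n_indications = 3))
#' @export
synthetic_profile <- function(seed,
                              n_indications = 3,
                              incidence_range = c(2.5, 142),
                              approval_spacing_years = c(1, 3),
                              patent_window_years = c(8, 14),
                              dose_range_grams = c(2, 50),
                              competitor_prob = 0.3) {
  stopifnot(n_indications >= 1)
  check_range <- function(r, nm, positive = TRUE) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        (positive && r[1] <= 0)) {
      stop("infeasible range for ", nm, ": ", deparse(r), call. = FALSE)
    }
  }
  check_range(incidence_range, "incidence_range")
  check_range(dose_range_grams, "dose_range_grams")
  check_range(patent_window_years, "patent_window_years")
  if (any(approval_spacing_years < 1)) {
    stop("approval_spacing_years must be >= 1 (approval years are strictly",
         " increasing)", call. = FALSE)
  }
  with_seed(seed, {
    launch <- sample(2014:2020, 1)
    window <- sample(patent_window_years[1]:patent_window_years[2], 1)
    spacing <- if (n_indications > 1) {
      sample(approval_spacing_years[1]:approval_spacing_years[2],
             n_indications - 1, replace = TRUE)
    } else integer(0)
    years <- launch + c(0L, cumsum(spacing))
    # keep every indication at least one year inside the patent window
    expiry <- launch + max(window, max(years) - launch + 1L)
    doses <- stats::runif(n_indications, dose_range_grams[1],
                          dose_range_grams[2])
    vial <- min(doses) * stats::runif(1, 0.05, 0.5)
    inds <- lapply(seq_len(n_indications), function(k) {
      comp <- NULL
      if (stats::runif(1) < competitor_prob) {
        comp <- data.frame(year = years[k] + sample(0:2, 1), count = 1L)
      }
      indication(
        label = sprintf("synthetic indication %d", k),
        approval_year = years[k],
        incidence_per_100k = stats::runif(1, incidence_range[1],
                                          incidence_range[2]),
        cascade = eligibility_cascade(
          subtype_share = stats::runif(1, 0.3, 1),
          stage_share = stats::runif(1, 0.2, 1),
          line_share = stats::runif(1, 0.1, 1),
          symptomatic_share = stats::runif(1, 0.8, 1),
          eligible_share = stats::runif(1, 0.3, 1),
          untreated_fraction = stats::runif(1, 0, 0.3),
          trial_fraction = 0.10
        ),
        grams_per_treatment = doses[k],
        competitors = comp
      )
    })
    drug_profile(
      name = sprintf("synthetic-%d", seed),
      launch_year = launch,
      patent_expiry = expiry,
      vial_grams = vial,
      cost = cost_structure(
        crd_adjusted = stats::runif(1, 5e8, 5e9),
        cex_adjusted = stats::runif(1, 5e7, 5e8),
        cman_per_gram_adjusted = stats::runif(1, 20, 150),
        mp = stats::runif(1, 0.05, 0.4),
        msm = 0.30
      ),
      indications = inds,
      region = "synthetic",
      alt_patent_expiry = expiry + 5L
    )
  })
}
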