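#' Cost structure of a drug
#'
#' All money values are in euros of the drug's launch year (see
#' [adjust_cost()] for converting source-currency figures).
#'
#' @param crd_adjusted Initial R&D cost (capitalized, risk-adjusted), EUR.
#' @param cex_adjusted Incremental R&D cost per new indication, EUR.
#' @param cman_per_gram_adjusted Manufacturing cost per gram of active
#'   ingredient, EUR/g.
#' @param mp Profit margin, a fraction in \[0, 1\].
#' @param msm Sales & marketing margin, a fraction in \[0, 1\].
#' @return An object of class `"cost_structure"`.
#' @export
cost_structure <- function(crd_adjusted, cex_adjusted,
                           cman_per_gram_adjusted, mp, msm) {
  x <- list(
    crd_adjusted = as.numeric(crd_adjusted),
    cex_adjusted = as.numeric(cex_adjusted),
    cman_per_gram_adjusted = as.numeric(cman_per_gram_adjusted),
    mp = as.numeric(mp),
    msm = as.numeric(msm)
  )
  class(x) <- "cost_structure"
  validate_cost_structure(x)
  x
}

validate_cost_structure <- function(x) {
  for (f in c("crd_adjusted", "cex_adjusted", "cman_per_gram_adjusted")) {
    if (length(x[[f]]) != 1L || !is.finite(x[[f]]) || x[[f]] < 0) {
      stop("cost field '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  for (f in c("mp", "msm")) {
    if (length(x[[f]]) != 1L || !is.finite(x[[f]]) || x[[f]] < 0 || x[[f]] > 1) {
      stop("margin '", f, "' must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  invisible(x)
}

#' One approved indication of a drug
#'
#' @param label Short human-readable name (disease, line of therapy).
#' @param approval_year Calendar year of regulatory approval.
#' @param incidence_per_100k Annual incidence of the disease per 100,000
#'   persons in the pricing region.
#' @param cascade An [eligibility_cascade()].
#' @param grams_per_treatment Weighted dose per treated patient over the full
#'   dosing schedule, in grams of active ingredient. Must be positive and at
#'   least one vial's worth when priced per vial.
#' @param competitors Competitor entry schedule: a data.frame with columns
#'   `year` and `count` (cumulative number of competitors on the market from
#'   that year on), or `NULL` for none. Market share is derived from the
#'   count via [market_share()].
#' @return An object of class `"indication_spec"`.
#' @export
indication <- function(label, approval_year, incidence_per_100k,
                       cascade = eligibility_cascade(),
                       grams_per_treatment,
                       competitors = NULL) {
  if (!is.null(competitors)) {
    competitors <- as.data.frame(competitors)
    if (!all(c("year", "count") %in% names(competitors))) {
      stop("competitors must have columns 'year' and 'count'", call. = FALSE)
    }
    competitors <- competitors[order(competitors$year), , drop = FALSE]
  }
  x <- list(
    label = as.character(label),
    approval_year = as.integer(approval_year),
    incidence_per_100k = as.numeric(incidence_per_100k),
    cascade = cascade,
    grams_per_treatment = as.numeric(grams_per_treatment),
    competitors = competitors
  )
  class(x) <- "indication_spec"
  validate_indication(x)
  x
}

validate_indication <- function(x) {
  errs <- character(0)
  if (!is.finite(x$incidence_per_100k) || x$incidence_per_100k <= 0) {
    errs <- c(errs, "incidence_per_100k must be > 0")
  }
  if (!is.finite(x$grams_per_treatment) || x$grams_per_treatment <= 0) {
    errs <- c(errs, "grams_per_treatment must be > 0")
  }
  if (!inherits(x$cascade, "eligibility_cascade")) {
    errs <- c(errs, "cascade must be an eligibility_cascade")
  } else {
    validate_cascade(x$cascade)
  }
  if (!is.null(x$competitors) && nrow(x$competitors) > 0 &&
      any(x$competitors$count < 0)) {
    errs <- c(errs, "competitor counts must be >= 0")
  }
  if (length(errs)) {
    stop("invalid indication '", x$label, "': ",
         paste(errs, collapse = "; "), call. = FALSE)
  }
  invisible(x)
}

#' Drug profile: everything needed to price one drug
#'
#' @param name Drug name.
#' @param launch_year Calendar year of first market access (= approval year of
#'   the first indication).
#' @param patent_expiry Calendar year in which patent protection ends; costs
#'   are recouped over the years `launch_year .. patent_expiry - 1`.
#' @param vial_grams Grams of active ingredient per vial.
#' @param cost A [cost_structure()].
#' @param indications List of [indication()] objects, sorted by approval year;
#'   the first one must be approved in `launch_year`.
#' @param region Label of the population region the incidence rates apply to.
#' @param conversion_factor Multiplicative factor that converts the profile's
#'   unadjusted source-currency cost inputs into launch-year euros; used by
#'   the scenario engine to adjust alternative literature cost inputs.
#' @param cost_basis_year Optional euro base year of the cost inputs
#'   (normally the launch year). When set, the scenario engine resolves
#'   source-specific conversion factors from the packaged factor table for
#'   this year; otherwise `conversion_factor` is used for every source.
#' @param alt_patent_expiry Optional alternative (less conservative) patent
#'   expiry year used by the extended-patent scenario.
#' @return An object of class `"drug_profile"`.
#' @seealso [read_profile()] for loading profiles from YAML,
#'   [synthetic_profile()] for seeded random profiles.
#' @export
drug_profile <- function(name, launch_year, patent_expiry, vial_grams,
                         cost, indications, region = "UN-MDR",
                         conversion_factor = 1,
                         cost_basis_year = NULL,
                         alt_patent_expiry = NULL) {
  x <- list(
    name = as.character(name),
    launch_year = as.integer(launch_year),
    patent_expiry = as.integer(patent_expiry),
    vial_grams = as.numeric(vial_grams),
    cost = cost,
    indications = indications,
    region = as.character(region),
    conversion_factor = as.numeric(conversion_factor),
    cost_basis_year = if (is.null(cost_basis_year)) NULL
                      else as.integer(cost_basis_year),
    alt_patent_expiry = if (is.null(alt_patent_expiry)) NULL
                        else as.integer(alt_patent_expiry)
  )
  class(x) <- "drug_profile"
  validate_profile(x)
  x
}

validate_profile <- function(x) {
  errs <- character(0)
  if (x$patent_expiry <= x$launch_year) {
    errs <- c(errs, sprintf("patent_expiry (%d) must be after launch_year (%d)",
                            x$patent_expiry, x$launch_year))
  }
  if (!is.finite(x$vial_grams) || x$vial_grams <= 0) {
    errs <- c(errs, "vial_grams must be > 0")
  }
  if (!is.finite(x$conversion_factor) || x$conversion_factor <= 0) {
    errs <- c(errs, "conversion_factor must be > 0")
  }
  if (!inherits(x$cost, "cost_structure")) {
    errs <- c(errs, "cost must be a cost_structure")
  } else {
    validate_cost_structure(x$cost)
  }
  if (length(x$indications) == 0L) {
    errs <- c(errs, "at least one indication is required")
  } else {
    for (ind in x$indications) {
      if (!inherits(ind, "indication_spec")) {
        errs <- c(errs, "all indications must be indication_spec objects")
        break
      }
      validate_indication(ind)
    }
    yrs <- vapply(x$indications, `[[`, integer(1), "approval_year")
    if (is.unsorted(yrs)) {
      bad <- which(diff(yrs) < 0)[1]
      errs <- c(errs, sprintf(
        "indications must be sorted by approval year (found %d before %d)",
        yrs[bad], yrs[bad + 1]))
    }
    if (yrs[1] != x$launch_year) {
      errs <- c(errs, sprintf(
        "first indication approval year (%d) must equal launch_year (%d)",
        yrs[1], x$launch_year))
    }
  }
  if (length(errs)) {
    stop("invalid drug profile '", x$name, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  invisible(x)
}

approval_years <- function(profile) {
  vapply(profile$indications, `[[`, integer(1), "approval_year")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("<drug_profile> %s (%s)\n", x$name, x$region))
  cat(sprintf("  launch %d, patent expiry %d, vial %.3g g\n",
              x$launch_year, x$patent_expiry, x$vial_grams))
  cat(sprintf("  C_rd %.4g EUR, C_ex %.4g EUR, C_man %.4g EUR/g, Mp %.3g, Msm %.3g\n",
              x$cost$crd_adjusted, x$cost$cex_adjusted,
              x$cost$cman_per_gram_adjusted, x$cost$mp, x$cost$msm))
  cat(sprintf("  %d indication(s):\n", length(x$indications)))
  for (ind in x$indications) {
    cat(sprintf("    [%d] %s (incidence %.4g/100k, dose %.4g g)\n",
                ind$approval_year, ind$label, ind$incidence_per_100k,
                ind$grams_per_treatment))
  }
  invisible(x)
}

PROFILE_SCHEMA_VERSION <- 1L

#' Read a drug profile from a YAML document
#'
#' The document must declare `schema_version: 1` and carry the fields of
#' [drug_profile()]; all invariants are validated and violations reported
#' together with their field paths.
#'
#' @param path Path to a YAML profile file.
#' @return A validated [drug_profile()].
#' @examples
#' prof <- read_profile(system.file("extdata", "daratumumab.yaml",
#'                                  package = "cbpricer"))
#' prof$patent_expiry
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  # large euro amounts overflow R's 32-bit integers; read all ints as doubles
  doc <- yaml::read_yaml(path, handlers = list(int = as.numeric))
  sv <- doc$schema_version
  if (is.null(sv) || sv != PROFILE_SCHEMA_VERSION) {
    stop("unsupported profile schema_version: ", deparse(sv),
         " (expected ", PROFILE_SCHEMA_VERSION, ")", call. = FALSE)
  }
  need <- c("name", "launch_year", "patent_expiry", "vial_grams", "cost",
            "indications")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop("profile ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cost_need <- c("crd_adjusted", "cex_adjusted", "cman_per_gram_adjusted",
                 "mp", "msm")
  cmiss <- setdiff(cost_need, names(doc$cost))
  if (length(cmiss)) {
    stop("profile ", path, " cost block is missing: ",
         paste(cmiss, collapse = ", "), call. = FALSE)
  }
  cost <- do.call(cost_structure, doc$cost[cost_need])
  inds <- lapply(seq_along(doc$indications), function(i) {
    d <- doc$indications[[i]]
    ineed <- c("label", "approval_year", "incidence_per_100k",
               "grams_per_treatment", "cascade")
    imiss <- setdiff(ineed, names(d))
    if (length(imiss)) {
      stop("profile ", path, " indications[", i, "] is missing: ",
           paste(imiss, collapse = ", "), call. = FALSE)
    }
    comp <- NULL
    if (!is.null(d$competitors) && length(d$competitors)) {
      comp <- do.call(rbind, lapply(d$competitors, function(ci) {
        data.frame(year = as.integer(ci$year), count = as.integer(ci$count))
      }))
    }
    indication(
      label = d$label,
      approval_year = d$approval_year,
      incidence_per_100k = d$incidence_per_100k,
      cascade = do.call(eligibility_cascade, d$cascade),
      grams_per_treatment = d$grams_per_treatment,
      competitors = comp
    )
  })
  drug_profile(
    name = doc$name,
    launch_year = doc$launch_year,
    patent_expiry = doc$patent_expiry,
    vial_grams = doc$vial_grams,
    cost = cost,
    indications = inds,
    region = if (is.null(doc$region)) "UN-MDR" else doc$region,
    conversion_factor = if (is.null(doc$conversion_factor)) 1
                        else doc$conversion_factor,
    cost_basis_year = doc$cost_basis_year,
    alt_patent_expiry = doc$alt_patent_expiry
  )
}
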