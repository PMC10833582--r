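# Return a copy of the profile with selected cost / patent fields replaced.
profile_with <- function(profile, crd = NULL, cex = NULL, cman = NULL,
                         mp = NULL, msm = NULL, patent_expiry = NULL) {
  cost <- profile$cost
  if (!is.null(crd)) cost$crd_adjusted <- crd
  if (!is.null(cex)) cost$cex_adjusted <- cex
  if (!is.null(cman)) cost$cman_per_gram_adjusted <- cman
  if (!is.null(mp)) cost$mp <- mp
  if (!is.null(msm)) cost$msm <- msm
  validate_cost_structure(cost)
  profile$cost <- cost
  if (!is.null(patent_expiry)) profile$patent_expiry <- as.integer(patent_expiry)
  validate_profile(profile)
  profile
}

DSA_INPUTS <- c("np", "crd", "mp", "cman")
DSA_DEFAULT_STEPS <- seq(0.7, 1.3, by = 0.1)

#' Stepwise deterministic one-way sensitivity analysis
#'
#' Recomputes the full per-vial price schedule while one input is varied
#' multiplicatively over a grid of steps (default −30% to +30% in 10%
#' increments), all other inputs held at base case:
#' \describe{
#'   \item{`np`}{every year's eligible patients are scaled by the step;}
#'   \item{`crd`}{the initial R&D cost is scaled;}
#'   \item{`mp`}{the profit-margin value itself is scaled (0.2 becomes 0.26
#'     at +30%), not the whole margin multiplier;}
#'   \item{`cman`}{the per-gram manufacturing cost is scaled.}
#' }
#' At step 1 the schedule is, by construction, identical to the base case.
#'
#' @param profile A [drug_profile()].
#' @param input One of `"np"`, `"crd"`, `"mp"`, `"cman"`.
#' @param population A [population_table()].
#' @param steps Positive multipliers; default `seq(0.7, 1.3, 0.1)`.
#' @param mode Evaluation grid, as in [cbp()].
#' @return A long-format data.frame of class `"cbp_dsa"` with columns
#'   `index`, `step`, `per_treatment`, `per_vial` plus attributes `input`
#'   and `drug`.
#' @examples
#' prof <- cbp_case_study("daratumumab")
#' d <- dsa(prof, "np")
#' dsa_range(d)
#' @export
dsa <- function(profile, input = c("np", "crd", "mp", "cman"),
                population = un_mdr_population(),
                steps = DSA_DEFAULT_STEPS,
                mode = c("year", "indication")) {
  input <- match.arg(input)
  mode <- match.arg(mode)
  if (any(steps <= 0)) stop("all DSA steps must be > 0", call. = FALSE)
  base_cost <- profile$cost
  out <- do.call(rbind, lapply(steps, function(s) {
    fit <- switch(
      input,
      np = cbp(profile, population, mode = mode, np_scale = s),
      crd = cbp(profile_with(profile, crd = base_cost$crd_adjusted * s),
                population, mode = mode),
      mp = cbp(profile_with(profile, mp = base_cost$mp * s),
               population, mode = mode),
      cman = cbp(profile_with(profile,
                              cman = base_cost$cman_per_gram_adjusted * s),
                 population, mode = mode)
    )
    data.frame(index = fit$schedule$index, step = s,
               per_treatment = fit$schedule$per_treatment,
               per_vial = fit$schedule$per_vial)
  }))
  rownames(out) <- NULL
  structure(out, input = input, drug = profile$name, mode = mode,
            class = c("cbp_dsa", "data.frame"))
}

#' Range of per-vial prices over a sensitivity table
#'
#' @param table A `"cbp_dsa"` table (or any data.frame with a `per_vial`
#'   column).
#' @return Named numeric vector `c(min, max)` over all (index, step) cells.
#' @export
dsa_range <- function(table) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("empty sensitivity table", call. = FALSE)
  }
  r <- range(table$per_vial)
  c(min = r[1], max = r[2])
}

#' @export
print.cbp_dsa <- function(x, ...) {
  cat(sprintf("Stepwise DSA of '%s' for %s (%s grid): %d cells\n",
              attr(x, "input"), attr(x, "drug"), attr(x, "mode"), nrow(x)))
  r <- dsa_range(x)
  cat(sprintf("  per-vial range: %s – %s EUR\n",
              format(round(r[1]), big.mark = ","),
              format(round(r[2]), big.mark = ",")))
  NextMethod()
}

#' @export
plot.cbp_dsa <- function(x, ...) {
  steps <- sort(unique(x$step))
  idx <- sort(unique(x$index))
  cols <- grDevices::hcl.colors(length(steps), "Zissou 1")
  graphics::matplot(idx,
                    sapply(steps, function(s) x$per_vial[x$step == s]),
                    type = "l", lty = 1, col = cols,
                    xlab = if (attr(x, "mode") == "year") "calendar year"
                           else "indication",
                    ylab = "EUR per vial",
                    main = sprintf("%s: one-way DSA of %s", attr(x, "drug"),
                                   attr(x, "input")), ...)
  graphics::legend("topright", legend = sprintf("%+d%%",
                   round((steps - 1) * 100)), col = cols, lty = 1, cex = 0.7)
  invisible(x)
}

# Alternative literature cost inputs used by the scenario engine
# (unadjusted, in each source's own currency/base year).
scenario_inputs <- function() {
  utils::read.csv(system.file("extdata", "scenario_inputs.csv",
                              package = "cbpricer", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

resolve_scenario_amount <- function(profile, scenario_id) {
  tab <- scenario_inputs()
  row <- tab[tab$scenario == scenario_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no cost input on record for scenario ", scenario_id, call. = FALSE)
  }
  fac <- if (!is.null(profile$cost_basis_year)) {
    get_conversion_factor(row$source_label, profile$cost_basis_year)$factor
  } else {
    profile$conversion_factor
  }
  adjust_cost(row$unadjusted, fac)
}

#' Scenario specification
#'
#' Resolves one of the ten predefined scenarios against a drug profile:
#' \enumerate{
#'   \item initial R&D at the lower confidence bound;
#'   \item initial R&D at the upper confidence bound;
#'   \item uncapitalized initial R&D (no cost of capital / failure gross-up);
#'   \item per-indication R&D at 10% of unadjusted initial R&D (mutual-fund
#'     association rule);
#'   \item manufacturing cost per gram, low literature estimate;
#'   \item manufacturing cost per gram, high literature estimate;
#'   \item profit margin 0%;
#'   \item profit margin 76.5% (highest published estimate);
#'   \item extended patent protection (profile's `alt_patent_expiry`);
#'   \item indication-based pricing instead of cumulative pricing.
#' }
#' Monetary scenario inputs are stored unadjusted (source currency) and are
#' converted with the conversion factor matching the profile's cost basis
#' year, so the same scenario definitions apply to any profile.
#'
#' @param id Scenario id, 1–10.
#' @param profile The [drug_profile()] the scenario will be applied to.
#' @param uncapitalized_cex Scenario 3 only: also scale the per-indication
#'   R&D cost by the uncapitalized/capitalized ratio (default `FALSE`:
#'   only the initial R&D cost is replaced).
#' @param zero_msm Scenario 7 only: also zero the sales & marketing margin
#'   (default `FALSE`: only the profit margin is zeroed).
#' @return A list with entries `id`, `label`, `overrides` (named list of
#'   profile/cost replacements) and `mode`.
#' @export
scenario_spec <- function(id, profile, uncapitalized_cex = FALSE,
                          zero_msm = FALSE) {
  if (length(id) != 1L || !id %in% 1:10) {
    stop("scenario id must be one of 1..10, got ", deparse(id), call. = FALSE)
  }
  ov <- list()
  mode <- "year"
  label <- switch(
    id,
    "initial R&D, lower CI bound",
    "initial R&D, upper CI bound",
    "initial R&D uncapitalized",
    "per-indication R&D at 10% of initial R&D",
    "manufacturing cost, low estimate",
    "manufacturing cost, high estimate",
    "profit margin 0%",
    "profit margin 76.5%",
    "extended patent protection",
    "indication-based pricing"
  )
  if (id %in% 1:3) {
    ov$crd <- resolve_scenario_amount(profile, id)
    if (id == 3 && uncapitalized_cex) {
      ov$cex <- profile$cost$cex_adjusted *
        ov$crd / profile$cost$crd_adjusted
    }
  } else if (id == 4) {
    ov$cex <- resolve_scenario_amount(profile, id)
  } else if (id %in% 5:6) {
    ov$cman <- resolve_scenario_amount(profile, id)
  } else if (id == 7) {
    ov$mp <- 0
    if (zero_msm) ov$msm <- 0
  } else if (id == 8) {
    ov$mp <- 0.765
  } else if (id == 9) {
    if (is.null(profile$alt_patent_expiry)) {
      stop("scenario 9 needs the profile to define alt_patent_expiry",
           call. = FALSE)
    }
    ov$patent_expiry <- profile$alt_patent_expiry
  } else if (id == 10) {
    mode <- "ibp"
  }
  list(id = id, label = label, overrides = ov, mode = mode)
}

#' Run a pricing scenario
#'
#' Applies a [scenario_spec()] to a profile and re-fits the pricing model;
#' scenario 10 switches to the indication-based mode, all others price per
#' cumulative year.
#'
#' @param profile A [drug_profile()].
#' @param id Scenario id 1–10, or an already-resolved [scenario_spec()].
#' @param population A [population_table()].
#' @param ... Passed to [scenario_spec()] (`uncapitalized_cex`, `zero_msm`).
#' @return A `"cbp"` fit with attribute `scenario` (the resolved spec).
#' @examples
#' prof <- cbp_case_study("daratumumab")
#' fit <- run_scenario(prof, 8)
#' round(fit$schedule$per_vial[1])
#' @export
run_scenario <- function(profile, id, population = un_mdr_population(),
                         ...) {
  spec <- if (is.list(id) && !is.null(id$overrides)) id
          else scenario_spec(id, profile, ...)
  ov <- spec$overrides
  mod <- profile_with(profile,
                      crd = ov$crd, cex = ov$cex, cman = ov$cman,
                      mp = ov$mp, msm = ov$msm,
                      patent_expiry = ov$patent_expiry)
  fit <- cbp(mod, population, mode = spec$mode)
  attr(fit, "scenario") <- spec
  fit
}
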