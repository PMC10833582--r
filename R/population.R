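#' Region population table
#'
#' Total population of the pricing region by calendar year. Years missing
#' from the table are linearly interpolated; extrapolation beyond the table
#' is off by default and, when enabled, continues the linear trend of the
#' last five tabulated years.
#'
#' @param years Integer vector of calendar years.
#' @param persons Numeric vector of population counts (> 0), same length.
#' @param region Region label.
#' @param allow_extrapolation Allow projection beyond the tabulated years.
#' @return An object of class `"population_table"`.
#' @seealso [read_population()], [un_mdr_population()]
#' @export
population_table <- function(years, persons, region = "region",
                             allow_extrapolation = FALSE) {
  years <- as.integer(years)
  persons <- as.numeric(persons)
  if (length(years) != length(persons) || length(years) < 2L) {
    stop("years and persons must have equal length >= 2", call. = FALSE)
  }
  if (anyDuplicated(years)) stop("duplicated years in population table",
                                 call. = FALSE)
  o <- order(years)
  years <- years[o]; persons <- persons[o]
  if (any(!is.finite(persons) | persons <= 0)) {
    stop("population counts must be positive and finite", call. = FALSE)
  }
  structure(
    list(region = as.character(region), years = years, persons = persons,
         allow_extrapolation = isTRUE(allow_extrapolation)),
    class = "population_table"
  )
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table> %s: %d–%d (%d rows), %.4g–%.4g persons\n",
              x$region, min(x$years), max(x$years), length(x$years),
              min(x$persons), max(x$persons)))
  invisible(x)
}

#' Population of a region in given years
#'
#' @param pop A [population_table()].
#' @param years Calendar years (interpolated if missing from the table).
#' @return Numeric vector of persons.
#' @export
population_at <- function(pop, years) {
  stopifnot(inherits(pop, "population_table"))
  years <- as.numeric(years)
  lo <- min(pop$years); hi <- max(pop$years)
  out_of_range <- years < lo | years > hi
  if (any(out_of_range) && !pop$allow_extrapolation) {
    stop("year(s) ", paste(years[out_of_range], collapse = ", "),
         " outside population table range [", lo, ", ", hi,
         "] and extrapolation is disabled", call. = FALSE)
  }
  res <- stats::approx(pop$years, pop$persons, xout = pmin(pmax(years, lo), hi),
                       rule = 2)$y
  if (any(out_of_range)) {
    # linear trend of the last (or first) five tabulated years
    n <- length(pop$years)
    idx_hi <- seq(max(1L, n - 4L), n)
    fit_hi <- stats::lm.fit(cbind(1, pop$years[idx_hi]), pop$persons[idx_hi])
    idx_lo <- seq_len(min(5L, n))
    fit_lo <- stats::lm.fit(cbind(1, pop$years[idx_lo]), pop$persons[idx_lo])
    above <- out_of_range & years > hi
    below <- out_of_range & years < lo
    res[above] <- fit_hi$coefficients[1] + fit_hi$coefficients[2] * years[above]
    res[below] <- fit_lo$coefficients[1] + fit_lo$coefficients[2] * years[below]
    if (any(res[out_of_range] <= 0)) {
      stop("extrapolated population is non-positive", call. = FALSE)
    }
  }
  res
}

#' Read a population table from CSV
#'
#' Expected columns: `region`, `year`, `persons`.
#'
#' @param path CSV path.
#' @param allow_extrapolation See [population_table()].
#' @return A [population_table()].
#' @export
read_population <- function(path, allow_extrapolation = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "persons")
  if (!all(need %in% names(df))) {
    stop("population CSV must have columns region, year, persons",
         call. = FALSE)
  }
  region <- unique(df$region)
  if (length(region) != 1L) {
    stop("population CSV must contain exactly one region, found: ",
         paste(region, collapse = ", "), call. = FALSE)
  }
  population_table(df$year, df$persons, region = region,
                   allow_extrapolation = allow_extrapolation)
}

#' Packaged UN "more developed regions" population table
#'
#' An aggregate population series (Europe, North America,
#' Australia/New Zealand, Japan) for 2014–2036. The series is an
#' approximate reconstruction of the published world-population-prospects
#' aggregate, shipped so that all computations run offline; the absolute
#' level (about 1.27 billion, near-flat over the period) is what matters for
#' the packaged case-study profiles, whose eligibility cascades are
#' calibrated against this very table.
#'
#' @param allow_extrapolation See [population_table()].
#' @return A [population_table()].
#' @export
un_mdr_population <- function(allow_extrapolation = FALSE) {
  read_population(system.file("extdata", "population_unmdr.csv",
                              package = "cbpricer", mustWork = TRUE),
                  allow_extrapolation = allow_extrapolation)
}

#' Market share as a function of competitor count
#'
#' With no competitor the drug captures the whole eligible population; one
#' competitor halves the share; two or more competitors reduce it to 33%
#' (the conventional printed value, not 1/3).
#'
#' @param competitors_approved Non-negative integer count(s) of competitors
#'   on the market.
#' @param shares Shares for 0, 1, and >= 2 competitors.
#' @return Numeric vector of market-share fractions.
#' @examples
#' market_share(0:3)
#' @export
market_share <- function(competitors_approved, shares = c(1, 0.5, 0.33)) {
  if (any(competitors_approved < 0)) {
    stop("competitors_approved must be >= 0", call. = FALSE)
  }
  stopifnot(length(shares) == 3L)
  idx <- pmin(as.integer(competitors_approved), 2L) + 1L
  shares[idx]
}

competitor_count_at <- function(ind, year) {
  comp <- ind$competitors
  if (is.null(comp) || nrow(comp) == 0L) return(0L)
  active <- comp$year <= year
  if (!any(active)) return(0L)
  as.integer(max(comp$count[active]))
}

#' Eligible patients for one indication in one year
#'
#' Projects the number of patients an indication contributes in a calendar
#' year: incident cases (incidence rate times region population) reduced by
#' the multiplicative eligibility cascade and the competitor-dependent
#' market share of that year. The result is a real number; amortization over
#' patients does not require integer census counts.
#'
#' @param ind An [indication()].
#' @param year Calendar year.
#' @param pop A [population_table()].
#' @param shares Market-share levels passed to [market_share()].
#' @return Eligible (treated, drug-buying) patient count, real-valued.
#' @export
eligible_patients <- function(ind, year, pop, shares = c(1, 0.5, 0.33)) {
  stopifnot(inherits(ind, "indication_spec"))
  persons <- population_at(pop, year)
  ms <- market_share(vapply(year, function(y) competitor_count_at(ind, y),
                            integer(1)), shares = shares)
  persons * ind$incidence_per_100k / 1e5 * cascade_factor(ind$cascade) * ms
}

#' Cumulative eligible patients over the remaining patent period
#'
#' Sums, over every indication approved by `eval_year`, the projected
#' eligible patients for each calendar year from that indication's approval
#' through `patent_expiry - 1`. This is the denominator of the cumulative
#' pricing algorithm: each indication is amortized over its own remaining
#' patent window.
#'
#' @param profile A [drug_profile()].
#' @param eval_year Evaluation year, `launch_year <= eval_year < patent_expiry`.
#' @param pop A [population_table()].
#' @return Total patient count (real-valued).
#' @export
cumulative_np <- function(profile, eval_year, pop) {
  agg <- patient_pool(profile, eval_year, pop)
  sum(agg$np)
}

# Per-indication patient totals and doses for all indications approved by
# eval_year; each indication contributes approval_year .. expiry-1.
patient_pool <- function(profile, eval_year, pop,
                         expiry = profile$patent_expiry) {
  stopifnot(inherits(profile, "drug_profile"))
  if (eval_year >= expiry) {
    stop("patent expired: evaluation year ", eval_year,
         " is not before patent expiry ", expiry, call. = FALSE)
  }
  if (eval_year < profile$launch_year) {
    stop("evaluation year ", eval_year, " precedes launch year ",
         profile$launch_year, call. = FALSE)
  }
  active <- Filter(function(ind) ind$approval_year <= eval_year,
                   profile$indications)
  np <- vapply(active, function(ind) {
    yrs <- seq.int(ind$approval_year, expiry - 1L)
    sum(eligible_patients(ind, yrs, pop))
  }, numeric(1))
  dose <- vapply(active, `[[`, numeric(1), "grams_per_treatment")
  list(np = np, dose = dose, labels = vapply(active, `[[`, character(1), "label"))
}
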