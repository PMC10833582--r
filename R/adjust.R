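#' Multiplicative cost conversion factor
#'
#' Converts a cost figure from its source currency and price year into euros
#' of a target (launch) year in one multiplication. Factors are specific to
#' a cost source because each source reports in its own base year; within a
#' source the same factor applies at every magnitude (the adjustment is
#' linear). The packaged factor table was derived from published
#' unadjusted/adjusted input pairs; see [cost_conversion_factors()].
#'
#' @param source_label Cost source the factor belongs to (e.g. the
#'   publication the figure was taken from).
#' @param source_currency ISO currency code of the unadjusted figure.
#' @param target_year Calendar year of the resulting euro value.
#' @param factor Positive multiplicative factor.
#' @return An object of class `"conversion_factor"`.
#' @export
conversion_factor <- function(source_label, source_currency, target_year,
                              factor) {
  factor <- as.numeric(factor)
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  structure(list(source_label = as.character(source_label),
                 source_currency = as.character(source_currency),
                 target_year = as.integer(target_year),
                 factor = factor),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> %s: %s -> EUR(%d), x %.7f\n",
              x$source_label, x$source_currency, x$target_year, x$factor))
  invisible(x)
}

#' Convert a cost input into launch-year euros
#'
#' @param amount Non-negative amount in the factor's source currency.
#' @param f A [conversion_factor()] or a bare positive number.
#' @return Amount in euros of the factor's target year.
#' @examples
#' f <- conversion_factor("example", "USD", 2015, 0.8507237)
#' adjust_cost(1e6, f)
#' @export
adjust_cost <- function(amount, f) {
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  fac <- if (inherits(f, "conversion_factor")) f$factor else as.numeric(f)
  if (length(fac) != 1L || !is.finite(fac) || fac <= 0) {
    stop("conversion factor must be a single positive number", call. = FALSE)
  }
  amount * fac
}

#' Derive the implied conversion factor from an input pair
#'
#' @param unadjusted Source-currency amount (> 0).
#' @param adjusted Corresponding euro amount.
#' @return The implied multiplicative factor `adjusted / unadjusted`.
#' @export
derive_factor <- function(unadjusted, adjusted) {
  if (any(unadjusted <= 0)) stop("unadjusted amount must be > 0",
                                 call. = FALSE)
  adjusted / unadjusted
}

#' Consistency check of a transcribed cost-input table
#'
#' For a set of rows from one cost source, each giving the unadjusted amount
#' and its euro adjustments to two target years, verifies that (a) the
#' implied factor of every row agrees with the source's reference factor
#' (the factor implied by the first row, or an explicit `reference_factor`)
#' to within `tol` relative, and (b) the ratio `adjusted_y2 / adjusted_y1`
#' — the relative purchasing-power/inflation path between the two target
#' years, which is a property of the years and not of the source — matches
#' `year_ratio` within `year_ratio_tol`.
#'
#' @param rows data.frame with columns `unadjusted`, `adjusted_y1`,
#'   `adjusted_y2` (and optionally `label`).
#' @param reference_factor Reference factor for target year 1; default: the
#'   first row's implied factor.
#' @param tol Relative tolerance for within-source factor agreement.
#' @param year_ratio Expected cross-year ratio `adjusted_y2 / adjusted_y1`.
#' @param year_ratio_tol Absolute tolerance on the cross-year ratio.
#' @return A data.frame report, one row per input row, with implied factors,
#'   year ratios and logical flags `factor_ok`, `ratio_ok`; overall
#'   consistency in `attr(, "consistent")`.
#' @export
check_factor_consistency <- function(rows, reference_factor = NULL,
                                     tol = 1e-4,
                                     year_ratio = 0.8342,
                                     year_ratio_tol = 0.001) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("empty input: no rows to check", call. = FALSE)
  need <- c("unadjusted", "adjusted_y1", "adjusted_y2")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  implied <- derive_factor(rows$unadjusted, rows$adjusted_y1)
  if (is.null(reference_factor)) reference_factor <- implied[1]
  ratio <- rows$adjusted_y2 / rows$adjusted_y1
  report <- data.frame(
    label = if ("label" %in% names(rows)) rows$label
            else paste0("row", seq_len(nrow(rows))),
    implied_factor = implied,
    factor_ok = abs(implied / reference_factor - 1) <= tol,
    year_ratio = ratio,
    ratio_ok = abs(ratio - year_ratio) <= year_ratio_tol,
    stringsAsFactors = FALSE
  )
  attr(report, "consistent") <- all(report$factor_ok & report$ratio_ok)
  report
}

#' Packaged cost conversion factors
#'
#' Factor table shipped with the package: one factor per cost source and
#' target year, derived from published unadjusted/adjusted cost-input pairs
#' (each source has its own base year, hence its own factors; the
#' 2014-vs-2015 ratio is common to all sources).
#'
#' @return data.frame with columns `source_label`, `source_currency`,
#'   `target_year`, `factor`, `provenance`.
#' @export
cost_conversion_factors <- function() {
  utils::read.csv(system.file("extdata", "conversion_factors.csv",
                              package = "cbpricer", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Packaged cost-input table
#'
#' The transcribed base-case and scenario cost inputs: unadjusted amounts in
#' each source's own currency/base year, with their euro adjustments to the
#' two case-study launch years (2015 in `adjusted_y1`, 2014 in
#' `adjusted_y2`). Used to pin conversion factors and to validate
#' transcription via [check_factor_consistency()].
#'
#' @return data.frame with columns `source_label`, `label`, `unadjusted`,
#'   `adjusted_y1`, `adjusted_y2`.
#' @export
cost_input_table <- function() {
  utils::read.csv(system.file("extdata", "cost_inputs.csv",
                              package = "cbpricer", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Look up a packaged conversion factor
#'
#' @param source_label Source to look up.
#' @param target_year Target euro year.
#' @return A [conversion_factor()].
#' @export
get_conversion_factor <- function(source_label, target_year) {
  tab <- cost_conversion_factors()
  hit <- tab[tab$source_label == source_label &
               tab$target_year == target_year, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("no unique factor for source '", source_label, "' and year ",
         target_year, call. = FALSE)
  }
  conversion_factor(hit$source_label, hit$source_currency, hit$target_year,
                    hit$factor)
}
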