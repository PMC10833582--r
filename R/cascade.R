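#' Eligibility cascade
#'
#' Multiplicative adjustments that convert incident cases of a disease into
#' patients eligible for (and actually receiving) the drug in a given
#' indication. Every field is a fraction in \[0, 1\]; fields that do not
#' apply to an indication are left at 1 (or 0 for the two "loss" fractions).
#'
#' The cascade is applied as
#' `subtype * stage * line * symptomatic * eligible * (1 - untreated) * (1 - trial)`,
#' and is therefore commutative: the order of the factors never matters.
#'
#' @param subtype_share Fraction of incident cases with the relevant disease
#'   subtype (e.g. a histology or molecular marker).
#' @param stage_share Fraction at the disease stage covered by the label.
#' @param line_share Fraction reaching the treatment line covered by the label.
#' @param symptomatic_share Fraction with symptomatic disease requiring
#'   treatment; 1 when the criterion does not apply.
#' @param eligible_share Residual clinical-eligibility fraction (fitness,
#'   contraindications, access).
#' @param untreated_fraction Fraction of otherwise eligible patients that
#'   receive no systemic treatment.
#' @param trial_fraction Fraction enrolled in clinical trials (and therefore
#'   not buying the drug).
#' @return An object of class `"eligibility_cascade"` (a named list).
#' @examples
#' eligibility_cascade(line_share = 0.1, untreated_fraction = 0.25,
#'                     trial_fraction = 0.10)
#' @export
eligibility_cascade <- function(subtype_share = 1,
                                stage_share = 1,
                                line_share = 1,
                                symptomatic_share = 1,
                                eligible_share = 1,
                                untreated_fraction = 0,
                                trial_fraction = 0) {
  x <- list(
    subtype_share = as.numeric(subtype_share),
    stage_share = as.numeric(stage_share),
    line_share = as.numeric(line_share),
    symptomatic_share = as.numeric(symptomatic_share),
    eligible_share = as.numeric(eligible_share),
    untreated_fraction = as.numeric(untreated_fraction),
    trial_fraction = as.numeric(trial_fraction)
  )
  class(x) <- "eligibility_cascade"
  validate_cascade(x)
  x
}

validate_cascade <- function(x) {
  for (f in names(x)) {
    v <- x[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("cascade field '", f, "' must be a single fraction in [0, 1], got ",
           deparse(v), call. = FALSE)
    }
  }
  invisible(x)
}

#' Net multiplicative factor of an eligibility cascade
#'
#' @param x An [eligibility_cascade()].
#' @return A single number in \[0, 1\]: the product of all retention factors.
#' @export
cascade_factor <- function(x) {
  stopifnot(inherits(x, "eligibility_cascade"))
  x$subtype_share * x$stage_share * x$line_share * x$symptomatic_share *
    x$eligible_share * (1 - x$untreated_fraction) * (1 - x$trial_fraction)
}

#' @export
print.eligibility_cascade <- function(x, ...) {
  cat("Eligibility cascade (net factor ",
      format(cascade_factor(x), digits = 4), ")\n", sep = "")
  for (f in names(x)) cat(sprintf("  %-20s %g\n", f, x[[f]]))
  invisible(x)
}
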