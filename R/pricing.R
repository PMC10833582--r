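#' Cost-based price per treatment (original single-indication model)
#'
#' The original cost-based price: initial R&D amortized over the eligible
#' patient population of the remaining patent period, plus manufacturing
#' cost per treatment, marked up by the profit margin:
#' `(crd / np + cman_per_treatment) * (1 + mp)`.
#'
#' @param crd Initial R&D cost, EUR.
#' @param np Eligible patients over the remaining patent period (> 0).
#' @param cman_per_treatment Manufacturing cost per treatment, EUR.
#' @param mp Profit margin (fraction).
#' @return Price per treatment, EUR.
#' @examples
#' price_per_treatment(crd = 100, np = 4, cman_per_treatment = 0, mp = 0)
#' @export
price_per_treatment <- function(crd, np, cman_per_treatment, mp) {
  if (any(np <= 0)) stop("np must be > 0 (got ", np[np <= 0][1], ")",
                         call. = FALSE)
  (crd / np + cman_per_treatment) * (1 + mp)
}

#' Convert a per-treatment R&D share into a per-vial price
#'
#' R&D is allocated per gram of active ingredient (per-treatment R&D divided
#' by the number of vials a treatment consumes) and manufacturing is priced
#' per vial content; margins apply to the sum:
#' `(rd_per_treatment / (grams_per_treatment / vial_grams)
#'    + vial_grams * manuf_per_gram) * multiplier`.
#'
#' @param per_treatment_rd Pre-margin R&D cost allocated per treatment, EUR.
#' @param manuf_per_gram Manufacturing cost per gram, EUR.
#' @param grams_per_treatment Weighted dose per treatment, grams.
#' @param vial_grams Active ingredient per vial, grams; requires
#'   `grams_per_treatment >= vial_grams > 0`.
#' @param multiplier Margin multiplier, `1 + mp + msm`.
#' @return Price per vial, EUR.
#' @export
per_vial_price <- function(per_treatment_rd, manuf_per_gram,
                           grams_per_treatment, vial_grams, multiplier) {
  if (any(vial_grams <= 0) || any(grams_per_treatment <= 0)) {
    stop("grams_per_treatment and vial_grams must be > 0", call. = FALSE)
  }
  if (any(grams_per_treatment < vial_grams)) {
    stop("grams_per_treatment must be at least one vial (",
         "got dose < vial_grams)", call. = FALSE)
  }
  vials_per_treatment <- grams_per_treatment / vial_grams
  (per_treatment_rd / vials_per_treatment +
     vial_grams * manuf_per_gram) * multiplier
}

#' Decompose a per-vial price into pre-margin R&D and manufacturing parts
#'
#' Inverse of the per-vial composition: strips the margin multiplier and the
#' per-vial manufacturing cost, leaving the per-vial R&D allocation. Useful
#' for anchoring sensitivity transforms to published (euro-rounded) prices.
#'
#' @param per_vial Price per vial, EUR (> 0).
#' @param vial_grams Active ingredient per vial, grams.
#' @param cman_per_gram Manufacturing cost per gram, EUR.
#' @param mp,msm Profit and sales & marketing margins (fractions).
#' @return Named numeric vector with `rd_component` and `manuf_component`
#'   (both per vial, pre-margin, EUR).
#' @examples
#' decompose_price(31941, vial_grams = 1.8, cman_per_gram = 42.61,
#'                 mp = 0.2, msm = 0.3)
#' @export
decompose_price <- function(per_vial, vial_grams, cman_per_gram, mp, msm) {
  if (per_vial <= 0) stop("per_vial must be > 0", call. = FALSE)
  multiplier <- 1 + mp + msm
  if (multiplier <= 0) stop("1 + mp + msm must be > 0", call. = FALSE)
  manuf <- vial_grams * cman_per_gram
  rd <- per_vial / multiplier - manuf
  if (rd < 0) {
    stop("price below manufacturing floor: per-vial R&D component would be ",
         format(rd), call. = FALSE)
  }
  c(rd_component = rd, manuf_component = manuf)
}

# One pricing evaluation -> a breakdown row. rd_total/np_total/doses are the
# aggregated R&D pool, patient pool and per-indication (np, dose) vectors.
breakdown_row <- function(profile, rd_total, np, dose, n_indications,
                          mp = profile$cost$mp, allow_unpriceable = FALSE) {
  multiplier <- 1 + mp + profile$cost$msm
  np_total <- sum(np)
  if (np_total <= 0) {
    if (allow_unpriceable) {
      return(data.frame(rd_component = NA_real_, manuf_component = NA_real_,
                        multiplier = multiplier, per_treatment = NA_real_,
                        per_vial = NA_real_, n_indications = n_indications,
                        total_patients = np_total, weighted_dose = NA_real_,
                        unpriceable = TRUE))
    }
    stop("unpriceable: cumulative eligible patient population is zero",
         call. = FALSE)
  }
  cman <- profile$cost$cman_per_gram_adjusted
  weighted_dose <- sum(np * dose) / np_total
  rd_per_treatment <- rd_total / np_total
  manuf_per_treatment <- weighted_dose * cman
  per_treatment <- (rd_per_treatment + manuf_per_treatment) * multiplier
  per_vial <- per_vial_price(rd_per_treatment, cman, weighted_dose,
                             profile$vial_grams, multiplier)
  data.frame(rd_component = rd_per_treatment,
             manuf_component = manuf_per_treatment,
             multiplier = multiplier,
             per_treatment = per_treatment,
             per_vial = per_vial,
             n_indications = n_indications,
             total_patients = np_total,
             weighted_dose = weighted_dose,
             unpriceable = FALSE)
}

#' Fit the cost-based pricing model to a drug profile
#'
#' Evaluates the cost-based price of a drug over its patent life in one of
#' three modes:
#' \describe{
#'   \item{`"year"`}{Cumulative yearly prices: at evaluation year `t`, total
#'     R&D is the initial cost plus one incremental cost per indication
#'     approved after launch up to `t`; the patient pool sums, for every
#'     indication approved by `t`, its projected eligible patients from its
#'     approval year through `patent_expiry - 1`. One row per calendar year
#'     from launch to `patent_expiry - 1`.}
#'   \item{`"indication"`}{Cumulative prices per indication: row `k` uses the
#'     initial R&D plus `k - 1` incremental costs, and the pooled patients of
#'     indications `1..k`, each over its own remaining patent window. Equals
#'     the yearly mode evaluated at indication `k`'s approval year.}
#'   \item{`"ibp"`}{Non-cumulative indication-based prices: row `k` amortizes
#'     only that indication's R&D (the full initial cost for the launch
#'     indication, the incremental cost otherwise) over only that
#'     indication's patients.}
#' }
#' Manufacturing per treatment uses the patient-weighted mean dose of the
#' pooled indications; margins `1 + mp + msm` apply to the pre-margin sum.
#'
#' @param profile A [drug_profile()].
#' @param population A [population_table()]; defaults to the packaged
#'   UN more-developed-regions table.
#' @param mode `"year"`, `"indication"`, or `"ibp"`.
#' @param np_scale Scale factor applied to every year's eligible patients
#'   (used by the sensitivity analysis); 1 leaves the projection untouched.
#' @param allow_unpriceable If `TRUE`, rows whose patient pool is zero are
#'   returned as flagged `NA` ("unpriceable") records instead of erroring.
#' @return An object of class `"cbp"`: a list with the evaluation `schedule`
#'   (one data.frame row per year or indication), the `profile`, `population`
#'   and `mode`. Prices are full double precision; see
#'   [print.cbp()]/[summary.cbp()] for euro-rounded display and
#'   [as.data.frame.cbp()] / [write_price_table()] for export.
#' @examples
#' prof <- cbp_case_study("daratumumab")
#' fit <- cbp(prof)
#' round(fit$schedule$per_vial[1])   # launch-year price per vial
#' summary(fit)
#' @export
cbp <- function(profile, population = un_mdr_population(),
                mode = c("year", "indication", "ibp"),
                np_scale = 1, allow_unpriceable = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "drug_profile"))
  if (np_scale <= 0) stop("np_scale must be > 0", call. = FALSE)
  cost <- profile$cost
  rows <- switch(
    mode,
    year = {
      yrs <- seq.int(profile$launch_year, profile$patent_expiry - 1L)
      do.call(rbind, lapply(yrs, function(t) {
        pool <- patient_pool(profile, t, population)
        n_new <- sum(approval_years(profile) > profile$launch_year &
                       approval_years(profile) <= t)
        rd <- cost$crd_adjusted + n_new * cost$cex_adjusted
        cbind(index = t,
              breakdown_row(profile, rd, pool$np * np_scale, pool$dose,
                            n_indications = length(pool$np),
                            allow_unpriceable = allow_unpriceable))
      }))
    },
    indication = {
      ks <- seq_along(profile$indications)
      do.call(rbind, lapply(ks, function(k) {
        inds <- profile$indications[seq_len(k)]
        np <- vapply(inds, function(ind) {
          if (ind$approval_year >= profile$patent_expiry) {
            stop("indication approved at/after patent expiry", call. = FALSE)
          }
          yrs <- seq.int(ind$approval_year, profile$patent_expiry - 1L)
          sum(eligible_patients(ind, yrs, population))
        }, numeric(1))
        dose <- vapply(inds, `[[`, numeric(1), "grams_per_treatment")
        rd <- cost$crd_adjusted + (k - 1L) * cost$cex_adjusted
        cbind(index = k,
              breakdown_row(profile, rd, np * np_scale, dose,
                            n_indications = k,
                            allow_unpriceable = allow_unpriceable))
      }))
    },
    ibp = {
      ks <- seq_along(profile$indications)
      do.call(rbind, lapply(ks, function(k) {
        ind <- profile$indications[[k]]
        if (ind$approval_year >= profile$patent_expiry) {
          stop("indication ", k, " approved at/after patent expiry",
               call. = FALSE)
        }
        yrs <- seq.int(ind$approval_year, profile$patent_expiry - 1L)
        np_k <- sum(eligible_patients(ind, yrs, population))
        rd <- if (k == 1L) cost$crd_adjusted else cost$cex_adjusted
        cbind(index = k,
              breakdown_row(profile, rd, np_k * np_scale,
                            ind$grams_per_treatment, n_indications = 1L,
                            allow_unpriceable = allow_unpriceable))
      }))
    }
  )
  rownames(rows) <- NULL
  structure(list(schedule = rows, profile = profile, population = population,
                 mode = mode, np_scale = np_scale),
            class = "cbp")
}

#' Price a profile at a single cumulative evaluation year
#'
#' Convenience wrapper returning the single breakdown row of the cumulative
#' yearly model at `eval_year`.
#'
#' @inheritParams cbp
#' @param eval_year Calendar year, `launch_year <= eval_year < patent_expiry`.
#' @return A one-row data.frame (the price breakdown).
#' @export
cumulative_price_by_year <- function(profile, eval_year,
                                     population = un_mdr_population(),
                                     np_scale = 1,
                                     allow_unpriceable = FALSE) {
  if (eval_year >= profile$patent_expiry) {
    stop("patent expired: evaluation year ", eval_year,
         " is not before patent expiry ", profile$patent_expiry,
         call. = FALSE)
  }
  fit <- cbp(profile, population, mode = "year", np_scale = np_scale,
             allow_unpriceable = allow_unpriceable)
  row <- fit$schedule[fit$schedule$index == eval_year, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("evaluation year ", eval_year, " outside the pricing grid",
         call. = FALSE)
  }
  row
}

#' Cumulative price after k indications
#'
#' @inheritParams cumulative_price_by_year
#' @param k Indication index, `1 <= k <= length(profile$indications)`.
#' @return A one-row data.frame (the price breakdown).
#' @export
cumulative_price_by_indication <- function(profile, k,
                                           population = un_mdr_population(),
                                           np_scale = 1,
                                           allow_unpriceable = FALSE) {
  check_indication_index(profile, k)
  fit <- cbp(profile, population, mode = "indication", np_scale = np_scale,
             allow_unpriceable = allow_unpriceable)
  fit$schedule[fit$schedule$index == k, , drop = FALSE]
}

#' Non-cumulative indication-based price of indication k
#'
#' @inheritParams cumulative_price_by_indication
#' @return A one-row data.frame (the price breakdown).
#' @export
indication_based_price <- function(profile, k,
                                   population = un_mdr_population(),
                                   np_scale = 1,
                                   allow_unpriceable = FALSE) {
  check_indication_index(profile, k)
  fit <- cbp(profile, population, mode = "ibp", np_scale = np_scale,
             allow_unpriceable = allow_unpriceable)
  fit$schedule[fit$schedule$index == k, , drop = FALSE]
}

check_indication_index <- function(profile, k) {
  n <- length(profile$indications)
  if (length(k) != 1L || k < 1 || k > n || k != as.integer(k)) {
    stop("indication index k must be an integer in 1..", n, " (got ",
         deparse(k), ")", call. = FALSE)
  }
}

#' @export
print.cbp <- function(x, ...) {
  lab <- switch(x$mode, year = "cumulative year", indication =
                "cumulative indication", ibp = "indication-based")
  cat(sprintf("Cost-based prices for %s (%s mode)\n", x$profile$name, lab))
  s <- x$schedule
  df <- data.frame(index = s$index,
                   per_treatment = round(s$per_treatment),
                   per_vial = round(s$per_vial),
                   patients = round(s$total_patients))
  names(df)[1] <- switch(x$mode, year = "year", "indication")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cbp <- function(object, ...) {
  s <- object$schedule
  ok <- !s$unpriceable
  out <- list(
    drug = object$profile$name,
    mode = object$mode,
    n = nrow(s),
    per_vial_range = range(s$per_vial[ok]),
    per_treatment_range = range(s$per_treatment[ok]),
    launch_per_vial = s$per_vial[1],
    multiplier = s$multiplier[1]
  )
  class(out) <- "summary.cbp"
  out
}

#' @export
print.summary.cbp <- function(x, ...) {
  cat(sprintf("Cost-based pricing summary: %s (%s mode, %d points)\n",
              x$drug, x$mode, x$n))
  cat(sprintf("  per-vial price range : %s – %s EUR\n",
              format(round(x$per_vial_range[1]), big.mark = ","),
              format(round(x$per_vial_range[2]), big.mark = ",")))
  cat(sprintf("  launch/first price   : %s EUR per vial\n",
              format(round(x$launch_per_vial), big.mark = ",")))
  cat(sprintf("  margin multiplier    : %.3f\n", x$multiplier))
  invisible(x)
}

#' @export
as.data.frame.cbp <- function(x, ...) {
  s <- x$schedule
  data.frame(drug = x$profile$name, mode = x$mode, index = s$index,
             rd_component = s$rd_component,
             manuf_component = s$manuf_component,
             multiplier = s$multiplier,
             per_treatment = s$per_treatment,
             per_vial = s$per_vial,
             stringsAsFactors = FALSE)
}

#' @export
plot.cbp <- function(x, which = c("per_vial", "per_treatment"), ...) {
  which <- match.arg(which)
  s <- x$schedule
  xlab <- if (x$mode == "year") "calendar year" else "indication"
  graphics::plot(s$index, s[[which]], type = "b", pch = 19,
                 xlab = xlab, ylab = paste("EUR", sub("_", " ", which)),
                 main = sprintf("%s (%s mode)", x$profile$name, x$mode), ...)
  invisible(x)
}

#' Per-vial prices from a fitted pricing model
#'
#' @param object A `"cbp"` fit.
#' @param index Years (mode `"year"`) or indication indices to extract;
#'   defaults to the full grid.
#' @param ... Unused.
#' @return Named numeric vector of per-vial prices.
#' @export
predict.cbp <- function(object, index = NULL, ...) {
  s <- object$schedule
  if (is.null(index)) index <- s$index
  m <- match(index, s$index)
  if (anyNA(m)) {
    stop("index value(s) ", paste(index[is.na(m)], collapse = ", "),
         " not on the evaluation grid", call. = FALSE)
  }
  stats::setNames(s$per_vial[m], s$index[m])
}
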