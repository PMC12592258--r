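# Steady-state exposure metrics (Ctrough, Caverage), cohort-level summaries,
# geometric-mean-ratio comparisons with bioequivalence-style verdicts,
# threshold attainment and annual drug cost.

#' Steady-state exposure metrics for one individual
#'
#' `ctrough` is the minimum concentration over the steady-state window,
#' located by evaluating the closed form on a regular grid augmented with the
#' exact pre-dose timepoints (at periodic steady state with oral absorption
#' the minimum falls on a pre-dose point, so it is not grid-limited).
#' `caverage` is the time-averaged concentration over the window, computed
#' analytically as `(dose per period) * F / (CL * period)`; at exact periodic
#' steady state the weekly average equals the per-period average.
#'
#' @param params A [structural_params()] object.
#' @param regimen A [regimen()] object.
#' @param grid_step Trough search grid, h.
#' @return A list with `ctrough` and `caverage`, mg/L.
#' @export
exposure_metrics <- function(params, regimen, grid_step = 0.1) {
  stopifnot(inherits(params, "structural_params"), inherits(regimen, "regimen"))
  times <- sort(unique(c(seq(0, regimen$period, by = grid_step), regimen$times)))
  list(ctrough = min(css_conc(params, regimen, times)),
       caverage = sum(regimen$amounts) * params$F / (params$CL * regimen$period))
}

# Vectorized steady-state trough across a cohort. Parameters are equal-length
# vectors; returns the per-patient minimum over (grid within one period +
# exact pre-dose times). ka values colliding with a disposition eigenvalue
# are nudged by the same relative perturbation as macro_constants().
cohort_trough <- function(CL, V1, Q, V2, ka, regimen, grid_step = 0.1, F = 1) {
  # grid_step = Inf restricts the search to the exact pre-dose times (the
  # minimum of an oral steady-state profile; used on hot paths)
  times <- if (is.finite(grid_step)) {
    sort(unique(c(seq(0, regimen$period, by = grid_step), regimen$times)))
  } else {
    sort(unique(regimen$times))
  }
  two <- any(Q > 0)
  if (two && any(Q <= 0))
    stop("mixed one-/two-compartment cohorts are not supported", call. = FALSE)
  if (two) {
    k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
    s <- k10 + k12 + k21; p <- k10 * k21
    disc <- sqrt(pmax(s^2 - 4 * p, 0))
    al <- (s + disc) / 2; be <- (s - disc) / 2
    hit <- abs(ka - al) / al < .KA_GAP | abs(ka - be) / be < .KA_GAP
    if (any(hit)) ka[hit] <- ka[hit] * (1 + .KA_GAP)
    lam <- cbind(al, be, ka)
    A <- F * ka / V1 * cbind((k21 - al) / ((ka - al) * (be - al)),
                             (k21 - be) / ((ka - be) * (al - be)),
                             (k21 - ka) / ((al - ka) * (be - ka)))
  } else {
    ke <- CL / V1
    hit <- abs(ka - ke) / ke < .KA_GAP
    if (any(hit)) ka[hit] <- ka[hit] * (1 + .KA_GAP)
    A1 <- F * ka / (V1 * (ka - ke))
    lam <- cbind(ke, ka)
    A <- cbind(A1, -A1)
  }
  Tt <- regimen$period
  conc <- matrix(0, length(CL), length(times))
  for (j in seq_along(regimen$times)) {
    dt <- (times - regimen$times[j]) %% Tt
    for (i in seq_len(ncol(lam))) {
      conc <- conc + regimen$amounts[j] * (A[, i] / (1 - exp(-lam[, i] * Tt))) *
        exp(-outer(lam[, i], dt))
    }
  }
  if (ncol(conc) == 1) return(conc[, 1])
  do.call(pmin, as.data.frame(conc))
}

#' Per-patient steady-state exposure metrics for a cohort
#'
#' @param cohort A cohort data frame from [sample_cohort()] (columns `CL`,
#'   `V1`, `Q`, `V2`, `ka`).
#' @param regimen A [regimen()] object.
#' @param grid_step Trough search grid, h.
#' @return A data frame with `patient_id`, `ctrough` and `caverage` (mg/L).
#' @export
cohort_exposures <- function(cohort, regimen, grid_step = 0.1) {
  stopifnot(inherits(regimen, "regimen"),
            all(c("CL", "V1", "Q", "V2", "ka") %in% names(cohort)))
  data.frame(
    patient_id = cohort$patient_id %||% seq_len(nrow(cohort)),
    ctrough = cohort_trough(cohort$CL, cohort$V1, cohort$Q, cohort$V2,
                            cohort$ka, regimen, grid_step),
    caverage = sum(regimen$amounts) / (cohort$CL * regimen$period))
}

#' Geometric mean
#' @param x Positive values.
#' @return `exp(mean(log(x)))`.
#' @export
geo_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires positive values", call. = FALSE)
  exp(mean(log(x)))
}

#' Summarize an exposure metric across a cohort
#'
#' Geometric mean and arithmetic coefficient of variation (sample SD / mean,
#' in percent) of a per-patient exposure metric.
#'
#' @param values Positive per-patient metric values, mg/L.
#' @param metric Metric name, `"Ctrough"` or `"Caverage"`.
#' @return An object of class `exposure_summary`: `metric`, `gm`, `cv_pct`, `n`.
#' @examples
#' summarize_exposures(c(1, 4), "Ctrough") # gm 2, cv 84.85%
#' @export
summarize_exposures <- function(values, metric = c("Ctrough", "Caverage")) {
  metric <- match.arg(metric)
  if (any(values <= 0)) stop("exposure values must be positive", call. = FALSE)
  cv <- if (length(values) > 1) stats::sd(values) / mean(values) else 0
  structure(list(metric = metric, gm = geo_mean(values), cv_pct = 100 * cv,
                 n = length(values)),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("%s: geometric mean %.3g mg/L (%.1f%% CV), n = %d\n",
              x$metric, x$gm, x$cv_pct, x$n))
  invisible(x)
}

#' Compare a test scenario against a reference scenario
#'
#' Computes the geometric mean ratio (GMR) of an exposure metric, the
#' bioequivalence-style verdicts, and the fraction of test patients above an
#' efficacy threshold. `equivalence_pass` applies the conventional
#' 0.80-1.25 window; `not_lower_pass` applies the one-sided "not more than
#' 20% lower" criterion (`gm_test >= 0.8 * gm_ref`).
#'
#' @param test,ref [summarize_exposures()] objects on the same metric.
#' @param test_values Per-patient test-scenario values (for the threshold
#'   fraction); optional.
#' @param threshold Efficacy threshold, mg/L (default the proposed 0.0568
#'   mg/L steady-state trough threshold).
#' @return An object of class `comparison_result`: `gmr`, `equivalence_pass`,
#'   `not_lower_pass`, `fraction_above_threshold` (percent, `NA` if no values
#'   supplied).
#' @export
compare_exposures <- function(test, ref, test_values = NULL, threshold = 0.0568) {
  stopifnot(inherits(test, "exposure_summary"), inherits(ref, "exposure_summary"))
  if (test$metric != ref$metric)
    stop("cannot compare different metrics (", test$metric, " vs ", ref$metric, ")",
         call. = FALSE)
  gmr <- test$gm / ref$gm
  structure(list(metric = test$metric, gmr = gmr,
                 equivalence_pass = gmr >= 0.80 && gmr <= 1.25,
                 not_lower_pass = test$gm >= 0.8 * ref$gm,
                 fraction_above_threshold =
                   if (is.null(test_values)) NA_real_
                   else fraction_above(test_values, threshold)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s GMR %.2f [equivalence (0.80-1.25): %s; not >20%% lower: %s]",
              x$metric, x$gmr,
              if (x$equivalence_pass) "pass" else "fail",
              if (x$not_lower_pass) "pass" else "fail"))
  if (!is.na(x$fraction_above_threshold))
    cat(sprintf("; %.1f%% above threshold", x$fraction_above_threshold))
  cat("\n")
  invisible(x)
}

#' Percentage of patients above an efficacy threshold
#'
#' Strict inequality; ties are measure-zero under the continuous model.
#'
#' @param values Per-patient metric values.
#' @param threshold Threshold on the same scale.
#' @return Percentage in \[0, 100\].
#' @export
fraction_above <- function(values, threshold) {
  100 * mean(values > threshold)
}

#' Annual drug cost of a regimen
#'
#' Pricing is per dosing day: any combination of tablets taken on the same
#' day costs one dosing-day price (the 80/160/240 mg strengths are priced
#' identically). A regimen's dosing days per year are
#' `365 * (days with at least one dose in the period) / (period in days)`;
#' once daily gives 365, every other day 182.5.
#'
#' @param regimen A [regimen()] object.
#' @param price_per_dosing_day Price, USD (default $728/day).
#' @param reference Optional reference [regimen()] for the savings column.
#' @param year_days Days per year (365; matches $728 x 365 = $265,720).
#' @return An object of class `cost_summary`: `regimen`,
#'   `price_per_dosing_day`, `dosing_days_per_year`, `annual_cost`,
#'   `savings_vs_reference` (`NA` without a reference).
#' @examples
#' annual_cost(regimen_preset("240QD"))                      # $265,720
#' annual_cost(regimen_preset("240QOD"), reference = regimen_preset("240QD"))
#' @export
annual_cost <- function(regimen, price_per_dosing_day = 728, reference = NULL,
                        year_days = 365) {
  stopifnot(inherits(regimen, "regimen"), price_per_dosing_day > 0)
  days <- function(r) {
    period_days <- r$period / 24
    dose_days <- length(unique(floor(r$times / 24)))
    year_days * dose_days / period_days
  }
  d <- days(regimen)
  cost <- price_per_dosing_day * d
  structure(list(regimen = regimen$label,
                 price_per_dosing_day = price_per_dosing_day,
                 dosing_days_per_year = d,
                 annual_cost = cost,
                 savings_vs_reference =
                   if (is.null(reference)) NA_real_
                   else price_per_dosing_day * days(reference) - cost),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("%s: %.1f dosing days/year x $%g = $%s/year",
              x$regimen, x$dosing_days_per_year, x$price_per_dosing_day,
              format(x$annual_cost, big.mark = ",")))
  if (!is.na(x$savings_vs_reference))
    cat(sprintf(" (savings vs reference: $%s)",
                format(x$savings_vs_reference, big.mark = ",")))
  cat("\n")
  invisible(x)
}
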