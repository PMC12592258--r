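# Closed-form linear PK engine: two-compartment (or one-compartment) model
# with first-order oral absorption, evaluated as a sum of exponentials and
# brought to exact periodic steady state by geometric-series superposition.

#' Apparent structural pharmacokinetic parameters for one individual
#'
#' All parameters are apparent oral-scale quantities (CL/F, V/F); relative
#' bioavailability `F` is fixed at 1 because only dose-normalized parameters
#' are identifiable from oral exposure data. Setting `Q = 0` (or `V2 = 0`)
#' collapses the model to one-compartment first-order absorption (Bateman)
#' kinetics.
#'
#' @param CL Apparent clearance, L/h.
#' @param V1 Apparent central volume of distribution, L.
#' @param Q Apparent inter-compartmental clearance, L/h. `0` selects the
#'   one-compartment model.
#' @param V2 Apparent peripheral volume, L. Ignored (may be 0) when `Q = 0`.
#' @param ka First-order absorption rate constant, 1/h.
#' @param F Relative bioavailability fraction, fixed default 1.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(CL = 57.5, V1 = 60, Q = 43, V2 = 1660, ka = 0.10)
#' structural_params(CL = 10, V1 = 50, Q = 0, V2 = 0, ka = 1) # one-compartment
#' @export
structural_params <- function(CL, V1, Q = 0, V2 = 0, ka, F = 1) {
  stopifnot(is.numeric(CL), is.numeric(V1), is.numeric(Q), is.numeric(V2),
            is.numeric(ka), is.numeric(F))
  if (CL <= 0 || V1 <= 0 || ka <= 0 || F <= 0)
    stop("CL, V1, ka and F must be strictly positive", call. = FALSE)
  if (Q < 0 || V2 < 0)
    stop("Q and V2 must be non-negative", call. = FALSE)
  if (xor(Q == 0, V2 == 0))
    stop("Q and V2 must both be zero (one-compartment) or both positive",
         call. = FALSE)
  structure(list(CL = CL, V1 = V1, Q = Q, V2 = V2, ka = ka, F = F),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf(
    "Apparent PK parameters (%s-compartment oral):\n", if (x$Q > 0) "two" else "one"))
  cat(sprintf("  CL = %.4g L/h, V1 = %.4g L, Q = %.4g L/h, V2 = %.4g L, ka = %.4g 1/h\n",
              x$CL, x$V1, x$Q, x$V2, x$ka))
  invisible(x)
}

# minimum relative gap between ka and a disposition eigenvalue before the
# removable singularity in the macro constants is perturbed away
.KA_GAP <- 1e-6

#' Macro-constant decomposition of the oral concentration curve
#'
#' Decomposes the single-dose central-compartment concentration into
#' per-unit-dose exponential terms, `C(t) = D * F * sum_i A_i exp(-lambda_i t)`.
#' For the two-compartment model the disposition eigenvalues `alpha >= beta`
#' solve `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0` and the oral
#' input contributes the third rate `ka`; for `Q = 0` the decomposition has
#' exactly two terms (the Bateman equation). The coefficients always sum to
#' zero, so the concentration starts at zero.
#'
#' If `ka` falls within a relative gap of `1e-6` of a disposition eigenvalue,
#' `ka` is perturbed upward by that relative amount (with a warning) rather
#' than evaluating the confluent limit.
#'
#' @param params A [structural_params()] object.
#' @return An object of class `macro_constants`: list with `lambda` (rates,
#'   1/h, all positive) and `A` (per-unit-dose coefficients, 1/L, summing to 0).
#' @examples
#' mc <- macro_constants(structural_params(CL = 57.5, V1 = 60, Q = 43,
#'                                         V2 = 1660, ka = 0.10))
#' sum(mc$A) # 0: oral curves start at zero concentration
#' @export
macro_constants <- function(params) {
  stopifnot(inherits(params, "structural_params"))
  ka <- params$ka
  if (params$Q > 0) {
    k10 <- params$CL / params$V1
    k12 <- params$Q / params$V1
    k21 <- params$Q / params$V2
    s <- k10 + k12 + k21
    p <- k10 * k21
    disc <- sqrt(max(s^2 - 4 * p, 0))
    lam <- c((s + disc) / 2, (s - disc) / 2)
    if (any(abs(ka - lam) / lam < .KA_GAP)) {
      warning("ka coincides with a disposition eigenvalue; perturbing ka by 1e-6 (relative)",
              call. = FALSE)
      while (any(abs(ka - lam) / lam < .KA_GAP)) ka <- ka * (1 + .KA_GAP)
    }
    al <- lam[1]; be <- lam[2]
    A <- params$F * ka / params$V1 * c(
      (k21 - al) / ((ka - al) * (be - al)),
      (k21 - be) / ((ka - be) * (al - be)),
      (k21 - ka) / ((al - ka) * (be - ka)))
    out <- list(lambda = c(al, be, ka), A = A)
  } else {
    ke <- params$CL / params$V1
    if (abs(ka - ke) / ke < .KA_GAP) {
      warning("ka coincides with the elimination rate; perturbing ka by 1e-6 (relative)",
              call. = FALSE)
      while (abs(ka - ke) / ke < .KA_GAP) ka <- ka * (1 + .KA_GAP)
    }
    A1 <- params$F * ka / (params$V1 * (ka - ke))
    out <- list(lambda = c(ke, ka), A = c(A1, -A1))
  }
  structure(out, class = "macro_constants")
}

#' Concentration after a single oral dose
#'
#' @param params A [structural_params()] object.
#' @param t Times since dose, h (vector, `>= 0`).
#' @param dose Dose amount, mg.
#' @return Concentrations, mg/L.
#' @export
conc_single_dose <- function(params, t, dose) {
  stopifnot(all(t >= 0), dose > 0)
  mc <- macro_constants(params)
  drop(dose * exp(-outer(t, mc$lambda)) %*% mc$A)
}

#' Periodic oral dosing regimen
#'
#' A regimen is a dosing period (h) and an ordered set of dose events within
#' it. Dose amounts must be composable from the available tablet strengths
#' (80 mg and 240 mg by default, i.e. any positive multiple of 80 mg).
#'
#' @param period Period length, h (e.g. 24 for once daily, 48 for every other
#'   day or alternating-dose schedules).
#' @param times Dose times within the period, h; strictly increasing,
#'   `0 <= t < period`.
#' @param amounts Dose amounts, mg; positive, same length as `times`.
#' @param label Text label.
#' @param tablets Available tablet strengths, mg; set `NULL` to skip the
#'   composability check.
#' @return An object of class `regimen`.
#' @seealso [regimen_preset()] for the built-in named regimens.
#' @examples
#' regimen(24, 0, 240, "240 mg QD")
#' regimen(48, c(0, 24), c(80, 160), "80/160 mg alternating")
#' @export
regimen <- function(period, times, amounts, label = NULL, tablets = c(80, 240)) {
  stopifnot(is.numeric(period), is.numeric(times), is.numeric(amounts))
  if (period <= 0) stop("period must be positive", call. = FALSE)
  if (length(times) == 0) stop("a regimen needs at least one dose event", call. = FALSE)
  if (length(times) != length(amounts))
    stop("times and amounts must have equal length", call. = FALSE)
  if (any(times < 0) || any(times >= period))
    stop("dose times must satisfy 0 <= t < period", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("dose times must be strictly increasing within the period", call. = FALSE)
  if (any(amounts <= 0)) stop("dose amounts must be positive", call. = FALSE)
  if (!is.null(tablets)) {
    bad <- !vapply(amounts, tablet_composable, logical(1), tablets = tablets)
    if (any(bad))
      stop(sprintf("dose amount(s) %s not composable from %s mg tablets",
                   paste(amounts[bad], collapse = ", "),
                   paste(tablets, collapse = "/")), call. = FALSE)
  }
  structure(list(period = period, times = times, amounts = amounts,
                 label = label %||% sprintf("%s mg at t=%s h / %g h",
                                            paste(amounts, collapse = "+"),
                                            paste(times, collapse = ","), period)),
            class = "regimen")
}

# can `amount` be written as a non-negative integer combination of tablets?
tablet_composable <- function(amount, tablets = c(80, 240)) {
  if (amount <= 0) return(FALSE)
  g <- tablets[1]
  for (t in tablets[-1]) {
    r <- function(a, b) if (b == 0) a else Recall(b, a %% b)
    g <- r(g, t)
  }
  if (amount %% g != 0) return(FALSE)
  # small search over counts of the largest tablet
  big <- max(tablets); small <- min(tablets)
  any((amount - big * 0:(amount %/% big)) %% small == 0)
}

#' Built-in dosing regimens
#'
#' Named presets: `"240QD"` (approved 240 mg once daily), `"160QD"` (160 mg
#' once daily as two 80 mg tablets), `"240QOD"` (240 mg every other day) and
#' `"80_160_ALT"` (80 mg and 160 mg on alternating days).
#'
#' @param name Preset name.
#' @return A [regimen()] object.
#' @export
regimen_preset <- function(name = c("240QD", "160QD", "240QOD", "80_160_ALT")) {
  name <- match.arg(name)
  switch(name,
    "240QD"      = regimen(24, 0, 240, "240 mg QD"),
    "160QD"      = regimen(24, 0, 160, "160 mg QD"),
    "240QOD"     = regimen(48, 0, 240, "240 mg every other day"),
    "80_160_ALT" = regimen(48, c(0, 24), c(80, 160), "80/160 mg alternating days"))
}

#' Read a regimen from a YAML-like JSON/CSV-free plain-text config
#'
#' The config is a JSON document with fields `period`, `events` (array of
#' `{time, amount}`) and optional `label`.
#'
#' @param path Path to a JSON regimen file.
#' @return A [regimen()] object.
#' @export
read_regimen <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$period) || is.null(x$events))
    stop("regimen config must contain 'period' and 'events'", call. = FALSE)
  ev <- as.data.frame(x$events)
  regimen(x$period, ev$time, ev$amount, x$label)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen '%s': period %g h, doses %s mg at t = %s h\n",
              x$label, x$period, paste(x$amounts, collapse = ", "),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

#' Steady-state concentration profile under periodic dosing
#'
#' Exact periodic steady state by superposition: each dose event contributes
#' `D * A_i * exp(-lambda_i * ((t - t_j) mod T)) / (1 - exp(-lambda_i * T))`
#' per exponential term. The profile is evaluated on a regular grid extended
#' with the exact pre-dose timepoints so that troughs are not grid-limited.
#' Oral absorption makes the curve continuous, so the value returned at a
#' dose time equals the pre-dose (trough) value.
#'
#' @param params A [structural_params()] object.
#' @param regimen A [regimen()] object.
#' @param window Length of the steady-state window, h (default one week).
#' @param grid_step Grid resolution, h (default 0.1).
#' @return A data frame of class `concentration_grid` with columns `time_h`
#'   and `conc_mg_per_L`.
#' @examples
#' p <- structural_params(CL = 57.5, V1 = 60, Q = 43, V2 = 1660, ka = 0.10)
#' prof <- css_profile(p, regimen_preset("240QD"))
#' range(prof$conc_mg_per_L)
#' @export
css_profile <- function(params, regimen, window = 168, grid_step = 0.1) {
  stopifnot(inherits(params, "structural_params"), inherits(regimen, "regimen"),
            window > 0, grid_step > 0)
  tgrid <- seq(0, window, by = grid_step)
  # exact pre-dose timepoints across the window
  predose <- as.vector(outer(regimen$times, seq(0, window, by = regimen$period), "+"))
  predose <- predose[predose <= window]
  times <- sort(unique(c(tgrid, predose)))
  conc <- css_conc(params, regimen, times)
  structure(data.frame(time_h = times, conc_mg_per_L = conc),
            class = c("concentration_grid", "data.frame"),
            regimen = regimen, params = params)
}

#' Steady-state concentration at arbitrary times
#'
#' Workhorse behind [css_profile()]; evaluates the superposition closed form
#' at the requested times.
#'
#' @inheritParams css_profile
#' @param times Times, h (any non-negative values; the profile is periodic).
#' @return Concentrations, mg/L.
#' @export
css_conc <- function(params, regimen, times) {
  mc <- macro_constants(params)
  conc <- numeric(length(times))
  Tt <- regimen$period
  for (j in seq_along(regimen$times)) {
    dt <- (times - regimen$times[j]) %% Tt
    for (i in seq_along(mc$lambda)) {
      li <- mc$lambda[i]
      conc <- conc + regimen$amounts[j] * mc$A[i] * exp(-li * dt) / (1 - exp(-li * Tt))
    }
  }
  conc
}

#' Export a concentration profile as CSV
#'
#' @param profile A `concentration_grid` from [css_profile()].
#' @param path Output CSV path (columns `time_h`, `conc_mg_per_L`).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("time_h", "conc_mg_per_L")],
                   path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
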