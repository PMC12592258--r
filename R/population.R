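# Virtual-patient cohort generator: covariate distributions, log-normal
# inter-individual variability, and the covariate model mapping a patient to
# individual structural PK parameters.

#' Covariate distribution of the simulated population
#'
#' The simulated population is non-Japanese, treatment-naive, with body
#' weight log-normal around a geometric mean of 70 kg with 20% coefficient of
#' variation (a European reference population) and a 1:1 sex ratio. The "20%
#' log-normal CV" is interpreted as the arithmetic CV of the log-normal
#' weight distribution, i.e. `sigma_log = sqrt(log(1 + cv^2))`.
#'
#' @param weight_gm Geometric mean body weight, kg.
#' @param weight_cv Arithmetic coefficient of variation of weight (fraction).
#' @param sex_prob_female Probability that a patient is female.
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(weight_gm = 70, weight_cv = 0.20, sex_prob_female = 0.5) {
  if (weight_gm <= 0) stop("weight_gm must be positive", call. = FALSE)
  if (weight_cv < 0) stop("weight_cv must be non-negative", call. = FALSE)
  if (sex_prob_female < 0 || sex_prob_female > 1)
    stop("sex_prob_female must lie in [0, 1]", call. = FALSE)
  structure(list(weight_gm = weight_gm, weight_cv = weight_cv,
                 sex_prob_female = sex_prob_female,
                 ethnicity = "non-Japanese", pretreatment = "treatment-naive"),
            class = "covariate_model")
}

#' Inter-individual variability model
#'
#' Log-normal random effects on the structural parameters. `omega_*` are
#' standard deviations of the log-scale effects; `corr_CL_V` is the
#' correlation between the clearance and central-volume effects (the other
#' effects are independent). Clearance variability is the dominant term (the
#' calibrated value is close to the reported ~37% clearance IIV); `omega_ka`
#' and `omega_V2` carry the additional between-patient dispersion seen in
#' trough (but not average) concentrations.
#'
#' @param omega_CL,omega_V1,omega_ka,omega_V2 Log-scale SDs (>= 0).
#' @param corr_CL_V Correlation between the CL and V1 effects, in \[-1, 1\].
#' @return An object of class `iiv_model`.
#' @export
iiv_model <- function(omega_CL = 0, omega_V1 = 0, omega_ka = 0, omega_V2 = 0,
                      corr_CL_V = 0) {
  om <- c(omega_CL, omega_V1, omega_ka, omega_V2)
  if (any(om < 0)) stop("omegas must be non-negative", call. = FALSE)
  if (abs(corr_CL_V) > 1) stop("corr_CL_V must lie in [-1, 1]", call. = FALSE)
  structure(list(omega_CL = omega_CL, omega_V1 = omega_V1, omega_ka = omega_ka,
                 omega_V2 = omega_V2, corr_CL_V = corr_CL_V),
            class = "iiv_model")
}

#' Population-typical model with covariate effects
#'
#' Typical (reference-individual) parameter values together with the
#' covariate model: allometric weight scaling (exponent 0.75 on clearances,
#' 1.0 on volumes, reference 70 kg), a multiplicative clearance fraction for
#' the GSTM1 null genotype, and neutral (1.0) multiplicative hooks for sex,
#' ethnicity and pretreatment, whose magnitudes are not identifiable from the
#' published exposure summaries.
#'
#' @param tvcl_nonnull Typical apparent clearance of a GSTM1 non-null
#'   individual, L/h.
#' @param gstm1_cl_fraction Multiplier on clearance for the null genotype
#'   (0 < fraction < 1); about 1/1.78 when calibrated.
#' @param tvv1,tvq,tvv2,tvka Typical disposition/absorption parameters.
#' @param allo_cl,allo_v Allometric exponents for clearances and volumes.
#' @param ref_weight Allometric reference weight, kg.
#' @param sex_cl_female Multiplicative sex effect on clearance (default 1,
#'   neutral).
#' @param iiv An [iiv_model()].
#' @return An object of class `typical_model`.
#' @export
typical_model <- function(tvcl_nonnull, gstm1_cl_fraction, tvv1, tvq, tvv2, tvka,
                          allo_cl = 0.75, allo_v = 1.0, ref_weight = 70,
                          sex_cl_female = 1.0, iiv = iiv_model()) {
  vals <- c(tvcl_nonnull, tvv1, tvka)
  if (any(vals <= 0)) stop("typical values must be positive", call. = FALSE)
  if (tvq < 0 || tvv2 < 0) stop("tvq and tvv2 must be non-negative", call. = FALSE)
  if (gstm1_cl_fraction <= 0 || gstm1_cl_fraction >= 1)
    stop("gstm1_cl_fraction must lie in (0, 1)", call. = FALSE)
  stopifnot(inherits(iiv, "iiv_model"))
  structure(list(tvcl_nonnull = tvcl_nonnull,
                 gstm1_cl_fraction = gstm1_cl_fraction,
                 tvv1 = tvv1, tvq = tvq, tvv2 = tvv2, tvka = tvka,
                 allo_cl = allo_cl, allo_v = allo_v, ref_weight = ref_weight,
                 sex_cl_female = sex_cl_female, iiv = iiv),
            class = "typical_model")
}

#' @export
print.typical_model <- function(x, ...) {
  cat("Population-typical PK model (apparent oral parameters)\n")
  cat(sprintf("  CL(non-null) %.4g L/h | GSTM1-null fraction %.4g (fold %.3g)\n",
              x$tvcl_nonnull, x$gstm1_cl_fraction, 1 / x$gstm1_cl_fraction))
  cat(sprintf("  V1 %.4g L | Q %.4g L/h | V2 %.4g L | ka %.4g 1/h\n",
              x$tvv1, x$tvq, x$tvv2, x$tvka))
  cat(sprintf("  allometry: CL,Q ~ (W/%g)^%g; V1,V2 ~ (W/%g)^%g\n",
              x$ref_weight, x$allo_cl, x$ref_weight, x$allo_v))
  cat(sprintf("  IIV (log-SD): CL %.3g, V1 %.3g, ka %.3g, V2 %.3g, corr(CL,V1) %.3g\n",
              x$iiv$omega_CL, x$iiv$omega_V1, x$iiv$omega_ka, x$iiv$omega_V2,
              x$iiv$corr_CL_V))
  invisible(x)
}

#' Map covariates and random effects to individual parameters
#'
#' `CL = tvcl_nonnull * (W/70)^0.75 * gstm1_cl_fraction^[null] * sex_effect *
#' exp(eta_CL)`, `V1 = tvv1 * (W/70)^1 * exp(eta_V1)`, `Q` and `V2` scale
#' allometrically with `ka = tvka * exp(eta_ka)`, `V2` carrying `eta_V2`.
#'
#' @param typical A [typical_model()].
#' @param weight Body weight, kg.
#' @param genotype `"null"` or `"non-null"`.
#' @param sex `"F"` or `"M"` (only acts through the neutral-by-default
#'   clearance hook).
#' @param eta_CL,eta_V1,eta_ka,eta_V2 Log-scale random effects.
#' @return A [structural_params()] object.
#' @examples
#' tm <- typical_model(57.5, 0.56, 60, 43, 1660, 0.10)
#' individualize(tm, weight = 70, genotype = "non-null") # the typical individual
#' @export
individualize <- function(typical, weight, genotype = c("non-null", "null"),
                          sex = "M", eta_CL = 0, eta_V1 = 0, eta_ka = 0,
                          eta_V2 = 0) {
  stopifnot(inherits(typical, "typical_model"), weight > 0)
  genotype <- match.arg(genotype)
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'", call. = FALSE)
  wcl <- (weight / typical$ref_weight)^typical$allo_cl
  wv <- (weight / typical$ref_weight)^typical$allo_v
  cl <- typical$tvcl_nonnull * wcl * exp(eta_CL) *
    (if (genotype == "null") typical$gstm1_cl_fraction else 1) *
    (if (sex == "F") typical$sex_cl_female else 1)
  structural_params(CL = cl,
                    V1 = typical$tvv1 * wv * exp(eta_V1),
                    Q = typical$tvq * wcl,
                    V2 = typical$tvv2 * wv * exp(eta_V2),
                    ka = typical$tvka * exp(eta_ka))
}

#' Sample a virtual cohort
#'
#' Draws `n` virtual patients: i.i.d. log-normal body weights (geometric mean
#' `weight_gm`, arithmetic CV `weight_cv`), Bernoulli sexes, a fixed GSTM1
#' genotype, and log-normal random effects from the IIV model (CL and V1
#' possibly correlated; ka and V2 independent), then maps each patient to
#' individual structural parameters.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param cov A [covariate_model()].
#' @param genotype `"null"` or `"non-null"` for the whole cohort.
#' @param typical A [typical_model()].
#' @return A data frame with one row per patient: `patient_id`, `weight_kg`,
#'   `sex`, `genotype`, `eta_CL`, `eta_V1`, `eta_ka`, `eta_V2`, `CL`, `V1`,
#'   `Q`, `V2`, `ka`.
#' @examples
#' tm <- typical_model(57.5, 0.56, 60, 43, 1660, 0.10,
#'                     iiv = iiv_model(omega_CL = 0.38))
#' coh <- sample_cohort(5, seed = 1, genotype = "null", typical = tm)
#' exp(mean(log(coh$CL))) # geometric-mean clearance
#' @export
sample_cohort <- function(n, seed, cov = covariate_model(),
                          genotype = c("non-null", "null"), typical) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  genotype <- match.arg(genotype)
  stopifnot(inherits(cov, "covariate_model"), inherits(typical, "typical_model"))
  iiv <- typical$iiv

  set.seed(as.integer(seed))
  sw <- sqrt(log(1 + cov$weight_cv^2))
  weight <- cov$weight_gm * exp(stats::rnorm(n, 0, sw))
  sex <- ifelse(stats::runif(n) < cov$sex_prob_female, "F", "M")
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  eta_CL <- iiv$omega_CL * z1
  eta_V1 <- iiv$omega_V1 * (iiv$corr_CL_V * z1 + sqrt(1 - iiv$corr_CL_V^2) * z2)
  eta_ka <- stats::rnorm(n, 0, iiv$omega_ka)
  eta_V2 <- stats::rnorm(n, 0, iiv$omega_V2)

  wcl <- (weight / typical$ref_weight)^typical$allo_cl
  wv <- (weight / typical$ref_weight)^typical$allo_v
  gfrac <- if (genotype == "null") typical$gstm1_cl_fraction else 1
  sfac <- ifelse(sex == "F", typical$sex_cl_female, 1)
  data.frame(
    patient_id = seq_len(n),
    weight_kg = weight, sex = sex, genotype = genotype,
    eta_CL = eta_CL, eta_V1 = eta_V1, eta_ka = eta_ka, eta_V2 = eta_V2,
    CL = typical$tvcl_nonnull * wcl * gfrac * sfac * exp(eta_CL),
    V1 = typical$tvv1 * wv * exp(eta_V1),
    Q = typical$tvq * wcl,
    V2 = typical$tvv2 * wv * exp(eta_V2),
    ka = typical$tvka * exp(eta_ka),
    stringsAsFactors = FALSE)
}

#' Export a cohort as CSV
#'
#' @param cohort A cohort data frame from [sample_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
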