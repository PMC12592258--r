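# Shared fixtures: example parameter sets and a memoized calibration so the
# expensive model fit runs once per test session.

# a generic two-compartment parameter set with a clear distribution phase
example_params <- function() {
  structural_params(CL = 5, V1 = 50, Q = 10, V2 = 100, ka = 1)
}

# a disposition shape similar to the calibrated model (slow terminal phase)
slow_params <- function(CL = 57.5) {
  structural_params(CL = CL, V1 = 60, Q = 43, V2 = 1660, ka = 0.10)
}

example_typical <- function(iiv = iiv_model()) {
  typical_model(tvcl_nonnull = 57.5, gstm1_cl_fraction = 0.561,
                tvv1 = 60, tvq = 43, tvv2 = 1660, tvka = 0.10, iiv = iiv)
}

.cache <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (is.null(.cache$cal)) .cache$cal <- calibrate_model(seed = 101)
  .cache$cal
}

cached_report <- function() {
  if (is.null(.cache$report))
    .cache$report <- run_paper_scenarios(cached_calibration(), n = 10000,
                                         seed = 202, keep_patients = TRUE)
  .cache$report
}

report_gm <- function(report, scenario, metric) {
  e <- report$exposure
  e$gm_mg_per_L[e$scenario == scenario & e$metric == metric]
}

report_cv <- function(report, scenario, metric) {
  e <- report$exposure
  e$cv_pct[e$scenario == scenario & e$metric == metric]
}

report_gmr <- function(report, scenario, metric) {
  g <- report$gmr
  g$gmr[g$scenario == scenario & g$metric == metric]
}
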