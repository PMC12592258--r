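# Calibration: closed-form inversions, disposition least squares,
# variance-component fit, and the full pipeline's self-consistency.

test_that("clearances invert from the average-concentration geometric means", {
  cl_nn <- clearances_from_caverage(240, 0.174)
  cl_null <- clearances_from_caverage(240, 0.310)
  expect_equal(cl_nn, 57.47, tolerance = 1e-4)
  expect_equal(cl_null, 32.26, tolerance = 1e-4)
  expect_equal(round(cl_nn / cl_null, 2), 1.78) # the genotype fold-change
  expect_error(clearances_from_caverage(0, 0.174), "positive")
})

test_that("clearance variability follows from the Caverage %CV in closed form", {
  om <- omega_cl_from_caverage_cv(0.425)
  expect_equal(om, sqrt(log(1 + 0.425^2) - 0.75^2 * log(1 + 0.2^2)),
               tolerance = 1e-12)
  expect_gt(om, 0.37) # consistent with ~37% reported clearance IIV
  expect_lt(om, 0.40)
  # no weight contribution: total variance is clearance variance
  expect_equal(omega_cl_from_caverage_cv(0.425, weight_cv = 0),
               sqrt(log(1 + 0.425^2)))
})

test_that("with clearance-only variability the Caverage CV matches theory", {
  om <- 0.38
  tm <- example_typical(iiv_model(omega_CL = om))
  coh <- sample_cohort(2e4, seed = 8, cov = covariate_model(weight_cv = 0),
                       genotype = "null", typical = tm)
  ca <- 240 / (coh$CL * 24)
  expect_equal(sd(ca) / mean(ca), sqrt(exp(om^2) - 1), tolerance = 0.02)
})

test_that("disposition fit recovers troughs generated by a known model", {
  truth <- list(V1 = 80, Q = 30, V2 = 3000, ka = 0.15)
  cl_nn <- 57.47; cl_null <- 32.26
  scen <- list(
    nonnull_240QD = list(CL = cl_nn, regimen = regimen_preset("240QD")),
    null_240QD = list(CL = cl_null, regimen = regimen_preset("240QD")),
    null_240QOD = list(CL = cl_null, regimen = regimen_preset("240QOD")))
  tg <- lapply(scen, function(s) {
    p <- structural_params(s$CL, truth$V1, truth$Q, truth$V2, truth$ka)
    exposure_metrics(p, s$regimen)$ctrough
  })
  fit <- fit_disposition(tg, scen, seed = 3, n_starts = 30)
  expect_true(fit$converged)
  expect_true(all(abs(fit$residuals) < 0.001)) # troughs reproduced to < 0.1%
  # and the fitted parameters predict the held-out 160 mg QD trough linearly
  pfit <- structural_params(cl_null, fit$tvv1, fit$tvq, fit$tvv2, fit$tvka)
  tr240 <- exposure_metrics(pfit, regimen_preset("240QD"))$ctrough
  tr160 <- exposure_metrics(pfit, regimen_preset("160QD"))$ctrough
  expect_equal(tr160, tr240 * 160 / 240, tolerance = 1e-10)
})

test_that("a one-compartment model cannot reproduce the published troughs", {
  cl_nn <- clearances_from_caverage(240, 0.174)
  cl_null <- clearances_from_caverage(240, 0.310)
  scen <- list(
    nonnull_240QD = list(CL = cl_nn, regimen = regimen_preset("240QD")),
    null_240QD = list(CL = cl_null, regimen = regimen_preset("240QD")),
    null_240QOD = list(CL = cl_null, regimen = regimen_preset("240QOD")))
  tg <- list(nonnull_240QD = 0.0962, null_240QD = 0.206, null_240QOD = 0.0864)
  fit1 <- fit_disposition(tg, scen, seed = 3, n_starts = 30,
                          one_compartment = TRUE)
  expect_false(fit1$converged)
  expect_gt(max(abs(fit1$residuals)), 0.02)
  # whereas the two-compartment fit succeeds on the same targets
  fit2 <- fit_disposition(tg, scen, seed = 3, n_starts = 30)
  expect_true(fit2$converged)
  expect_true(all(abs(fit2$residuals) < 0.001))
})

test_that("disposition fit and IIV fit are deterministic given their seeds", {
  cl_nn <- 57.47; cl_null <- 32.26
  scen <- list(
    nonnull_240QD = list(CL = cl_nn, genotype = "non-null",
                         regimen = regimen_preset("240QD")),
    null_240QD = list(CL = cl_null, genotype = "null",
                      regimen = regimen_preset("240QD")),
    null_240QOD = list(CL = cl_null, genotype = "null",
                       regimen = regimen_preset("240QOD")))
  tg <- list(nonnull_240QD = 0.0962, null_240QD = 0.206, null_240QOD = 0.0864)
  f1 <- fit_disposition(tg, scen, seed = 5, n_starts = 20)
  f2 <- fit_disposition(tg, scen, seed = 5, n_starts = 20)
  expect_identical(f1[c("tvv1", "tvq", "tvv2", "tvka")],
                   f2[c("tvv1", "tvq", "tvv2", "tvka")])
  tm <- typical_model(cl_nn, cl_null / cl_nn, f1$tvv1, f1$tvq, f1$tvv2,
                      f1$tvka, iiv = iiv_model(omega_CL = 0.379))
  cvt <- c(nonnull_240QD = 64.1, null_240QD = 56.2, null_240QOD = 64.0)
  g1 <- fit_iiv(tm, cvt, scen, n = 5000, seed = 9, cv_tol_pp = Inf)
  g2 <- fit_iiv(tm, cvt, scen, n = 5000, seed = 9, cv_tol_pp = Inf)
  expect_identical(g1$iiv, g2$iiv)
})

test_that("equal variance components give higher trough CV at higher clearance", {
  # the printed CV ordering (non-null 64.1% > null 56.2%) emerges from the
  # trough's nonlinearity in clearance, not from genotype-specific omegas
  tm <- example_typical(iiv_model(omega_CL = 0.379, omega_ka = 1.0))
  reg <- regimen_preset("240QD")
  cv_of <- function(genotype) {
    coh <- sample_cohort(2e4, seed = 13, genotype = genotype, typical = tm)
    tr <- cohort_exposures(coh, reg, grid_step = 0.5)$ctrough
    sd(tr) / mean(tr)
  }
  expect_gt(cv_of("non-null"), cv_of("null"))
})

test_that("targets file validation names the offending cell", {
  t0 <- utils::read.csv(system.file("extdata", "table1_targets.csv",
                                    package = "lazdose"))
  bad <- t0
  bad$gm_mg_per_L[3] <- -0.1
  path <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_targets(path), "row 3.*null_240QD")
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(t0[, -1], path2, row.names = FALSE)
  expect_error(read_targets(path2), "scenario")
})

test_that("full calibration converges and survives a JSON round-trip", {
  cal <- cached_calibration()
  expect_s3_class(cal, "calibration_result")
  expect_true(cal$diagnostics$converged)
  # fitted GM cells reproduced within 2% by the verification Monte Carlo
  fitted <- subset(cal$residuals,
                   (metric == "Ctrough" &
                      scenario %in% c("nonnull_240QD", "null_240QD",
                                      "null_240QOD")) |
                     (metric == "Caverage" &
                        scenario %in% c("nonnull_240QD", "null_240QD")))
  expect_true(all(abs(fitted$gm_rel_err) < 0.02))
  # trough %CVs within the documented 5-point band
  expect_true(all(abs(cal$diagnostics$iiv$cv_errors_pp) < 5))
  # clearance IIV consistent with the reported ~37%
  expect_equal(cal$typical$iiv$omega_CL, 0.37, tolerance = 0.1)
  path <- tempfile(fileext = ".json")
  write_model_json(cal, path)
  back <- read_model_json(path)
  expect_equal(back$tvcl_nonnull, cal$typical$tvcl_nonnull)
  expect_equal(back$iiv, cal$typical$iiv)
  expect_equal(back$tvv2, cal$typical$tvv2)
})

test_that("typical exposure ratios of the calibrated model match print", {
  cal <- cached_calibration()
  p_null <- individualize(cal$typical, 70, "null")
  m <- exposure_metrics(p_null, regimen_preset("240QD"))
  # typical null individual on the approved dose: trough/average ~ 0.206/0.310
  expect_equal(m$ctrough / m$caverage, 0.206 / 0.310, tolerance = 0.05)
})
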