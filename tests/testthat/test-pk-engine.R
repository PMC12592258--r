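# Closed-form engine: macro constants, single-dose curves, steady-state
# superposition, and their invariants.

test_that("macro constants define a curve that starts at zero and decays", {
  for (p in list(example_params(), slow_params(),
                 structural_params(CL = 20, V1 = 200, Q = 5, V2 = 500, ka = 0.5))) {
    mc <- macro_constants(p)
    expect_length(mc$lambda, 3L)
    expect_true(all(mc$lambda > 0))
    expect_equal(sum(mc$A), 0, tolerance = 1e-12)
    expect_equal(conc_single_dose(p, 0, 240), 0, tolerance = 1e-12)
  }
})

test_that("Q = 0 reduces to the two-term Bateman equation", {
  p <- structural_params(CL = 5, V1 = 50, Q = 0, V2 = 0, ka = 1)
  mc <- macro_constants(p)
  expect_length(mc$lambda, 2L)
  ke <- 5 / 50
  t <- seq(0.5, 96, by = 0.5)
  bateman <- 240 * 1 / (50 * (1 - ke)) * (exp(-ke * t) - exp(-1 * t))
  expect_equal(conc_single_dose(p, t, 240), bateman, tolerance = 1e-12)
})

test_that("two-compartment limit Q -> 0 converges to the one-compartment form", {
  p1 <- structural_params(CL = 5, V1 = 50, Q = 0, V2 = 0, ka = 1)
  p2 <- structural_params(CL = 5, V1 = 50, Q = 1e-9, V2 = 1e-9 * 100 / 5,
                          ka = 1)
  t <- seq(0, 96, by = 1)
  c1 <- conc_single_dose(p1, t, 240)
  c2 <- conc_single_dose(p2, t, 240)
  expect_lt(max(abs(c2 - c1)) / max(c1), 1e-6)
})

test_that("closed form agrees with numerical integration of the ODE system", {
  skip_if_not_installed("deSolve")
  for (p in list(example_params(), slow_params())) {
    rhs <- function(t, y, parms) {
      with(as.list(parms), {
        list(c(-ka * y[1],
               ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
               k12 * y[2] - k21 * y[3]))
      })
    }
    parms <- c(ka = p$ka, k10 = p$CL / p$V1, k12 = p$Q / p$V1,
               k21 = p$Q / p$V2)
    t <- seq(0, 336, by = 1)
    num <- deSolve::lsoda(c(240, 0, 0), t, rhs, parms,
                          rtol = 1e-12, atol = 1e-12)[, 3] / p$V1
    cf <- conc_single_dose(p, t, 240)
    expect_lt(max(abs(num - cf)) / max(cf), 1e-6)
  }
})

test_that("steady-state profile matches brute-force superposition of 200 doses", {
  p <- example_params() # terminal phase fast enough for 200 periods to converge
  reg <- regimen_preset("240QD")
  t_check <- c(3.7, 11.2, 23.9)
  brute <- sapply(t_check, function(tt) {
    sum(conc_single_dose(p, tt + 24 * (0:199), 240))
  })
  expect_equal(css_conc(p, reg, t_check), brute, tolerance = 1e-6)
})

test_that("steady-state profile is exactly periodic and dose-linear", {
  p <- slow_params()
  reg <- regimen(48, c(0, 24), c(80, 160), "alternating")
  t <- c(0, 0.31, 7.7, 23.9, 24, 29.5, 47.2)
  c0 <- css_conc(p, reg, t)
  expect_lt(max(abs(css_conc(p, reg, t + 48) - c0)) / max(c0), 1e-9)
  reg3 <- regimen(48, c(0, 24), 3 * c(80, 160), "scaled", tablets = NULL)
  expect_equal(css_conc(p, reg3, t), 3 * c0, tolerance = 1e-12)
})

test_that("css_profile covers the window and is non-negative", {
  prof <- css_profile(slow_params(), regimen_preset("240QOD"), window = 168,
                      grid_step = 0.25)
  expect_s3_class(prof, "concentration_grid")
  expect_equal(range(prof$time_h), c(0, 168))
  expect_true(all(prof$conc_mg_per_L >= 0))
  # pre-dose times are on the grid exactly
  expect_true(all(c(0, 48, 96, 144) %in% prof$time_h))
})

test_that("raising clearance strictly lowers trough and average", {
  reg <- regimen_preset("240QD")
  m_lo <- exposure_metrics(slow_params(CL = 30), reg)
  m_hi <- exposure_metrics(slow_params(CL = 60), reg)
  expect_lt(m_hi$ctrough, m_lo$ctrough)
  expect_lt(m_hi$caverage, m_lo$caverage)
})

test_that("every-other-day trough is below once-daily trough at equal dose", {
  p <- slow_params()
  tr_qd <- exposure_metrics(p, regimen_preset("240QD"))$ctrough
  tr_qod <- exposure_metrics(p, regimen_preset("240QOD"))$ctrough
  expect_lt(tr_qod, tr_qd)
})

test_that("ka colliding with an eigenvalue is perturbed with a warning", {
  p1 <- structural_params(CL = 5, V1 = 50, Q = 0, V2 = 0, ka = 5 / 50)
  expect_warning(mc <- macro_constants(p1), "perturbing ka")
  expect_true(all(is.finite(mc$A)))
  p2 <- example_params()
  al <- macro_constants(p2)$lambda[1]
  p2c <- structural_params(CL = p2$CL, V1 = p2$V1, Q = p2$Q, V2 = p2$V2, ka = al)
  expect_warning(mc2 <- macro_constants(p2c), "perturbing ka")
  expect_true(all(is.finite(mc2$A)))
})

test_that("parameter and regimen validation rejects bad input", {
  expect_error(structural_params(CL = -1, V1 = 50, ka = 1), "positive")
  expect_error(structural_params(CL = 1, V1 = 50, Q = 2, V2 = 0, ka = 1),
               "one-compartment")
  expect_error(regimen(0, 0, 240), "period")
  expect_error(regimen(24, numeric(0), numeric(0)), "dose event")
  expect_error(regimen(48, c(0, 0), c(80, 80)), "strictly increasing")
  expect_error(regimen(24, 25, 240), "0 <= t < period")
  expect_error(regimen(24, 0, 100), "not composable")
  expect_silent(regimen(24, 0, 160))  # 2 x 80 mg
  expect_silent(regimen(24, 0, 560))  # 240 + 4 x 80
})

test_that("regimen JSON config round-trips", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(period = 48,
                            events = data.frame(time = c(0, 24),
                                                amount = c(80, 160)),
                            label = "alternating"),
                       path, auto_unbox = TRUE)
  reg <- read_regimen(path)
  expect_equal(reg$period, 48)
  expect_equal(reg$amounts, c(80, 160))
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(period = 24), bad, auto_unbox = TRUE)
  expect_error(read_regimen(bad), "events")
})
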