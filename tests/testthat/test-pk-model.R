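test_that("single-dose concentration matches the Bateman solution properties", {
  p <- pk_params(ka = 0.447, cl = 4.459, v = 227)
  expect_equal(conc_single_dose(p, dose = 200, t = 0), 0)
  # linearity in dose
  t <- c(0.5, 2, 6.37, 24, 96)
  expect_equal(conc_single_dose(p, 400, t), 2 * conc_single_dose(p, 200, t))
})

test_that("single-dose concentration agrees with RK integration of the ODE system", {
  doses <- data.frame(time = 0, amt = 200)
  times <- c(0.5, 2, 6.37, 12, 24, 48, 96, 168)
  p <- pk_params(ka = 0.447, cl = 4.459, v = 227)
  expect_equal(conc_single_dose(p, 200, times),
               ode_conc_oracle(0.447, 4.459, 227, doses, times),
               tolerance = 1e-3)
  # randomised valid parameters
  set.seed(71)
  for (i in 1:5) {
    ka <- runif(1, 0.1, 2); cl <- runif(1, 1, 10); v <- runif(1, 50, 400)
    p <- pk_params(ka, cl, v)
    expect_equal(conc_single_dose(p, 200, times),
                 ode_conc_oracle(ka, cl, v, doses, times),
                 tolerance = 1e-3)
  }
})

test_that("degenerate equal absorption/elimination rates is rejected or handled", {
  p <- pk_params(ka = 0.02, cl = 0.02 * 227, v = 227)
  expect_error(conc_single_dose(p, 200, 10), "equal")
  expect_error(conc_steady_state(p, 200, 56, 10), "equal")
  # limit form agrees with the ODE oracle
  lim <- conc_single_dose(p, 200, c(5, 20, 50), equal_rates_limit = TRUE)
  ode <- ode_conc_oracle(0.02, 0.02 * 227, 227, data.frame(time = 0, amt = 200),
                         c(5, 20, 50))
  expect_equal(lim, ode, tolerance = 1e-3)
  # steady-state limit form agrees with long superposition of the limit form
  t_in <- c(0, 10, 30, 56)
  css <- conc_steady_state(p, 200, 56, t_in, equal_rates_limit = TRUE)
  sup <- vapply(t_in, function(tt) {
    sum(conc_single_dose(p, 200, tt + 56 * (0:400), equal_rates_limit = TRUE))
  }, numeric(1))
  expect_equal(css, sup, tolerance = 1e-6)
})

test_that("steady-state concentration reproduces published trough values", {
  cm <- covariate_model()
  p_aag30 <- pk_params(0.447, apply_covariates(cm, 30, FALSE), 227)
  expect_equal(conc_steady_state(p_aag30, 200, 56, 0), 0.460, tolerance = 5e-3)
  # periodic boundary: trough at t = 0 equals t = tau
  expect_equal(conc_steady_state(p_aag30, 200, 56, 56),
               conc_steady_state(p_aag30, 200, 56, 0))
  p_gg100 <- pk_params(0.447, apply_covariates(cm, 100, TRUE), 227)
  expect_equal(conc_steady_state(p_gg100, 200, 56, 0), 2.815, tolerance = 5e-3)
})

test_that("regimen superposition converges to the closed-form steady state", {
  p <- pk_params(0.447, 4.459, 227)
  # single dose event: identical to conc_single_dose
  r1 <- regimen(200, 0)
  tt <- c(1, 5, 20)
  expect_equal(conc_profile(p, r1, tt), conc_single_dose(p, 200, tt))
  expect_identical(conc_profile(p, r1, numeric(0)), numeric(0))
  # 200 mg every 56 h for 30 weeks, evaluated in the final interval
  n_dose <- 30 * 3
  r <- regimen(rep(200, n_dose), 56 * (0:(n_dose - 1)))
  t_final <- 56 * (n_dose - 1) + c(0.5, 6, 28, 55)
  sup <- conc_profile(p, r, t_final)
  css <- conc_steady_state(p, 200, 56, t_final - 56 * (n_dose - 1))
  expect_equal(sup, css, tolerance = 1e-3)
  # steady-state-flagged regimen delegates to the closed form
  rss <- regimen(200, 0, ss = TRUE, ii = 56)
  expect_equal(conc_profile(p, rss, c(3, 10)),
               conc_steady_state(p, 200, 56, c(3, 10)))
})

test_that("covariate model reproduces the published clearance relationships", {
  cm <- covariate_model()
  expect_equal(apply_covariates(cm, 28.9, FALSE), 4.54, tolerance = 1e-12)
  expect_equal(apply_covariates(cm, 10, FALSE), 600 / 79.746, tolerance = 1e-4)
  expect_equal(apply_covariates(cm, 100, TRUE), 600 / 538.383, tolerance = 1e-4)
  # strictly decreasing in GGT; GG below A/AG at equal GGT
  g <- seq(10, 200, by = 5)
  cl <- apply_covariates(cm, g, FALSE)
  expect_true(all(diff(cl) < 0))
  expect_true(all(apply_covariates(cm, g, TRUE) < cl))
  expect_error(apply_covariates(cm, 1e6, TRUE), "non-positive")
  expect_error(apply_covariates(cm, -5, FALSE), "positive")
})

test_that("exposure metrics agree with published values and numeric integration", {
  cm <- covariate_model()
  p <- pk_params(0.447, apply_covariates(cm, 30, FALSE), 227)
  em <- exposure_metrics(p, dose = 200, tau = 56)
  expect_equal(em$auc_weekly_ss, 134.529, tolerance = 5e-3)
  expect_equal(em$cmax_ss, 1.165, tolerance = 5e-3)
  expect_equal(em$cmin_ss, 0.460, tolerance = 5e-3)
  # peak is the max over a fine grid
  tg <- seq(0, 56, by = 1 / 60)
  cg <- conc_steady_state(p, 200, 56, tg)
  expect_equal(em$cmax_ss, max(cg), tolerance = 1e-6)
  expect_equal(em$tmax_ss, tg[which.max(cg)], tolerance = 1e-2)
  # analytic weekly AUC against trapezoidal integration at 1-minute resolution
  tw <- seq(0, 168, by = 1 / 60)
  cw <- conc_steady_state(p, 200, 56, tw %% 56)
  auc_num <- sum(diff(tw) * (head(cw, -1) + tail(cw, -1)) / 2)
  expect_equal(em$auc_weekly_ss, auc_num, tolerance = 5e-3)
  # AUC halves exactly when clearance doubles
  p2 <- pk_params(0.447, 2 * p$cl, 227)
  expect_equal(exposure_metrics(p2, 200, 56)$auc_weekly_ss,
               em$auc_weekly_ss / 2)
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_params(0, 4, 227))
  expect_error(pk_params(0.4, -1, 227))
  expect_error(regimen(-200, 0), "positive")
  expect_error(regimen(200, 0, ss = TRUE), "ii")
  expect_error(regimen(c(200, 200), c(5, 0)), "non-decreasing")
})
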