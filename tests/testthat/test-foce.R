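test_that("conditional -2LL matches a direct density computation", {
  m <- bdq_final_model()
  d <- one_subject_data(times = c(6, 30), dv = c(1.1, 0.6))
  eta <- c(0.3, -0.2)
  # direct computation written out independently
  p_i <- pk_params(0.447 * 1, 4.54 * exp(eta[1]), 227 * exp(eta[2]))
  f <- conc_steady_state(p_i, 200, 56, c(6, 30))
  g <- f^2 * 0.322^2
  direct <- sum(log(2 * pi * g) + (c(1.1, 0.6) - f)^2 / g) +
    2 * log(2 * pi) + log(0.387^2) + log(0.835^2) +
    eta[1]^2 / 0.387^2 + eta[2]^2 / 0.835^2
  expect_equal(conditional_m2ll(d, m, eta), direct, tolerance = 1e-10)
})

test_that("conditional -2LL increases as an observation moves off its prediction", {
  m <- bdq_final_model()
  p <- pk_params(0.447, 4.54, 227)
  f1 <- conc_steady_state(p, 200, 56, 6)
  vals <- vapply(c(0, 0.2, 0.5, 1), function(shift) {
    conditional_m2ll(one_subject_data(6, f1 + shift), m, c(0, 0))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # at the exact prediction with eta = 0, only normalisation terms remain
  g1 <- f1^2 * 0.322^2
  norm_only <- log(2 * pi * g1) + 2 * log(2 * pi) +
    log(0.387^2) + log(0.835^2)
  expect_equal(conditional_m2ll(one_subject_data(6, f1), m, c(0, 0)),
               norm_only, tolerance = 1e-10)
})

test_that("FOCE objective matches adaptive Gauss-Hermite quadrature", {
  m <- bdq_final_model()
  omega <- c(0.387^2, 0.835^2)
  cases <- list(
    list(times = 6.4, dv = 1.3),
    list(times = c(6.4, 40), dv = c(1.3, 0.5)),
    list(times = c(2, 50), dv = c(0.35, 0.62))
  )
  for (cs in cases) {
    d <- one_subject_data(cs$times, cs$dv)
    ofv <- as.numeric(foce_objective(d, m))
    loglik <- function(eta) {
      p_i <- pk_params(0.447, 4.54 * exp(eta[1]), 227 * exp(eta[2]))
      f <- conc_steady_state(p_i, 200, 56, cs$times)
      g <- f^2 * 0.322^2
      sum(stats::dnorm(cs$dv, f, sqrt(g), log = TRUE))
    }
    exact <- aghq_m2ll_oracle(loglik, omega)
    expect_lt(abs(ofv - exact), 0.5)
  }
})

test_that("vanishing IIV pins etas at zero and recovers the fixed-effects -2LL", {
  m <- population_model(theta = c(ka = 0.447, cl = 4.54, v = 227),
                        omega = c(cl = 1e-8, v = 1e-8),
                        sigma = c(prop = 0.322, add = 0))
  times <- c(6, 30); dv <- c(1.2, 0.55)
  d <- one_subject_data(times, dv)
  p <- pk_params(0.447, 4.54, 227)
  f <- conc_steady_state(p, 200, 56, times)
  g <- f^2 * 0.322^2
  fixed_m2ll <- sum(log(2 * pi * g) + (dv - f)^2 / g)
  expect_equal(as.numeric(foce_objective(d, m)), fixed_m2ll, tolerance = 1e-4)
})

test_that("fit is invariant to subject ordering", {
  d <- simulate_pk_dataset(small_design(30), seed = 301)
  d <- suppressMessages(impute_missing(d, c("GGT", "rs319952")))
  ids <- unique(d$ID)
  set.seed(1)
  perm <- sample(ids)
  d_perm <- d[order(match(d$ID, perm), d$TIME), ]
  ctl <- foce_control(rel_tol = 1e-7, nm_iter = 100L, max_cycles = 2L)
  f1 <- pk_fit(d, bdq_final_model(), se = FALSE, control = ctl)
  f2 <- pk_fit(d_perm, bdq_final_model(), se = FALSE, control = ctl)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-5)
  expect_equal(f1$params$estimate, f2$params$estimate, tolerance = 1e-3)
})

test_that("adding an unpenalised parameter never increases the minimised OFV", {
  d <- simulate_pk_dataset(small_design(40), seed = 77)
  d <- suppressMessages(impute_missing(d, c("GGT", "rs319952")))
  ctl <- foce_control(inner_tol = 1e-7, rel_tol = 1e-6, nm_iter = 100L,
                      max_cycles = 2L)
  base <- pk_fit(d, bdq_base_model(), se = FALSE, control = ctl)
  bigger <- bdq_base_model()
  bigger$covariate_effects <- list(
    cov_effect("cl", "GGT", "power", value = 0, reference = 28.9))
  full <- pk_fit(d, bigger, se = FALSE, control = ctl)
  expect_lte(full$ofv, base$ofv + 1e-6)
})

test_that("diagnostics are calibrated when the model generated the data", {
  d <- simulate_pk_dataset(seed = 88)
  d <- suppressMessages(impute_missing(d, c("GGT", "rs319952")))
  fit <- pk_fit(d, bdq_final_model(), se = FALSE,
                control = foce_control(inner_tol = 1e-7, rel_tol = 1e-6,
                                       nm_iter = 100L, max_cycles = 2L))
  expect_true(fit$converged)
  aug <- augment(fit)
  expect_equal(nrow(aug), 246)
  expect_lt(abs(mean(aug$CWRES)), 0.1)
  expect_gt(sd(aug$CWRES), 0.85)
  expect_lt(sd(aug$CWRES), 1.15)
  # shrinkage is reported within [0, 100] and positive under sparse sampling
  expect_true(all(fit$shrinkage$shrinkage_pct > 0))
  expect_true(all(fit$shrinkage$shrinkage_pct < 100))
  # broom-style accessors
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "se", "rse") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n_obs, 246L)
})

test_that("eta shrinkage grows as sampling gets sparser", {
  rich <- study_design(n_subjects = 40,
                       samples_per_subject = c(`6` = 40), lod = 0.024)
  sparse <- study_design(n_subjects = 40,
                         samples_per_subject = c(`1` = 40), lod = 0.024)
  m <- bdq_final_model()
  d_rich <- suppressMessages(impute_missing(
    simulate_pk_dataset(rich, m, seed = 55), c("GGT", "rs319952")))
  d_sparse <- suppressMessages(impute_missing(
    simulate_pk_dataset(sparse, m, seed = 55), c("GGT", "rs319952")))
  ctl <- foce_control(inner_tol = 1e-7, rel_tol = 1e-6, nm_iter = 100L,
                      max_cycles = 2L)
  f_rich <- pk_fit(d_rich, m, se = FALSE, control = ctl)
  f_sparse <- pk_fit(d_sparse, m, se = FALSE, control = ctl)
  shr_rich <- f_rich$shrinkage$shrinkage_pct[f_rich$shrinkage$component == "eta_cl"]
  shr_sparse <- f_sparse$shrinkage$shrinkage_pct[f_sparse$shrinkage$component == "eta_cl"]
  expect_gt(shr_sparse, shr_rich)
})
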