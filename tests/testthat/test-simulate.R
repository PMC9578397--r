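test_that("default design reproduces the study sampling marginals exactly", {
  for (seed in c(1, 99, 20201001)) {
    d <- simulate_pk_dataset(seed = seed)
    expect_identical(length(unique(d$ID)), 99L)
    obs <- d[d$EVID == 0, ]
    expect_identical(nrow(obs), 246L)
    per_subj <- table(table(obs$ID))
    expect_identical(as.integer(per_subj[as.character(1:8)]),
                     c(38L, 24L, 12L, 11L, 7L, 5L, 1L, 1L))
    # dosing rows carry the steady-state fields
    doses <- d[d$EVID == 1, ]
    expect_true(all(doses$SS == 1 & doses$II == 56 & doses$AMT == 200))
    expect_true(all(obs$TIME >= 0 & obs$TIME <= 56))
  }
})

test_that("simulated covariates match the study distributions", {
  ggt_means <- gg_freq <- numeric(30)
  for (r in 1:30) {
    cov <- simulate_covariates(seed = 5000 + r)
    ggt_means[r] <- mean(cov$GGT)
    cmp <- attr(cov, "complete")
    gg_freq[r] <- mean(cmp$rs319952 == "GG")
  }
  expect_lt(abs(mean(ggt_means) - 36.4), 5)
  expect_lt(abs(mean(gg_freq) - 0.1313), 0.03)
  # ranges respected
  cov <- simulate_covariates(seed = 17)
  tab <- table1_reference()
  for (i in seq_len(nrow(tab))) {
    x <- cov[[tab$name[i]]]
    expect_true(all(x >= tab$min[i] & x <= tab$max[i]))
  }
  # observed genotypes carry missingness; complete ones do not
  expect_gt(sum(is.na(cov$rs319952)), 0)
  expect_false(anyNA(attr(cov, "complete")$rs319952))
})

test_that("noise-free simulation returns the typical steady-state predictions", {
  des <- small_design(40)
  d <- simulate_pk_dataset(des, seed = 9, simulate_iiv = FALSE,
                           simulate_residual = FALSE)
  truth <- attr(d, "truth")
  obs <- d[d$EVID == 0, ]
  typ <- typical_parameters(truth$covariates[match(obs$ID,
                                                   truth$covariates$ID), ],
                            truth$model)
  pred <- vapply(seq_len(nrow(obs)), function(i) {
    conc_steady_state(pk_params(typ$ka[i], typ$cl[i], typ$v[i]), 200, 56,
                      obs$TIME[i])
  }, numeric(1))
  expect_equal(obs$DV, pred, tolerance = 1e-12)
})

test_that("sub-detection-limit draws are substituted with the limit value", {
  # inflate residual noise so the substitution path is exercised
  noisy <- population_model(sigma = c(prop = 0.9, add = 0),
                            covariate_effects = bdq_final_model()$covariate_effects)
  d <- simulate_pk_dataset(model = noisy, seed = 31)
  obs <- d[d$EVID == 0, ]
  expect_gt(sum(obs$BLQ), 0)
  expect_true(all(obs$DV >= 0.024))
  expect_true(all(obs$DV[obs$BLQ] == 0.024))
  # at the reference noise level sub-LOD draws are rare
  d0 <- simulate_pk_dataset(seed = 31)
  expect_lt(sum(d0$BLQ[d0$EVID == 0]), 10)
})

test_that("simulation truth round-trips through the dataset attributes", {
  d <- simulate_pk_dataset(seed = 12)
  truth <- attr(d, "truth")
  expect_identical(nrow(truth$etas), 99L)
  expect_true(all(c("eta_cl", "eta_v") %in% names(truth$etas)))
  expect_false(anyNA(truth$covariates$rs319952))
  expect_identical(truth$seed, 12)
})

test_that("datasets round-trip through CSV and are validated on read", {
  d <- simulate_pk_dataset(small_design(30), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(d, path)
  d2 <- read_pk_dataset(path)
  expect_equal(d2$DV[d2$EVID == 0], d$DV[d$EVID == 0])
  expect_equal(d2$GGT, d$GGT)
  expect_identical(d2$rs319952, d$rs319952)

  # a minimal valid two-row file parses
  mini <- tibble::tibble(ID = 1, TIME = c(0, 6), EVID = c(1, 0),
                         AMT = c(200, NA), SS = c(1, 0), II = c(56, 0),
                         DV = c(NA, 1.2))
  write_pk_dataset(mini, path)
  expect_silent(read_pk_dataset(path))

  # informative errors name the offending rows/columns
  bad <- mini; bad$DV[2] <- NA
  expect_error(write_pk_dataset(bad, path), "DV missing on observation row")
  bad2 <- mini; bad2$II[1] <- 0
  expect_error(write_pk_dataset(bad2, path), "II > 0")
  nofile <- tibble::tibble(ID = 1, TIME = 0)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(nofile, p2, row.names = FALSE)
  expect_error(read_pk_dataset(p2), "missing required column")

  # within-subject covariate consistency is enforced
  incons <- simulate_pk_dataset(small_design(30), seed = 3)
  incons$GGT[2] <- incons$GGT[2] + 1
  expect_error(write_pk_dataset(incons, path), "varies within subject")
})
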