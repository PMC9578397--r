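# Independent numerical oracles used by the tests; they never call the
# package's closed-form or Laplacian code paths they are meant to check.

# Runge-Kutta integration of the two-state absorption/disposition ODE system:
#   dA_gut/dt = -ka * A_gut;  dA_c/dt = ka * A_gut - ke * A_c
# with bolus doses added to the gut compartment. Returns central
# concentrations at `times` (must include 0 in the dose schedule span).
ode_conc_oracle <- function(ka, cl, v, doses, times) {
  ke <- cl / v
  rhs <- function(t, y, parms) {
    list(c(-ka * y[1], ka * y[1] - ke * y[2]))
  }
  events <- data.frame(var = "gut", time = doses$time, value = doses$amt,
                       method = "add")
  t_all <- sort(unique(c(0, doses$time, times)))
  out <- deSolve::lsoda(c(gut = 0, central = 0), t_all, rhs, parms = NULL,
                        events = list(data = events),
                        rtol = 1e-10, atol = 1e-12)
  conc <- out[match(times, out[, "time"]), "central"] / v
  unname(conc)
}

# Exact marginal -2 log-likelihood of one subject's observations by adaptive
# Gauss-Hermite quadrature (tensor product over the eta dimensions), centred
# and scaled at the conditional mode found by direct grid+optim search.
# `loglik(eta)` must return the log of p(y | eta); the eta prior is normal
# with diagonal variances `omega`.
aghq_m2ll_oracle <- function(loglik, omega, n_nodes = 41) {
  k <- length(omega)
  neg_joint <- function(eta) {
    -loglik(eta) + 0.5 * sum(eta^2 / omega) +
      0.5 * sum(log(2 * pi * omega))
  }
  opt <- stats::optim(rep(0, k), neg_joint, method = "BFGS",
                      hessian = TRUE, control = list(reltol = 1e-12))
  mode <- opt$par
  Hch <- chol(solve(opt$hessian))
  gh <- pracma::gaussHermite(n_nodes)
  grids <- replicate(k, seq_len(n_nodes), simplify = FALSE)
  idx <- as.matrix(expand.grid(grids))
  total <- 0
  for (r in seq_len(nrow(idx))) {
    z <- gh$x[idx[r, ]]
    w <- prod(gh$w[idx[r, ]])
    eta <- mode + sqrt(2) * as.numeric(t(Hch) %*% z)
    total <- total + w * exp(-neg_joint(eta) + sum(z^2))
  }
  log_int <- log(total) + 0.5 * log(det(2 * solve(opt$hessian)))
  -2 * log_int
}

# Minimal single-subject dataset at steady state, as a plain tibble.
one_subject_data <- function(times, dv, ggt = 28.9, geno = "AA",
                             dose = 200, tau = 56, id = 1) {
  dplyr::bind_rows(
    tibble::tibble(ID = id, TIME = 0, EVID = 1, AMT = dose, SS = 1, II = tau,
                   DV = NA_real_, GGT = ggt, rs319952 = geno),
    tibble::tibble(ID = id, TIME = times, EVID = 0, AMT = NA_real_, SS = 0,
                   II = 0, DV = dv, GGT = ggt, rs319952 = geno)
  )
}

# Small-sample study design used to keep replicate-heavy tests fast.
small_design <- function(n = 40) {
  study_design(n_subjects = n,
               samples_per_subject = stats::setNames(
                 c(n - 25, 10, 10, 5), c("1", "2", "3", "4")))
}
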