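#' Control settings for the FOCE estimation engine
#'
#' @param inner_tol Gradient-norm tolerance for the per-subject eta mode search.
#' @param inner_max_iter Maximum Newton iterations of the inner search.
#' @param fd_h Finite-difference step for eta derivatives.
#' @param rel_tol Relative tolerance of the outer minimisation.
#' @param iter_max Maximum outer iterations.
#' @param grad_tol Outer-gradient bound (OFV units per log-parameter unit)
#'   under which a stop reported as "false convergence" is accepted.
#' @param nm_iter Iteration budget of the derivative-free verification pass.
#' @param max_cycles Maximum gradient-search / verification cycles.
#' @return A list of class `foce_control`.
#' @export
foce_control <- function(inner_tol = 1e-8, inner_max_iter = 200L, fd_h = 1e-4,
                         rel_tol = 1e-8, iter_max = 300L, grad_tol = 0.5,
                         nm_iter = 400L, max_cycles = 4L) {
  structure(list(inner_tol = inner_tol, inner_max_iter = inner_max_iter,
                 fd_h = fd_h, rel_tol = rel_tol, iter_max = iter_max,
                 grad_tol = grad_tol, nm_iter = nm_iter,
                 max_cycles = max_cycles),
            class = "foce_control")
}

.dataset_cols <- c("ID", "TIME", "EVID", "AMT", "SS", "II", "DV")

# Internal estimation layout: observation vector, subject index, and an
# (observation x dose) pair table so predictions are one vectorised pass.
.prepare_data <- function(data, model = NULL) {
  .validate_dataset(data)
  ids <- unique(data$ID)
  n_subj <- length(ids)
  sidx <- match(data$ID, ids)
  cov_cols <- setdiff(names(data), c(.dataset_cols, "BLQ"))
  cov <- data[!duplicated(data$ID), c("ID", cov_cols), drop = FALSE]
  cov <- tibble::as_tibble(cov)

  obs <- which(data$EVID == 0)
  if (!length(obs)) stop("dataset contains no observation rows", call. = FALSE)
  po <- integer(0); ps <- integer(0); pa <- pt <- ptau <- numeric(0); pss <- logical(0)
  for (s in seq_len(n_subj)) {
    rows <- which(sidx == s)
    drows <- rows[data$EVID[rows] == 1]
    orows <- rows[data$EVID[rows] == 0]
    if (!length(drows)) stop("subject ", ids[s], " has no dose records", call. = FALSE)
    dtime <- data$TIME[drows]; dss <- data$SS[drows] == 1
    for (o in orows) {
      prior <- drows[dtime <= data$TIME[o]]
      if (!length(prior)) {
        stop("observation at row ", o, " precedes all doses for subject ", ids[s],
             call. = FALSE)
      }
      pss_prior <- data$SS[prior] == 1
      # a steady-state dose resets history: keep the last SS dose and any
      # later non-SS doses
      if (any(pss_prior)) prior <- prior[seq(max(which(pss_prior)), length(prior))]
      oi <- match(o, obs)
      po <- c(po, rep.int(oi, length(prior)))
      ps <- c(ps, rep.int(s, length(prior)))
      pa <- c(pa, data$AMT[prior])
      pt <- c(pt, data$TIME[o] - data$TIME[prior])
      pss <- c(pss, data$SS[prior] == 1)
      ptau <- c(ptau, data$II[prior])
    }
  }
  subj_obs <- sidx[obs]
  # fast paths: one dose pair per observation, observations grouped by subject
  simple_pairs <- identical(po, seq_along(obs))
  subj_ends <- if (!is.unsorted(subj_obs)) cumsum(tabulate(subj_obs, n_subj))
               else NULL
  list(y = data$DV[obs], n_obs = length(obs), obs_rows = obs,
       subj = subj_obs, n_subj = n_subj, ids = ids,
       time = data$TIME[obs],
       pairs = list(obs = po, subj = ps, amt = pa, dt = pt, ss = pss, tau = ptau),
       simple_pairs = simple_pairs, subj_ends = subj_ends,
       cov = cov)
}

# Vectorised one-compartment kernel over (obs, dose) pairs.
.conc_kernel <- function(ka, ke, v, amt, dt, ss, tau) {
  out <- numeric(length(ka))
  i <- !ss
  if (any(i)) {
    out[i] <- amt[i] * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * dt[i]) - exp(-ka[i] * dt[i]))
  }
  if (any(ss)) {
    t0 <- dt[ss] %% tau[ss]
    kas <- ka[ss]; kes <- ke[ss]; taus <- tau[ss]
    out[ss] <- amt[ss] * kas / (v[ss] * (kas - kes)) *
      (exp(-kes * t0) / (1 - exp(-kes * taus)) -
         exp(-kas * t0) / (1 - exp(-kas * taus)))
  }
  out
}

.predict_conc <- function(prep, ka_s, cl_s, v_s) {
  pr <- prep$pairs
  ka <- ka_s[pr$subj]; cl <- cl_s[pr$subj]; v <- v_s[pr$subj]
  contrib <- .conc_kernel(ka, cl / v, v, pr$amt, pr$dt, pr$ss, pr$tau)
  if (prep$simple_pairs) return(contrib)
  f <- numeric(prep$n_obs)
  agg <- rowsum(contrib, pr$obs, reorder = FALSE)
  f[as.integer(rownames(agg))] <- agg[, 1]
  f
}

# per-subject sums of an observation-level vector
.subject_sum <- function(prep, x) {
  if (!is.null(prep$subj_ends)) {
    cs <- cumsum(x)[prep$subj_ends]
    return(diff(c(0, cs)))
  }
  s <- numeric(prep$n_subj)
  agg <- rowsum(x, prep$subj, reorder = FALSE)
  s[as.integer(rownames(agg))] <- agg[, 1]
  s
}

.scale_params <- function(typ, model, E) {
  sc <- typ
  on <- names(model$omega)
  for (j in seq_along(on)) sc[[on[j]]] <- sc[[on[j]]] * exp(E[, j])
  sc
}

# Per-subject conditional -2 log joint density of (observations, eta):
#   sum_j [log 2*pi*g_j + (y_j - f_j)^2 / g_j] + k log 2*pi + log|Omega|
#   + eta' Omega^-1 eta
.subject_m2ll_vec <- function(prep, model, typ, E) {
  sc <- .scale_params(typ, model, E)
  f <- .predict_conc(prep, sc$ka, sc$cl, sc$v)
  g <- switch(model$residual,
              additive     = rep_len(model$sigma[["add"]]^2, length(f)),
              proportional = f^2 * model$sigma[["prop"]]^2,
              combined     = f^2 * model$sigma[["prop"]]^2 + model$sigma[["add"]]^2)
  bad <- !is.finite(f) | g <= 0
  term <- if (any(bad)) {
    tm <- rep_len(Inf, length(f))
    tm[!bad] <- log(2 * pi * g[!bad]) + (prep$y[!bad] - f[!bad])^2 / g[!bad]
    tm
  } else {
    log(2 * pi * g) + (prep$y - f)^2 / g
  }
  s <- .subject_sum(prep, term)
  om <- model$omega
  k <- length(om)
  prior <- k * log(2 * pi) + sum(log(om)) +
    as.numeric(E^2 %*% (1 / om))
  s + prior
}

# Vectorised-across-subjects Levenberg-Marquardt search for the eta modes.
# Gradients and Hessians of the conditional -2LL are analytic when the
# random effects act on clearance/volume (the usual case) and otherwise come
# from a finite-difference stencil. Each subject carries its own damping,
# raised until its step improves. Returns the modes, their conditional -2LL,
# the per-subject Hessians, and (analytic case) the prediction sensitivities.
.inner_solve <- function(prep, model, typ, E0, control) {
  n <- nrow(E0); k <- ncol(E0); h <- control$fd_h
  analytic <- all(names(model$omega) %in% c("cl", "v"))
  fl <- function(E) .subject_m2ll_vec(prep, model, typ, E)
  E <- E0
  l <- fl(E)
  if (any(!is.finite(l))) { E <- matrix(0, n, k); l <- fl(E) }
  # conditional surfaces can be multimodal, and a descent from a single
  # start captures basins chaotically as the parameters move; seed each
  # subject at the best point of a fixed coarse eta grid (evaluated in a
  # handful of vectorised passes) so the global basin is found reproducibly
  sd_eta <- sqrt(unlist(model$omega))
  grid_pts <- expand.grid(rep(list(c(-2.5, 0, 2.5)), k))
  for (gi in seq_len(nrow(grid_pts))) {
    if (all(grid_pts[gi, ] == 0)) next
    Eg <- matrix(rep(as.numeric(grid_pts[gi, ]) * sd_eta, each = n), n, k)
    lg <- fl(Eg)
    better <- is.finite(lg) & lg < l
    E[better, ] <- Eg[better, , drop = FALSE]
    l[better] <- lg[better]
  }
  G <- matrix(0, n, k)
  H <- array(0, c(k, k, n))
  A <- NULL
  lambda <- rep(1e-3, n)
  # a subject is done when its gradient is small or when no damped step can
  # improve it any further (stagnation at the numerical optimum; absolute
  # gradient tolerances are unreachable at very sharply curved modes)
  stagnant <- rep(FALSE, n)
  for (it in seq_len(control$inner_max_iter)) {
    if (analytic) {
      de <- .inner_derivs(prep, model, typ, E)
      G <- de$G; H <- de$H; A <- de$A
      l <- de$l
    } else {
      lp <- lm_ <- matrix(0, n, k)
      for (j in seq_len(k)) {
        Ep <- E; Ep[, j] <- Ep[, j] + h; lp[, j] <- fl(Ep)
        Em <- E; Em[, j] <- Em[, j] - h; lm_[, j] <- fl(Em)
      }
      G <- (lp - lm_) / (2 * h)
      for (j in seq_len(k)) H[j, j, ] <- (lp[, j] - 2 * l + lm_[, j]) / h^2
      if (k > 1) {
        for (j1 in seq_len(k - 1)) for (j2 in seq((j1 + 1), k)) {
          Epp <- E; Epp[, j1] <- Epp[, j1] + h; Epp[, j2] <- Epp[, j2] + h
          Epm <- E; Epm[, j1] <- Epm[, j1] + h; Epm[, j2] <- Epm[, j2] - h
          Emp <- E; Emp[, j1] <- Emp[, j1] - h; Emp[, j2] <- Emp[, j2] + h
          Emm <- E; Emm[, j1] <- Emm[, j1] - h; Emm[, j2] <- Emm[, j2] - h
          cr <- (fl(Epp) - fl(Epm) - fl(Emp) + fl(Emm)) / (4 * h^2)
          H[j1, j2, ] <- H[j2, j1, ] <- cr
        }
      }
    }
    active <- rowSums(abs(G) >= control$inner_tol) > 0 & !stagnant
    if (!any(active)) break
    need <- active
    for (attempt in 1:20) {
      D <- .lm_step(H, G, lambda, k)
      E1 <- E + D * need
      l1 <- fl(E1)
      acc <- need & is.finite(l1) & l1 <= l + 1e-10
      E[acc, ] <- E1[acc, , drop = FALSE]
      l[acc] <- l1[acc]
      lambda[acc] <- pmax(lambda[acc] / 3, 1e-6)
      need <- need & !acc
      if (!any(need)) break
      lambda[need] <- lambda[need] * 10
    }
    stagnant[need] <- TRUE
  }
  list(eta = E, l = l, H = H, grad = G, stagnant = stagnant, A = A)
}

# Damped Newton directions -(H + lambda I)^{-1} G per subject, vectorised for
# the 1- and 2-eta cases; the damping is raised where H + lambda I is not
# positive definite.
# Analytic value, eta-gradient and eta-Hessian of the per-subject
# conditional -2LL when the random effects act on clearance and/or volume.
# With F the predicted concentration, eta_cl and eta_v derivatives reduce to
#   dF/d(eta_cl) = F_c,  dF/d(eta_v) = -F - F_c,
#   F_cc as below, F_cd = -F_c - F_cc, F_dd = F + 2 F_c + F_cc,
# so one pass yields everything the mode search and the FOCE linearisation
# need. Identities hold per dose contribution and are linear, hence survive
# superposition.
.inner_derivs <- function(prep, model, typ, E) {
  on <- names(model$omega)
  k <- length(on)
  sc <- .scale_params(typ, model, E)
  pr <- prep$pairs
  ka <- sc$ka[pr$subj]; cl <- sc$cl[pr$subj]; v <- sc$v[pr$subj]
  ke <- cl / v
  q <- 1 / (ka - ke)
  P <- pr$amt * ka / v
  t0 <- ifelse(pr$ss, pr$dt %% pr$tau, pr$dt)
  if (any(pr$ss)) {
    b <- ifelse(pr$ss, exp(-ke * pr$tau), 0)
    sgeo <- 1 / (1 - b)
    u <- exp(-ke * t0) * sgeo
    wden <- ifelse(pr$ss, 1 - exp(-ka * pr$tau), 1)
    w <- exp(-ka * t0) / wden
    tb <- t0 + pr$tau * b * sgeo
    tb[!pr$ss] <- t0[!pr$ss]
    up <- -u * tb
    upp <- u * tb^2 + ifelse(pr$ss, u * pr$tau^2 * b * sgeo * (1 + b * sgeo), 0)
  } else {
    u <- exp(-ke * t0); w <- exp(-ka * t0)
    up <- -t0 * u; upp <- t0^2 * u
  }
  duw <- u - w
  f_pair <- P * q * duw
  gke1 <- P * (q^2 * duw + q * up)
  gke2 <- P * (2 * q^3 * duw + 2 * q^2 * up + q * upp)
  fc_pair <- ke * gke1
  fcc_pair <- fc_pair + ke^2 * gke2

  agg <- function(x) {
    if (prep$simple_pairs) return(x)
    out <- numeric(prep$n_obs)
    a <- rowsum(x, pr$obs, reorder = FALSE)
    out[as.integer(rownames(a))] <- a[, 1]
    out
  }
  f <- agg(f_pair); fc <- agg(fc_pair); fcc <- agg(fcc_pair)
  fd <- -f - fc; fcd <- -fc - fcc; fdd <- f + 2 * fc + fcc

  sp2 <- if (model$residual %in% c("proportional", "combined"))
    model$sigma[["prop"]]^2 else 0
  sa2 <- if (model$residual %in% c("additive", "combined"))
    model$sigma[["add"]]^2 else 0
  g <- sp2 * f^2 + sa2
  r <- prep$y - f
  bad <- !is.finite(f) | g <= 0
  gp <- 2 * sp2 * f
  gpp <- 2 * sp2
  t0v <- log(2 * pi * g) + r^2 / g
  t1v <- gp / g - 2 * r / g - r^2 * gp / g^2
  t2v <- (gpp * g - gp^2) / g^2 + 2 / g + 4 * r * gp / g^2 -
    r^2 * gpp / g^2 + 2 * r^2 * gp^2 / g^3
  if (any(bad)) { t0v[bad] <- Inf; t1v[bad] <- 0; t2v[bad] <- 0 }

  dmap <- list(cl = fc, v = fd)
  d2map <- list(cl = list(cl = fcc, v = fcd), v = list(cl = fcd, v = fdd))
  om <- model$omega
  l <- .subject_sum(prep, t0v) + k * log(2 * pi) + sum(log(om)) +
    as.numeric(E^2 %*% (1 / om))
  G <- matrix(0, prep$n_subj, k)
  H <- array(0, c(k, k, prep$n_subj))
  for (j in seq_len(k)) {
    Fj <- dmap[[on[j]]]
    G[, j] <- .subject_sum(prep, t1v * Fj) + 2 * E[, j] / om[[j]]
    for (j2 in j:k) {
      Fj2 <- dmap[[on[j2]]]
      hj <- .subject_sum(prep, t2v * Fj * Fj2 + t1v * d2map[[on[j]]][[on[j2]]])
      if (j == j2) hj <- hj + 2 / om[[j]]
      H[j, j2, ] <- H[j2, j, ] <- hj
    }
  }
  A <- matrix(0, prep$n_obs, k)
  for (j in seq_len(k)) A[, j] <- dmap[[on[j]]]
  list(l = l, G = G, H = H, f = f, A = A)
}

# Conditional surfaces can be multimodal (the steady-state concentration is
# non-monotone in the volume), so the search must stay a conservative local
# descent from its start: damping grows tenfold until each block is positive
# definite, and steps are capped, which keeps every subject in the basin it
# started in rather than hopping into spurious narrow modes.
.lm_step <- function(H, G, lambda, k, step_cap = 1) {
  n <- nrow(G)
  if (k == 1) {
    a <- H[1, 1, ]
    lam <- pmax(lambda, 1e-3)
    for (t in 1:25) {
      pd <- (a + lam) > 0
      if (all(pd)) break
      lam[!pd] <- lam[!pd] * 10
    }
    D <- matrix(-G[, 1] / (a + lam), n, 1)
  } else if (k == 2) {
    a <- H[1, 1, ]; b <- H[1, 2, ]; c <- H[2, 2, ]
    lam <- pmax(lambda, 1e-3)
    for (t in 1:25) {
      pd <- (a + lam) > 0 & ((a + lam) * (c + lam) - b^2) > 0
      if (all(pd)) break
      lam[!pd] <- lam[!pd] * 10
    }
    aa <- a + lam; cc <- c + lam
    det <- aa * cc - b^2
    D <- cbind(-(cc * G[, 1] - b * G[, 2]) / det,
               -(aa * G[, 2] - b * G[, 1]) / det)
  } else {
    D <- matrix(0, n, k)
    for (s in seq_len(n)) {
      Hs <- H[, , s] + diag(lambda[s], k)
      ch <- tryCatch(chol(Hs), error = function(e) NULL)
      if (is.null(ch)) {
        ch <- chol(Hs + diag(sum(abs(diag(Hs))) + 1, k))
      }
      D[s, ] <- -backsolve(ch, forwardsolve(t(ch), G[s, ]))
    }
  }
  # cap the step so a single damped-Newton move cannot leap across basins
  D[D > step_cap] <- step_cap
  D[D < -step_cap] <- -step_cap
  D
}

.foce_eval <- function(prep, model, control, warm = NULL) {
  typ <- .typical_params(model, prep$cov)
  k <- length(model$omega)
  # the eta search always cold-starts from zero so the objective is an
  # exactly deterministic function of the parameters (a warm start would
  # leak path dependence into the outer finite differences)
  E0 <- matrix(0, prep$n_subj, k)
  sol <- .inner_solve(prep, model, typ, E0, control)
  if (!is.null(warm)) warm$E <- sol$eta
  # Classical FOCE-I marginal: linearise the prediction in eta around the
  # conditional mode, giving the Gaussian approximation per subject
  #   -2 log L_i = log|2 pi V| + r' V^{-1} r,
  #   V = A Omega A' + diag(g),  r = y - f(eta_hat) + A eta_hat,
  # with g evaluated at the individual prediction (interaction). Unlike the
  # exact-Hessian Laplace form this is smooth in the parameters and stays
  # accurate for sharply curved conditional modes.
  h <- control$fd_h
  f_hat <- {
    sc <- .scale_params(typ, model, sol$eta)
    .predict_conc(prep, sc$ka, sc$cl, sc$v)
  }
  g_hat <- switch(model$residual,
                  additive     = rep_len(model$sigma[["add"]]^2, length(f_hat)),
                  proportional = f_hat^2 * model$sigma[["prop"]]^2,
                  combined     = f_hat^2 * model$sigma[["prop"]]^2 +
                    model$sigma[["add"]]^2)
  A <- sol$A
  if (is.null(A)) {
    A <- matrix(0, prep$n_obs, k)
    for (j in seq_len(k)) {
      Ep <- sol$eta; Ep[, j] <- Ep[, j] + h
      Em <- sol$eta; Em[, j] <- Em[, j] - h
      scp <- .scale_params(typ, model, Ep)
      scm <- .scale_params(typ, model, Em)
      A[, j] <- (.predict_conc(prep, scp$ka, scp$cl, scp$v) -
                   .predict_conc(prep, scm$ka, scm$cl, scm$v)) / (2 * h)
    }
  }
  om <- diag(unlist(model$omega), k)
  per_subject <- rep(NA_real_, prep$n_subj)
  for (s in seq_len(prep$n_subj)) {
    rows <- which(prep$subj == s)
    if (any(!is.finite(f_hat[rows])) || any(g_hat[rows] <= 0)) next
    As <- A[rows, , drop = FALSE]
    V <- As %*% om %*% t(As) + diag(g_hat[rows], length(rows))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) next
    r <- prep$y[rows] - f_hat[rows] + as.numeric(As %*% sol$eta[s, ])
    z <- forwardsolve(t(ch), r)
    per_subject[s] <- length(rows) * log(2 * pi) + 2 * sum(log(diag(ch))) +
      sum(z^2)
  }
  inner_ok <- all(is.finite(per_subject))
  list(ofv = if (inner_ok) sum(per_subject) else Inf,
       per_subject = per_subject,
       eta = sol$eta, H = sol$H, A = A, typ = typ, converged = inner_ok)
}

#' Conditional -2 log-likelihood of one subject's data and random effects
#'
#' The joint density of a subject's observations given `eta`, plus the normal
#' prior on `eta` — the quantity whose mode and curvature drive the FOCE
#' (Laplacian) marginal approximation.
#'
#' @param data Dataset rows for a single subject (see [read_pk_dataset()] for
#'   the column layout).
#' @param model A [population_model()].
#' @param eta Numeric vector of random effects, `length(model$omega)`.
#' @return A scalar.
#' @export
conditional_m2ll <- function(data, model, eta) {
  prep <- .prepare_data(data, model)
  if (prep$n_subj != 1) stop("`data` must contain a single subject", call. = FALSE)
  k <- length(model$omega)
  stopifnot(length(eta) == k)
  if (any(model$omega <= 0)) stop("omega must be positive definite", call. = FALSE)
  typ <- .typical_params(model, prep$cov)
  as.numeric(.subject_m2ll_vec(prep, model, typ, matrix(eta, 1)))
}

#' FOCE-with-interaction objective function value
#'
#' Sum over subjects of the first-order conditional approximation to
#' -2 log marginal likelihood: each subject's conditional -2LL is minimised
#' over eta, the prediction is linearised around that mode, and the
#' resulting Gaussian marginal is evaluated with the residual variance
#' taken at the individual prediction (interaction). Deterministic given
#' data and parameters.
#'
#' @param data A pharmacokinetic dataset (see [read_pk_dataset()]).
#' @param model A [population_model()].
#' @param control A [foce_control()].
#' @return The OFV (scalar) with attribute `per_subject`.
#' @export
foce_objective <- function(data, model, control = foce_control()) {
  prep <- .prepare_data(data, model)
  ev <- .foce_eval(prep, model, control)
  structure(ev$ofv, per_subject = ev$per_subject)
}

# Parameter packing: log transform for theta / omega / sigma (positivity),
# identity for covariate-effect values. `fixed` names are left out of the
# search vector.
.param_spec <- function(model, fixed = character()) {
  entries <- list()
  for (p in names(model$theta)) {
    entries[[length(entries) + 1]] <- list(name = p, block = "theta", key = p,
                                           trans = "log")
  }
  for (i in seq_along(model$covariate_effects)) {
    e <- model$covariate_effects[[i]]
    entries[[length(entries) + 1]] <- list(name = .effect_label(e),
                                           block = "effect", key = i,
                                           trans = "identity")
  }
  for (p in names(model$omega)) {
    entries[[length(entries) + 1]] <- list(name = paste0("omega_", p),
                                           block = "omega", key = p, trans = "log")
  }
  sig <- switch(model$residual, proportional = "prop", additive = "add",
                combined = c("prop", "add"))
  for (p in sig) {
    entries[[length(entries) + 1]] <- list(name = paste0("sigma_", p),
                                           block = "sigma", key = p, trans = "log")
  }
  keep <- !vapply(entries, function(e) e$name %in% fixed, logical(1))
  entries <- entries[keep]

  get_nat <- function(m, e) {
    switch(e$block, theta = m$theta[[e$key]],
           effect = m$covariate_effects[[e$key]]$value,
           omega = m$omega[[e$key]], sigma = m$sigma[[e$key]])
  }
  pack <- function(m) {
    vapply(entries, function(e) {
      x <- get_nat(m, e)
      if (e$trans == "log") log(x) else x
    }, numeric(1))
  }
  unpack <- function(par) {
    m <- model
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      x <- if (e$trans == "log") exp(par[i]) else par[i]
      if (e$block == "theta") m$theta[[e$key]] <- x
      else if (e$block == "effect") m$covariate_effects[[e$key]]$value <- x
      else if (e$block == "omega") m$omega[[e$key]] <- x
      else m$sigma[[e$key]] <- x
    }
    m
  }
  list(entries = entries, pack = pack, unpack = unpack,
       names = vapply(entries, `[[`, character(1), "name"),
       trans = vapply(entries, `[[`, character(1), "trans"))
}

#' Fit a population pharmacokinetic model by FOCE-I
#'
#' Minimises the FOCE-with-interaction objective over log-transformed fixed
#' effects and variance components (covariate-effect values are searched
#' untransformed). Standard errors come from a finite-difference Hessian of
#' the objective; empirical Bayes estimates (EBEs) and eta/epsilon shrinkage
#' are computed at the optimum. Non-convergence is reported via the
#' `converged` flag, never silently.
#'
#' @param data A pharmacokinetic dataset (see [read_pk_dataset()]).
#' @param model A [population_model()] providing structure and initial values.
#' @param se Compute standard errors (adds a Hessian pass; disable for speed
#'   in replicate studies).
#' @param fixed Character vector of parameter labels to hold at their initial
#'   values (see `tidy()` output for labels).
#' @param control A [foce_control()].
#' @return An object of class `bdq_fit`; see [tidy.bdq_fit()],
#'   [glance.bdq_fit()], [augment.bdq_fit()].
#' @export
pk_fit <- function(data, model, se = TRUE, fixed = character(),
                   control = foce_control()) {
  stopifnot(inherits(model, "bdq_model"))
  prep <- .prepare_data(data, model)
  spec <- .param_spec(model, fixed)
  if (!length(spec$entries)) stop("no free parameters to estimate", call. = FALSE)
  k <- length(model$omega)
  warm <- new.env(parent = emptyenv())
  warm$E <- matrix(0, prep$n_subj, k)
  n_evals <- 0L
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    key <- paste(par, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_evals <<- n_evals + 1L
    m <- spec$unpack(par)
    ev <- tryCatch(.foce_eval(prep, m, control, warm), error = function(e) NULL)
    v <- if (is.null(ev) || !is.finite(ev$ofv)) 1e10 else ev$ofv
    cache[[key]] <- v
    v
  }
  # forward-difference outer gradient: the cold-started inner solve makes
  # the objective deterministic, so h = 1e-5 truncation error is negligible
  # against the curvature scales involved
  gr <- function(par) {
    h <- 1e-5
    f0 <- fn(par)
    vapply(seq_along(par), function(i) {
      ei <- numeric(length(par)); ei[i] <- h
      (fn(par + ei) - f0) / h
    }, numeric(1))
  }
  par0 <- spec$pack(model)
  nlminb_ctl <- list(rel.tol = control$rel_tol, iter.max = control$iter_max,
                     eval.max = 10L * control$iter_max)
  # The objective carries small steps (~0.1 OFV) where a subject's eta modes
  # swap order, which makes nlminb prone to stalling ("false convergence")
  # well short of the optimum. The search therefore runs in restart cycles —
  # nlminb resets its internal trust region on restart and usually walks
  # through such a step — and each cycle ends with a short Nelder-Mead pass,
  # which is insensitive to micro-steps, to verify practical stationarity.
  opt <- stats::nlminb(par0, fn, gradient = gr, control = nlminb_ctl)
  stationary <- FALSE
  for (cycle in seq_len(control$max_cycles)) {
    for (restart in 1:5) {
      if (opt$convergence == 0) break
      opt2 <- stats::nlminb(opt$par, fn, gradient = gr, control = nlminb_ctl)
      improved <- opt2$objective < opt$objective - 0.01
      if (opt2$objective <= opt$objective) opt <- opt2
      if (!improved) break
    }
    nm <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = control$nm_iter, reltol = 1e-9))
    if (nm$value >= opt$objective - 0.1) {
      if (nm$value < opt$objective) opt$par <- nm$par
      opt$objective <- min(opt$objective, nm$value)
      stationary <- TRUE
      break
    }
    opt <- stats::nlminb(nm$par, fn, gradient = gr, control = nlminb_ctl)
  }
  m_hat <- spec$unpack(opt$par)
  final <- .foce_eval(prep, m_hat, control, warm)
  converged <- final$converged && stationary

  est_nat <- .natural_estimates(spec, opt$par)
  se_nat <- rep(NA_real_, length(opt$par))
  if (se) {
    Hh <- .fd_hessian(fn, opt$par, h_rel = 0.02)
    cov_t <- tryCatch(2 * solve(Hh), error = function(e) NULL)
    if (!is.null(cov_t) && all(diag(cov_t) > 0)) {
      se_t <- sqrt(diag(cov_t))
      # delta method through the transform
      deriv <- ifelse(spec$trans == "log", est_nat, 1)
      se_nat <- se_t * abs(deriv)
    }
  }
  params <- tibble::tibble(
    term = spec$names,
    block = vapply(spec$entries, `[[`, character(1), "block"),
    estimate = est_nat,
    se = se_nat,
    rse = 100 * se_nat / abs(est_nat)
  )

  ebes <- tibble::as_tibble(stats::setNames(
    as.data.frame(final$eta), paste0("eta_", names(model$omega))))
  ebes <- dplyr::bind_cols(tibble::tibble(ID = prep$ids), ebes)

  shr <- .shrinkage(prep, m_hat, final)

  structure(list(model = m_hat, start = model, params = params, ofv = final$ofv,
                 ebes = ebes, shrinkage = shr, converged = converged,
                 n_function_evals = n_evals, prep = prep, control = control,
                 data = data, final = final),
            class = "bdq_fit")
}

.natural_estimates <- function(spec, par) {
  ifelse(spec$trans == "log", exp(par), par)
}

.fd_hessian <- function(fn, par, h_rel = 1e-4) {
  p <- length(par)
  h <- h_rel * pmax(1, abs(par))
  H <- matrix(0, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    fp <- fn(par + ei); fm <- fn(par - ei)
    H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) - fn(par - ei + ej) +
           fn(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

.shrinkage <- function(prep, model, final) {
  k <- length(model$omega)
  eta_shr <- vapply(seq_len(k), function(j) {
    100 * (1 - stats::sd(final$eta[, j]) / sqrt(model$omega[[j]]))
  }, numeric(1))
  sc <- .scale_params(final$typ, model, final$eta)
  ipred <- .predict_conc(prep, sc$ka, sc$cl, sc$v)
  g <- residual_variance(ipred, model)
  iwres <- (prep$y - ipred) / sqrt(g)
  eps_shr <- 100 * (1 - stats::sd(iwres))
  tibble::tibble(component = c(paste0("eta_", names(model$omega)), "epsilon"),
                 shrinkage_pct = c(eta_shr, eps_shr))
}

#' @export
print.bdq_fit <- function(x, ...) {
  cat(sprintf("<bdq_fit> OFV = %.3f, %d subjects, %d observations, %s\n",
              x$ofv, x$prep$n_subj, x$prep$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params, n = Inf)
  invisible(x)
}

#' Tidy a fitted population PK model
#'
#' @param x A [pk_fit()] result.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`, `block`,
#'   `estimate`, `se`, `rse` (\%). Variance components are reported as
#'   variances; `iiv_cv` gives the CV\% for omega terms.
#' @exportS3Method generics::tidy
tidy.bdq_fit <- function(x, ...) {
  dplyr::mutate(x$params,
                iiv_cv = ifelse(.data$block == "omega",
                                100 * sqrt(abs(.data$estimate)), NA_real_))
}

#' One-line summary of a fitted population PK model
#'
#' @inheritParams tidy.bdq_fit
#' @return A one-row tibble: `ofv`, `n_subjects`, `n_obs`, `n_params`,
#'   `converged`, `n_function_evals`.
#' @exportS3Method generics::glance
glance.bdq_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, n_subjects = x$prep$n_subj, n_obs = x$prep$n_obs,
                 n_params = nrow(x$params), converged = x$converged,
                 n_function_evals = x$n_function_evals)
}

#' Observation-level diagnostics for a fitted model
#'
#' Returns the population prediction (`PRED`, at eta = 0), the individual
#' prediction (`IPRED`, at the EBE), individual weighted residuals (`IWRES`)
#' and conditional weighted residuals (`CWRES`). CWRES decorrelates each
#' subject's residual vector using the FOCE linearisation around the EBE:
#' cov = A Omega A' + diag(g), with A the sensitivity of the prediction to
#' eta and g the residual variance at the individual prediction.
#'
#' @param x A [pk_fit()] result.
#' @param ... Unused.
#' @return A tibble with one row per observation.
#' @exportS3Method generics::augment
augment.bdq_fit <- function(x, ...) {
  prep <- x$prep; model <- x$model; final <- x$final
  typ <- final$typ
  pred <- .predict_conc(prep, typ$ka, typ$cl, typ$v)
  sc <- .scale_params(typ, model, final$eta)
  ipred <- .predict_conc(prep, sc$ka, sc$cl, sc$v)
  g <- residual_variance(ipred, model)
  iwres <- (prep$y - ipred) / sqrt(g)
  k <- length(model$omega)
  h <- x$control$fd_h
  A <- matrix(0, prep$n_obs, k)
  for (j in seq_len(k)) {
    Ep <- final$eta; Ep[, j] <- Ep[, j] + h
    Em <- final$eta; Em[, j] <- Em[, j] - h
    scp <- .scale_params(typ, model, Ep); scm <- .scale_params(typ, model, Em)
    A[, j] <- (.predict_conc(prep, scp$ka, scp$cl, scp$v) -
                 .predict_conc(prep, scm$ka, scm$cl, scm$v)) / (2 * h)
  }
  om <- diag(unlist(model$omega), k)
  cwres <- numeric(prep$n_obs)
  for (s in seq_len(prep$n_subj)) {
    rows <- which(prep$subj == s)
    As <- A[rows, , drop = FALSE]
    V <- As %*% om %*% t(As) + diag(g[rows], length(rows))
    L <- tryCatch(t(chol(V)), error = function(e) {
      stop("per-subject residual covariance is not invertible (subject ",
           prep$ids[s], ")", call. = FALSE)
    })
    ey <- ipred[rows] - as.numeric(As %*% final$eta[s, ])
    cwres[rows] <- forwardsolve(L, prep$y[rows] - ey)
  }
  tibble::tibble(ID = prep$ids[prep$subj], TIME = prep$time, DV = prep$y,
                 PRED = pred, IPRED = ipred, RES = prep$y - pred,
                 IWRES = iwres, CWRES = cwres)
}
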