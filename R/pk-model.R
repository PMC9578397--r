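#' Structural one-compartment pharmacokinetic parameters
#'
#' Bundle of the three structural parameters of a one-compartment model with
#' first-order absorption: the absorption rate constant `ka`, the apparent
#' clearance `cl` (CL/F) and the apparent central volume `v` (Vc/F).
#' Bioavailability F is not separately identifiable after oral dosing, so both
#' clearance and volume are apparent quantities.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param cl Apparent clearance CL/F (L/h).
#' @param v Apparent central volume of distribution Vc/F (L).
#' @return An object of class `pk_params`: a named list with elements
#'   `ka`, `cl`, `v` and the derived elimination rate constant `ke = cl/v`.
#' @examples
#' pk_params(ka = 0.447, cl = 4.54, v = 227)
#' @export
pk_params <- function(ka, cl, v) {
  stopifnot(is.numeric(ka), is.numeric(cl), is.numeric(v),
            length(ka) == 1, length(cl) == 1, length(v) == 1)
  if (!all(is.finite(c(ka, cl, v))) || any(c(ka, cl, v) <= 0)) {
    stop("`ka`, `cl` and `v` must all be strictly positive and finite", call. = FALSE)
  }
  structure(list(ka = ka, cl = cl, v = v, ke = cl / v), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> ka = %.4g /h, CL/F = %.4g L/h, Vc/F = %.4g L (ke = %.4g /h)\n",
              x$ka, x$cl, x$v, x$ke))
  invisible(x)
}

# Relative tolerance below which ka and ke are treated as numerically equal
# (flip-flop degenerate case of the Bateman solution).
.ka_ke_tol <- 1e-8

.check_rates <- function(ka, ke, equal_rates_limit) {
  degenerate <- abs(ka - ke) <= .ka_ke_tol * max(ka, ke)
  if (degenerate && !equal_rates_limit) {
    stop("absorption and elimination rate constants are numerically equal; ",
         "set `equal_rates_limit = TRUE` to use the equal-rates limit form",
         call. = FALSE)
  }
  degenerate
}

#' Concentration after a single oral dose
#'
#' Bateman solution of the one-compartment model with first-order absorption:
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})}
#' with \eqn{k_e = CL/V}. When `ka` and `ke` coincide the solution degenerates;
#' by default this raises an error, or with `equal_rates_limit = TRUE` the
#' limit form \eqn{C(t) = D k_a t e^{-k_a t}/V} is used.
#'
#' @param p A [pk_params()] object.
#' @param dose Dose amount (mg), a positive scalar.
#' @param t Time(s) since the dose (h), non-negative.
#' @param equal_rates_limit Use the ka = ke limit form instead of erroring.
#' @return Concentration(s) in mg/L, same length as `t`.
#' @export
conc_single_dose <- function(p, dose, t, equal_rates_limit = FALSE) {
  stopifnot(inherits(p, "pk_params"), is.numeric(dose), length(dose) == 1, dose > 0,
            is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  ka <- p$ka; ke <- p$ke; v <- p$v
  if (.check_rates(ka, ke, equal_rates_limit)) {
    return(dose * ka * t * exp(-ka * t) / v)
  }
  dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Steady-state concentration under repeated identical dosing
#'
#' Closed-form periodic solution for a dose `dose` given every `tau` hours
#' after the accumulation transient has died out:
#' \deqn{C_{ss}(t) = \frac{D k_a}{V (k_a-k_e)}\left[
#'   \frac{e^{-k_e t}}{1 - e^{-k_e \tau}} - \frac{e^{-k_a t}}{1 - e^{-k_a \tau}}
#' \right], \quad 0 \le t \le \tau.}
#' `t = 0` and `t = tau` both give the trough (pre-dose) concentration.
#'
#' @inheritParams conc_single_dose
#' @param tau Interdose interval (h), positive. Thrice-weekly dosing is
#'   represented as evenly spaced doses with `tau = 56`.
#' @param t Time(s) after the last dose, in `[0, tau]`.
#' @return Concentration(s) in mg/L.
#' @export
conc_steady_state <- function(p, dose, tau, t, equal_rates_limit = FALSE) {
  stopifnot(inherits(p, "pk_params"), is.numeric(dose), length(dose) == 1, dose > 0,
            is.numeric(tau), length(tau) == 1, tau > 0, is.numeric(t))
  if (any(t < 0 | t > tau)) stop("`t` must lie within [0, tau]", call. = FALSE)
  ka <- p$ka; ke <- p$ke; v <- p$v
  if (.check_rates(ka, ke, equal_rates_limit)) {
    # superposition of the limit-form Bateman terms: sum_{n>=0} D ka (t+n tau)
    # exp(-ka (t+n tau)) / v, summed in closed form via the geometric series
    q <- exp(-ka * tau)
    return(dose * ka * exp(-ka * t) / v * (t / (1 - q) + tau * q / (1 - q)^2))
  }
  dose * ka / (v * (ka - ke)) *
    (exp(-ke * t) / (1 - exp(-ke * tau)) - exp(-ka * t) / (1 - exp(-ka * tau)))
}

#' Build a dosing regimen
#'
#' A regimen is a tibble of dose events. Either an explicit sequence of
#' (time, amount) pairs, or a steady-state regimen flagged with `ss = TRUE`
#' and an interdose interval `ii`, in which case predictions use the periodic
#' closed form and `time` marks the start of the observed interval.
#'
#' @param amount Dose amount(s) in mg, recycled against `time`.
#' @param time Dose times in h, non-decreasing.
#' @param ss Logical: is this a steady-state (periodic) regimen?
#' @param ii Interdose interval (h); required when `ss = TRUE`.
#' @return A tibble of class `pk_regimen` with columns `time`, `amt`, `ss`, `ii`.
#' @examples
#' # 400 mg daily for two weeks, then 200 mg three times weekly (as tau = 56 h)
#' regimen(amount = 200, time = 0, ss = TRUE, ii = 56)
#' @export
regimen <- function(amount, time = 0, ss = FALSE, ii = NULL) {
  n <- max(length(amount), length(time))
  amount <- rep_len(amount, n); time <- rep_len(time, n)
  if (any(amount <= 0)) stop("dose amounts must be positive", call. = FALSE)
  if (is.unsorted(time)) stop("dose times must be non-decreasing", call. = FALSE)
  if (isTRUE(ss)) {
    if (is.null(ii) || ii <= 0) stop("steady-state regimen requires `ii` > 0", call. = FALSE)
    if (n != 1) stop("a steady-state regimen has a single repeating dose event", call. = FALSE)
  }
  out <- tibble::tibble(time = time, amt = amount, ss = isTRUE(ss),
                        ii = if (isTRUE(ss)) ii else NA_real_)
  class(out) <- c("pk_regimen", class(out))
  out
}

#' Concentration-time profile under a regimen
#'
#' Superposition of single-dose contributions from every dose at or before
#' each requested time; a steady-state-flagged regimen delegates to the
#' periodic closed form [conc_steady_state()] (times are folded into the
#' dosing interval).
#'
#' @inheritParams conc_single_dose
#' @param r A [regimen()].
#' @param times Observation times (h).
#' @return Concentrations in mg/L, same length as `times`.
#' @export
conc_profile <- function(p, r, times, equal_rates_limit = FALSE) {
  stopifnot(inherits(p, "pk_params"), inherits(r, "pk_regimen"), is.numeric(times))
  if (length(times) == 0) return(numeric(0))
  if (r$ss[1]) {
    tad <- (times - r$time[1]) %% r$ii[1]
    return(conc_steady_state(p, r$amt[1], r$ii[1], tad, equal_rates_limit))
  }
  out <- numeric(length(times))
  for (i in seq_len(nrow(r))) {
    active <- times >= r$time[i]
    if (any(active)) {
      out[active] <- out[active] +
        conc_single_dose(p, r$amt[i], times[active] - r$time[i], equal_rates_limit)
    }
  }
  out
}

#' Covariate model for apparent clearance
#'
#' The final covariate model relates CL/F to gamma-glutamyl transferase (GGT)
#' through a power function normalised at the study median, with an additive
#' shift for rs319952 GG homozygotes:
#' \deqn{CL/F = \theta_{CL} (GGT/GGT_{ref})^{\theta_{GGT}} + \theta_{GG}\,[GG]}
#'
#' @param base_cl Typical CL/F at the reference GGT for non-GG subjects (L/h).
#' @param ggt_exponent Power exponent on normalised GGT (dimensionless).
#' @param ggt_reference Normalising GGT value (U/L), the study median.
#' @param genotype_shift Additive CL/F change for rs319952 GG carriers (L/h).
#' @return An object of class `bdq_covariate_model`.
#' @seealso [apply_covariates()], [bdq_final_model()]
#' @export
covariate_model <- function(base_cl = 4.54, ggt_exponent = -0.476,
                            ggt_reference = 28.9, genotype_shift = -1.4) {
  stopifnot(base_cl > 0, ggt_reference > 0)
  structure(list(base_cl = base_cl, ggt_exponent = ggt_exponent,
                 ggt_reference = ggt_reference, genotype_shift = genotype_shift),
            class = "bdq_covariate_model")
}

#' Typical apparent clearance for given covariates
#'
#' @param cm A [covariate_model()].
#' @param ggt GGT level(s), U/L, strictly positive.
#' @param rs319952_gg Logical: rs319952 GG homozygote? Recycled against `ggt`.
#' @return CL/F in L/h, vectorised over inputs.
#' @examples
#' apply_covariates(covariate_model(), ggt = 28.9, rs319952_gg = FALSE) # 4.54
#' @export
apply_covariates <- function(cm, ggt, rs319952_gg = FALSE) {
  stopifnot(inherits(cm, "bdq_covariate_model"), is.numeric(ggt))
  if (any(ggt <= 0)) stop("`ggt` must be strictly positive", call. = FALSE)
  n <- max(length(ggt), length(rs319952_gg))
  ggt <- rep_len(ggt, n); gg <- rep_len(as.logical(rs319952_gg), n)
  cl <- cm$base_cl * (ggt / cm$ggt_reference)^cm$ggt_exponent +
    ifelse(gg, cm$genotype_shift, 0)
  if (any(cl <= 0)) {
    stop("covariate model yields non-positive CL/F (GGT = ",
         paste(signif(ggt[cl <= 0], 4), collapse = ", "), ")", call. = FALSE)
  }
  cl
}

#' Time of the steady-state concentration maximum
#'
#' Closed-form stationary point of [conc_steady_state()] within one interval:
#' \deqn{t_{max} = \frac{1}{k_a - k_e}
#'   \log\frac{k_a (1 - e^{-k_e \tau})}{k_e (1 - e^{-k_a \tau})}.}
#' @inheritParams conc_steady_state
#' @return Time after dose (h) of the peak.
#' @export
tmax_steady_state <- function(p, tau) {
  stopifnot(inherits(p, "pk_params"), tau > 0)
  ka <- p$ka; ke <- p$ke
  .check_rates(ka, ke, equal_rates_limit = FALSE)
  log((ka * (1 - exp(-ke * tau))) / (ke * (1 - exp(-ka * tau)))) / (ka - ke)
}

#' Steady-state exposure metrics for a typical subject
#'
#' Peak, trough and weekly area-under-the-curve at steady state under a dose
#' `dose` every `tau` hours. The peak comes from the closed-form stationary
#' point, the trough from the interval boundary, and the weekly AUC from the
#' identity \eqn{AUC_{weekly,ss} = \mathrm{weekly\ dose} / (CL/F)}.
#'
#' @inheritParams conc_steady_state
#' @param weekly_dose Total dose per week (mg); defaults to `dose * 168 / tau`.
#' @return A one-row tibble with `cmax_ss` (mg/L), `tmax_ss` (h), `cmin_ss`
#'   (mg/L) and `auc_weekly_ss` (mg h/L).
#' @examples
#' p <- pk_params(0.447, apply_covariates(covariate_model(), 30), 227)
#' exposure_metrics(p, dose = 200, tau = 56)
#' @export
exposure_metrics <- function(p, dose, tau, weekly_dose = dose * 168 / tau) {
  stopifnot(inherits(p, "pk_params"), tau > 0)
  tmax <- tmax_steady_state(p, tau)
  tibble::tibble(
    cmax_ss = conc_steady_state(p, dose, tau, tmax),
    tmax_ss = tmax,
    cmin_ss = conc_steady_state(p, dose, tau, 0),
    auc_weekly_ss = weekly_dose / p$cl
  )
}
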