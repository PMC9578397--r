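#' Impute missing covariate values
#'
#' Continuous covariates are filled with the median of the observed values;
#' categorical covariates with the most frequent category. Both are computed
#' across subjects (covariates are constant within subject). The number of
#' imputed subjects per covariate is reported as a message.
#'
#' @param data A pharmacokinetic dataset tibble.
#' @param covariates Character vector of covariate columns to impute.
#' @return The dataset with missing values filled.
#' @export
impute_missing <- function(data, covariates) {
  .validate_dataset(data)
  first <- !duplicated(data$ID)
  for (cc in covariates) {
    x <- data[[cc]]
    if (is.null(x)) stop("covariate `", cc, "` not found", call. = FALSE)
    if (all(is.na(x[first]))) stop("covariate `", cc, "` is entirely missing", call. = FALSE)
    n_miss <- sum(is.na(x[first]))
    if (n_miss == 0) next
    if (is.numeric(x)) {
      fill <- stats::median(x[first], na.rm = TRUE)
    } else {
      tab <- table(x[first], useNA = "no")
      fill <- names(tab)[which.max(tab)]
    }
    data[[cc]][is.na(data[[cc]])] <- fill
    message("imputed ", n_miss, " subject(s) for covariate ", cc,
            " with ", format(fill))
  }
  data
}

#' Screen covariates against empirical Bayes estimates
#'
#' For each structural parameter carrying IIV and each candidate covariate,
#' tests the association between the log individual parameter (typical value
#' times exp(EBE)) and the covariate: a log-log linear regression slope test
#' for continuous covariates, one-way ANOVA for categorical ones. Candidates
#' with p below `alpha` are retained. Categorical levels with fewer than two
#' subjects are pooled into the modal level (reported as a message);
#' zero-variance covariates are excluded with a warning.
#'
#' @param fit A [pk_fit()] of the (typically covariate-free) base model.
#' @param covariates Character vector of covariate columns to screen.
#' @param alpha Screening significance level.
#' @param categorical_form Shift form to propose for categorical candidates:
#'   `"fractional"` (the general search form) or `"additive"`.
#' @return A tibble of candidates: `parameter`, `covariate`, `kind`, `form`,
#'   `p_value`, `reference` (continuous median), `level` (categorical
#'   contrast), `retained`.
#' @export
screen_covariates <- function(fit, covariates, alpha = 0.05,
                              categorical_form = c("fractional", "additive")) {
  stopifnot(inherits(fit, "bdq_fit"))
  categorical_form <- match.arg(categorical_form)
  prep <- fit$prep
  model <- fit$model
  typ <- .typical_params(model, prep$cov)
  out <- list()
  for (p in names(model$omega)) {
    j <- match(p, names(model$omega))
    log_pi <- log(typ[[p]]) + fit$final$eta[, j]
    for (cc in covariates) {
      x <- prep$cov[[cc]]
      if (is.null(x)) stop("covariate `", cc, "` not found", call. = FALSE)
      keep <- !is.na(x)
      if (length(unique(x[keep])) < 2) {
        warning("covariate ", cc, " has no variation; excluded", call. = FALSE)
        next
      }
      if (is.numeric(x)) {
        fitlm <- stats::lm(log_pi[keep] ~ log(x[keep]))
        pv <- summary(fitlm)$coefficients[2, 4]
        out[[length(out) + 1]] <- tibble::tibble(
          parameter = p, covariate = cc, kind = "continuous", form = "power",
          p_value = pv, reference = stats::median(x[keep]),
          level = NA_character_, init = unname(stats::coef(fitlm)[2]))
      } else {
        xx <- as.character(x[keep])
        tab <- table(xx)
        rare <- names(tab)[tab < 2]
        if (length(rare)) {
          modal <- names(tab)[which.max(tab)]
          xx[xx %in% rare] <- modal
          message("pooled rare level(s) ", paste(rare, collapse = ", "),
                  " of ", cc, " into ", modal)
          tab <- table(xx)
        }
        if (length(tab) < 2) {
          warning("covariate ", cc, " has no variation after pooling; excluded",
                  call. = FALSE)
          next
        }
        y <- log_pi[keep]
        gm <- tapply(y, xx, mean)
        lev <- names(gm)[which.max(abs(gm - mean(y)))]
        # test the most deviant level against all others, the binary
        # contrast the shift form (Eq-8 style indicator) would encode
        pv <- stats::t.test(y[xx == lev], y[xx != lev])$p.value
        diff <- mean(y[xx == lev]) - mean(y[xx != lev])
        init <- if (categorical_form == "fractional") expm1(diff)
                else mean(exp(y[xx != lev])) * expm1(diff)
        out[[length(out) + 1]] <- tibble::tibble(
          parameter = p, covariate = cc, kind = "categorical",
          form = categorical_form, p_value = pv, reference = NA_real_,
          level = lev, init = init)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(res)
  dplyr::arrange(dplyr::mutate(res, retained = .data$p_value < alpha),
                 .data$p_value)
}

.candidate_effect <- function(cand, value = NULL) {
  if (is.null(value)) {
    value <- if (!is.null(cand$init) && is.finite(cand$init)) cand$init else 0
  }
  cov_effect(cand$parameter, cand$covariate, cand$form, value = value,
             reference = if (cand$form == "power") cand$reference else NULL,
             level = if (cand$form != "power") cand$level else NULL)
}

.candidate_label <- function(cand) {
  .effect_label(.candidate_effect(cand))
}

.fit_ofv <- function(data, model, control) {
  f <- tryCatch(pk_fit(data, model, se = FALSE, control = control),
                error = function(e) NULL)
  if (is.null(f) || !f$converged) return(NULL)
  f
}

#' Forward inclusion of covariate effects
#'
#' Iteratively adds the candidate whose inclusion gives the largest drop in
#' OFV, provided that drop strictly exceeds the chi-square quantile at
#' `alpha` with 1 degree of freedom (6.635 at alpha = 0.01); ties are broken
#' by candidate order. Candidate fits that fail to converge are skipped and
#' logged in the trace.
#'
#' @param data A pharmacokinetic dataset (missing covariates imputed).
#' @param base_model Starting [population_model()].
#' @param candidates Candidate tibble from [screen_covariates()] (rows with
#'   `retained = FALSE` are ignored if the column is present).
#' @param alpha Forward inclusion significance level.
#' @param control A [foce_control()].
#' @return A list: `model`, `fit`, `trace` (one row per candidate test).
#' @export
forward_include <- function(data, base_model, candidates, alpha = 0.01,
                            control = foce_control()) {
  if ("retained" %in% names(candidates)) {
    candidates <- candidates[candidates$retained, , drop = FALSE]
  }
  threshold <- stats::qchisq(1 - alpha, df = 1)
  fit0 <- pk_fit(data, base_model, se = FALSE, control = control)
  model <- fit0$model; ofv <- fit0$ofv; best_fit <- fit0
  remaining <- seq_len(nrow(candidates))
  trace <- list()
  while (length(remaining)) {
    results <- lapply(remaining, function(i) {
      cand <- candidates[i, ]
      m <- model
      m$covariate_effects <- c(m$covariate_effects, list(.candidate_effect(cand)))
      .fit_ofv(data, m, control)
    })
    delta <- vapply(results, function(f) if (is.null(f)) NA_real_ else ofv - f$ofv,
                    numeric(1))
    for (idx in seq_along(remaining)) {
      cand <- candidates[remaining[idx], ]
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = "forward", candidate = .candidate_label(cand),
        ofv_ref = ofv, delta_ofv = delta[idx], df = 1, threshold = threshold,
        decision = if (is.na(delta[idx])) "not converged" else "tested")
    }
    ok <- which(!is.na(delta) & delta > threshold)
    if (!length(ok)) break
    best <- ok[which.max(delta[ok])]
    cand <- candidates[remaining[best], ]
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = "forward", candidate = .candidate_label(cand), ofv_ref = ofv,
      delta_ofv = delta[best], df = 1, threshold = threshold,
      decision = "included")
    best_fit <- results[[best]]
    model <- best_fit$model; ofv <- best_fit$ofv
    remaining <- remaining[-best]
  }
  list(model = model, fit = best_fit, trace = dplyr::bind_rows(trace))
}

#' Backward elimination of covariate effects
#'
#' Iteratively removes the effect whose removal raises the OFV least, as long
#' as that rise does not exceed the chi-square quantile at `alpha` with 1
#' degree of freedom (7.879 at alpha = 0.005); retention requires the rise to
#' strictly exceed the threshold.
#'
#' @param data A pharmacokinetic dataset.
#' @param full_model Model from the forward step.
#' @param alpha Backward elimination significance level.
#' @param control A [foce_control()].
#' @return A list: `model`, `fit`, `trace`.
#' @export
backward_eliminate <- function(data, full_model, alpha = 0.005,
                               control = foce_control()) {
  threshold <- stats::qchisq(1 - alpha, df = 1)
  fit_full <- pk_fit(data, full_model, se = FALSE, control = control)
  model <- fit_full$model; ofv <- fit_full$ofv; best_fit <- fit_full
  trace <- list()
  while (length(model$covariate_effects)) {
    results <- lapply(seq_along(model$covariate_effects), function(i) {
      m <- model
      m$covariate_effects <- m$covariate_effects[-i]
      .fit_ofv(data, m, control)
    })
    rise <- vapply(results, function(f) if (is.null(f)) NA_real_ else f$ofv - ofv,
                   numeric(1))
    for (i in seq_along(model$covariate_effects)) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = "backward", candidate = .effect_label(model$covariate_effects[[i]]),
        ofv_ref = ofv, delta_ofv = rise[i], df = 1, threshold = threshold,
        decision = if (is.na(rise[i])) "not converged" else "tested")
    }
    ok <- which(!is.na(rise) & rise <= threshold)
    if (!length(ok)) break
    drop <- ok[which.min(rise[ok])]
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = "backward", candidate = .effect_label(model$covariate_effects[[drop]]),
      ofv_ref = ofv, delta_ofv = rise[drop], df = 1, threshold = threshold,
      decision = "removed")
    best_fit <- results[[drop]]
    model <- best_fit$model; ofv <- best_fit$ofv
  }
  list(model = model, fit = best_fit, trace = dplyr::bind_rows(trace))
}

#' Stepwise covariate modelling
#'
#' Screens candidates on the base-model empirical Bayes estimates, then runs
#' likelihood-ratio forward inclusion (`alpha = 0.01`) and backward
#' elimination (`alpha = 0.005`).
#'
#' @param data A pharmacokinetic dataset; covariates in `covariates` are
#'   imputed before fitting.
#' @param covariates Character vector of candidate covariate columns.
#' @param base_model Starting model; defaults to [bdq_base_model()].
#' @param screen_alpha,forward_alpha,backward_alpha Significance levels of the
#'   three stages.
#' @param control A [foce_control()].
#' @param categorical_form Passed to [screen_covariates()].
#' @return A list: `model` (final), `fit`, `screen` (candidate tibble),
#'   `trace` (combined forward/backward log).
#' @export
run_scm <- function(data, covariates, base_model = bdq_base_model(),
                    screen_alpha = 0.05, forward_alpha = 0.01,
                    backward_alpha = 0.005, control = foce_control(),
                    categorical_form = c("fractional", "additive")) {
  categorical_form <- match.arg(categorical_form)
  data <- impute_missing(data, covariates)
  base_fit <- pk_fit(data, base_model, se = FALSE, control = control)
  cands <- screen_covariates(base_fit, covariates, alpha = screen_alpha,
                             categorical_form = categorical_form)
  if (!nrow(cands) || !any(cands$retained)) {
    return(list(model = base_fit$model, fit = base_fit, screen = cands,
                trace = tibble::tibble()))
  }
  fw <- forward_include(data, base_fit$model, cands, alpha = forward_alpha,
                        control = control)
  bw <- backward_eliminate(data, fw$model, alpha = backward_alpha,
                           control = control)
  list(model = bw$model, fit = bw$fit, screen = cands,
       trace = dplyr::bind_rows(fw$trace, bw$trace))
}
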