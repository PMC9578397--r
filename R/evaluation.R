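#' Nonparametric bootstrap of a population PK model
#'
#' Resamples subjects (not observations) with replacement to the original
#' subject count, refits the model on each resample starting from the
#' supplied estimates, and aggregates the converged fits: per-parameter
#' medians and 5th-95th percentiles, plus the convergence success rate.
#'
#' @param data A pharmacokinetic dataset.
#' @param model Fitted [population_model()] (starting values for refits).
#' @param n_resamples Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param control A [foce_control()].
#' @return An object of class `bdq_boot` with elements `estimates` (long
#'   tibble: `resample`, `term`, `estimate`), `success_rate` (\%),
#'   `n_resamples`; see [tidy.bdq_boot()].
#' @export
pk_bootstrap <- function(data, model, n_resamples = 1000, seed = 20201001,
                         control = foce_control()) {
  stopifnot(n_resamples >= 1)
  .validate_dataset(data)
  set.seed(seed)
  ids <- unique(data$ID)
  n <- length(ids)
  rows_by_id <- split(seq_len(nrow(data)), match(data$ID, ids))
  est <- list()
  n_ok <- 0L
  for (b in seq_len(n_resamples)) {
    pick <- sample.int(n, n, replace = TRUE)
    parts <- lapply(seq_along(pick), function(i) {
      d <- data[rows_by_id[[pick[i]]], ]
      d$ID <- i
      d
    })
    db <- dplyr::bind_rows(parts)
    f <- tryCatch(pk_fit(db, model, se = FALSE, control = control),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      n_ok <- n_ok + 1L
      est[[length(est) + 1]] <- dplyr::mutate(
        f$params[, c("term", "estimate")], resample = b)
    }
  }
  if (!n_ok) stop("no bootstrap resample converged", call. = FALSE)
  structure(list(estimates = dplyr::bind_rows(est),
                 success_rate = 100 * n_ok / n_resamples,
                 n_resamples = n_resamples, seed = seed),
            class = "bdq_boot")
}

#' Summarise bootstrap parameter distributions
#'
#' @param x A [pk_bootstrap()] result.
#' @param ... Unused.
#' @return A tibble: `term`, `median`, `q5`, `q95`, `n`.
#' @exportS3Method generics::tidy
tidy.bdq_boot <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$estimates, .data$term),
                   median = stats::median(.data$estimate),
                   q5 = stats::quantile(.data$estimate, 0.05, names = FALSE),
                   q95 = stats::quantile(.data$estimate, 0.95, names = FALSE),
                   n = dplyr::n(), .groups = "drop")
}

#' @exportS3Method generics::glance
glance.bdq_boot <- function(x, ...) {
  tibble::tibble(n_resamples = x$n_resamples, success_rate = x$success_rate)
}

#' @export
print.bdq_boot <- function(x, ...) {
  cat(sprintf("<bdq_boot> %d resamples, %.1f%% converged\n",
              x$n_resamples, x$success_rate))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model simulations are rescaled by the ratio of the bin
#' median population prediction to each point's own population prediction,
#' removing covariate- and dose-driven heterogeneity before percentile
#' comparison. Observed prediction-corrected 5th/50th/95th percentiles per
#' time bin are compared with 90\% confidence bands of the same percentiles
#' across simulation replicates of the original design.
#'
#' @param data A pharmacokinetic dataset.
#' @param model Fitted [population_model()].
#' @param n_sim Number of simulation replicates (>= 100).
#' @param bins Number of equal-count bins over time after dose.
#' @param seed Integer seed.
#' @param lod Detection limit applied to simulated values (substitution, as
#'   in the observed data); `0` disables.
#' @return An object of class `bdq_vpc`: a tibble with one row per bin and
#'   percentile (`bin`, `t_lo`, `t_hi`, `t_mid`, `n_obs`, `percentile`,
#'   `observed`, `sim_lo`, `sim_med`, `sim_hi`), plus attributes; see
#'   [autoplot.bdq_vpc()].
#' @export
pc_vpc <- function(data, model, n_sim = 1000, bins = 8, seed = 20201001,
                   lod = 0.024) {
  stopifnot(n_sim >= 100)
  prep <- .prepare_data(data, model)
  set.seed(seed)
  typ <- .typical_params(model, prep$cov)
  pred <- .predict_conc(prep, typ$ka, typ$cl, typ$v)
  # time after the most recent dose, per observation
  tad <- tapply(prep$pairs$dt, prep$pairs$obs, min)[as.character(seq_len(prep$n_obs))]
  tad <- as.numeric(tad)

  nb <- min(bins, prep$n_obs %/% 2)
  repeat {
    brk <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(tad, brk, include.lowest = TRUE, labels = FALSE)
    if (all(table(bin) >= 2) || nb == 1) break
    message("merging a time bin with fewer than 2 observations")
    nb <- nb - 1
  }
  n_bins <- length(unique(bin))

  med_pred <- tapply(pred, bin, stats::median)
  corr <- as.numeric(med_pred[as.character(bin)]) / pred
  pc_obs <- prep$y * corr

  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- vapply(split(pc_obs, bin), stats::quantile, numeric(3),
                    probs = probs, names = FALSE)

  k <- length(model$omega)
  sim_pct <- array(NA_real_, c(3, n_bins, n_sim))
  for (r in seq_len(n_sim)) {
    E <- matrix(stats::rnorm(prep$n_subj * k), prep$n_subj, k) %*%
      diag(sqrt(unlist(model$omega)), k)
    sc <- .scale_params(typ, model, E)
    f <- .predict_conc(prep, sc$ka, sc$cl, sc$v)
    eps_p <- if (model$residual %in% c("proportional", "combined"))
      stats::rnorm(prep$n_obs, 0, model$sigma[["prop"]]) else 0
    eps_a <- if (model$residual %in% c("additive", "combined"))
      stats::rnorm(prep$n_obs, 0, model$sigma[["add"]]) else 0
    y <- f * (1 + eps_p) + eps_a
    if (lod > 0) y <- pmax(y, lod)
    sim_pct[, , r] <- vapply(split(y * corr, bin), stats::quantile, numeric(3),
                             probs = probs, names = FALSE)
  }
  ci <- apply(sim_pct, c(1, 2), stats::quantile,
              probs = c(0.05, 0.5, 0.95), names = FALSE)

  t_lo <- tapply(tad, bin, min); t_hi <- tapply(tad, bin, max)
  out <- tidyr::expand_grid(bin = seq_len(n_bins), percentile = probs * 100)
  out$t_lo <- as.numeric(t_lo[out$bin]); out$t_hi <- as.numeric(t_hi[out$bin])
  out$t_mid <- (out$t_lo + out$t_hi) / 2
  out$n_obs <- as.integer(table(bin))[out$bin]
  ip <- match(out$percentile, probs * 100)
  out$observed <- obs_pct[cbind(ip, out$bin)]
  out$sim_lo <- ci[cbind(1, ip, out$bin)]
  out$sim_med <- ci[cbind(2, ip, out$bin)]
  out$sim_hi <- ci[cbind(3, ip, out$bin)]
  out <- out[order(out$bin, out$percentile), ]
  class(out) <- c("bdq_vpc", class(out))
  attr(out, "n_sim") <- n_sim
  out
}

#' Plot a prediction-corrected visual predictive check
#'
#' @param object A [pc_vpc()] summary.
#' @param ... Unused.
#' @return A ggplot: observed prediction-corrected percentiles (lines) over
#'   the 90\% simulation bands (ribbons) per percentile.
#' @exportS3Method ggplot2::autoplot
autoplot.bdq_vpc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$percentile <- factor(df$percentile, levels = c(5, 50, 95))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi,
                                      fill = .data$percentile), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (mg/L)",
                  colour = "Percentile", fill = "Percentile") +
    ggplot2::theme_minimal()
}
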