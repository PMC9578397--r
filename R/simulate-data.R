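# Baseline characteristics of the study population: mean, SD and observed
# range per continuous covariate. Values are drawn from normal distributions
# truncated to the printed ranges.
.table1 <- tibble::tribble(
  ~name,   ~mean, ~sd,   ~min,  ~max,
  "AGE",    38.1, 14.1,  11,    78,
  "HT",    166.4, 12.4,  73.3,  183,
  "WT",     58,   12.6,  17,    90.7,
  "RBC",     4.5,  0.7,   2.54,  6.32,
  "HGB",   134.2, 22.6,  67,    174,
  "WBC",     5.9,  2.1,   2.47, 13.88,
  "PLT",   227.1, 79.4, 105,   553,
  "NEUT",   59.1, 11,    32,    91.7,
  "EO",      2.6,  1.9,   0,    10.1,
  "BASO",    0.5,  0.2,   0,     1,
  "LYMPH",  28.2,  9.9,   3.7,  52.5,
  "MONO",    9.6,  2.4,   4.1,  16.8,
  "ALT",    28.6, 24.2,   6,   138.8,
  "AST",    38.5, 24,    14.5, 176.1,
  "GGT",    36.4, 31.1,   8,   271.8,
  "TP",     77.5,  5.8,  65.4,  94.6,
  "ALB",    46.2,  3.3,  38.2,  55.6
)

# Genotype counts per SNP among the 99 study subjects. Single-letter labels
# in the source table denote homozygotes and are expanded (A -> AA); NA rows
# are subjects without a genotype call.
.snp_counts <- tibble::tribble(
  ~snp,         ~genotype, ~count,
  "rs1045642",  "AA", 11,  "rs1045642",  "GG", 27,  "rs1045642",  "GA", 45,  "rs1045642",  NA, 16,
  "rs3740065",  "AA", 33,  "rs3740065",  "AG", 40,  "rs3740065",  "GG", 10,  "rs3740065",  NA, 16,
  "rs319952",   "AA", 31,  "rs319952",   "AG", 39,  "rs319952",   "GG", 13,  "rs319952",   NA, 16,
  "rs320003",   "AA", 12,  "rs320003",   "GG", 69,  "rs320003",   NA, 18,
  "rs2070401",  "AA", 50,  "rs2070401",  "GG",  4,  "rs2070401",  "GA", 29,  "rs2070401",  NA, 16,
  "rs9332096",  "CC", 77,  "rs9332096",  "CT",  6,  "rs9332096",  NA, 16,
  "rs4986893",  "AG",  7,  "rs4986893",  "GG", 76,  "rs4986893",  NA, 16,
  "rs2031920",  "CC", 46,  "rs2031920",  "TT",  3,  "rs2031920",  "TC", 12,  "rs2031920",  NA, 38,
  "rs1695",     "AA", 53,  "rs1695",     "GG",  1,  "rs1695",     "GA", 28,  "rs1695",     NA, 17,
  "rs11080344", "CC", 29,  "rs11080344", "TT", 18,  "rs11080344", "TC", 36,  "rs11080344", NA, 16,
  "rs10946739", "CC", 55,  "rs10946739", "TC", 28,  "rs10946739", NA, 16,
  "rs4149056",  "CC",  8,  "rs4149056",  "TT", 59,  "rs4149056",  "TC", 15,  "rs4149056",  NA, 17,
  "rs1495741",  "AA", 18,  "rs1495741",  "AG", 38,  "rs1495741",  "GG", 26,  "rs1495741",  NA, 17,
  "rs11125883", "AA", 30,  "rs11125883", "CC", 13,  "rs11125883", "CA", 40,  "rs11125883", NA, 16
)

#' Reference distributions of the study covariates
#'
#' @return `table1_reference()`: a tibble of mean, SD and range per continuous
#'   baseline covariate. `snp_reference()`: a tibble of genotype counts per
#'   SNP (out of 99 subjects; `NA` genotype = no call).
#' @export
table1_reference <- function() .table1

#' @rdname table1_reference
#' @export
snp_reference <- function() .snp_counts

#' Describe the sparse steady-state sampling design of the study
#'
#' 99 subjects contributing 246 concentrations in total: 38 subjects with one
#' sample, 24 with two, 12 with three, 11 with four, 7 with five, 5 with six,
#' and one each with seven and eight, all drawn at random times within a 56-h
#' steady-state dosing interval of 200 mg thrice weekly. One observation in
#' the study fell below the assay detection limit (0.024 mg/L) and was
#' replaced by that value.
#'
#' @param n_subjects Number of subjects.
#' @param samples_per_subject Named integer vector: `names` are samples per
#'   subject, values are subject counts; must sum to `n_subjects`.
#' @param dose Maintenance dose (mg).
#' @param tau Interdose interval (h).
#' @param lod Assay limit of detection (mg/L); observations below it are
#'   substituted with this value and flagged.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_subjects = 99,
                         samples_per_subject = c(`1` = 38, `2` = 24, `3` = 12,
                                                 `4` = 11, `5` = 7, `6` = 5,
                                                 `7` = 1, `8` = 1),
                         dose = 200, tau = 56, lod = 0.024) {
  stopifnot(sum(samples_per_subject) == n_subjects, dose > 0, tau > 0, lod >= 0)
  n_obs <- sum(as.integer(names(samples_per_subject)) * samples_per_subject)
  structure(list(n_subjects = n_subjects,
                 samples_per_subject = samples_per_subject,
                 n_obs = n_obs, dose = dose, tau = tau, lod = lod),
            class = "study_design")
}

.rtruncnorm <- function(n, mean, sd, min, max) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(min, mean, sd); hi <- stats::pnorm(max, mean, sd)
  if (hi <= lo) stop("infeasible truncation for mean ", mean, ", sd ", sd, call. = FALSE)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Strongly right-skewed laboratory covariates (large CV, positive support)
# are drawn from a lognormal matched to the printed mean and SD; a normal
# truncated to the printed range cannot reproduce those moments.
.rtrunclnorm <- function(n, mean, sd, min, max) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  lo <- stats::plnorm(min, meanlog, sdlog); hi <- stats::plnorm(max, meanlog, sdlog)
  if (hi <= lo) stop("infeasible truncation for mean ", mean, ", sd ", sd, call. = FALSE)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

#' Simulate subject-level covariates emulating the study population
#'
#' Continuous covariates are drawn from normal distributions truncated to the
#' observed ranges; genotypes are drawn per SNP from the study genotype
#' frequencies, including the no-call (`NA`) fraction so that downstream
#' imputation is exercised. The complete (unmasked) genotypes are kept in the
#' `complete` attribute for use as simulation truth. Weeks on therapy is
#' recorded as metadata (`WEEK`); it does not affect steady-state kinetics.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject (`ID`, continuous covariates,
#'   `SEX`, `WEEK`, one column per SNP), with attribute `complete` holding
#'   the unmasked genotype columns.
#' @export
simulate_covariates <- function(design = study_design(), seed = 20201001) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  n <- design$n_subjects
  out <- tibble::tibble(ID = seq_len(n))
  for (i in seq_len(nrow(.table1))) {
    r <- .table1[i, ]
    skewed <- r$min > 0 && r$sd / r$mean > 0.5
    gen <- if (skewed) .rtrunclnorm else .rtruncnorm
    out[[r$name]] <- round(gen(n, r$mean, r$sd, r$min, r$max), 2)
  }
  out$SEX <- sample(c("M", "F"), n, replace = TRUE)
  wk <- round(exp(.rtruncnorm(n, log(20), 0.6, log(2), log(64))))
  out$WEEK <- pmin(pmax(wk, 2), 64)
  complete <- tibble::tibble(ID = seq_len(n))
  for (s in unique(.snp_counts$snp)) {
    tab <- .snp_counts[.snp_counts$snp == s, ]
    called <- !is.na(tab$genotype)
    true_geno <- sample(tab$genotype[called], n, replace = TRUE,
                        prob = tab$count[called] / sum(tab$count[called]))
    miss <- stats::runif(n) < sum(tab$count[!called]) / sum(tab$count)
    complete[[s]] <- true_geno
    out[[s]] <- ifelse(miss, NA_character_, true_geno)
  }
  attr(out, "complete") <- complete
  out
}

#' Simulate a sparse steady-state concentration dataset
#'
#' Generates one dataset with the statistical structure of the study: for
#' each subject, random effects are drawn from the IIV distribution,
#' individual parameters are computed through the covariate model (using the
#' complete genotypes as truth), each sample time is drawn uniformly within
#' the steady-state dosing interval, the steady-state concentration is
#' computed in closed form and perturbed by the residual-error model, and
#' values below the detection limit are replaced by the limit value and
#' flagged (`BLQ`). Negative draws under a combined/additive error model are
#' resampled and counted.
#'
#' @param design A [study_design()].
#' @param model Generating [population_model()]; defaults to the final model.
#' @param seed Integer seed.
#' @param covariates Optional pre-simulated covariate table from
#'   [simulate_covariates()]; drawn fresh when `NULL`.
#' @param simulate_iiv,simulate_residual Disable to obtain the noise-free
#'   limit (every concentration equals its typical/individual prediction).
#' @return A dataset tibble (see [read_pk_dataset()]) with attribute `truth`:
#'   a list with the generating `model`, per-subject `etas`, the complete
#'   `covariates`, the `seed`, and `n_resampled` negative draws.
#' @export
simulate_pk_dataset <- function(design = study_design(), model = bdq_final_model(),
                                seed = 20201001, covariates = NULL,
                                simulate_iiv = TRUE, simulate_residual = TRUE) {
  stopifnot(inherits(design, "study_design"), inherits(model, "bdq_model"))
  if (is.null(covariates)) covariates <- simulate_covariates(design, seed = seed)
  set.seed(seed + 1L)
  n <- design$n_subjects
  stopifnot(nrow(covariates) == n)
  complete <- attr(covariates, "complete")
  cov_truth <- covariates
  if (!is.null(complete)) {
    for (cc in setdiff(names(complete), "ID")) cov_truth[[cc]] <- complete[[cc]]
  }
  k <- length(model$omega)
  etas <- matrix(0, n, k)
  if (simulate_iiv && k > 0) {
    for (j in seq_len(k)) etas[, j] <- stats::rnorm(n, 0, sqrt(model$omega[[j]]))
  }
  typ <- .typical_params(model, cov_truth)
  ind <- .scale_params(typ, model, etas)

  n_per <- sample(rep(as.integer(names(design$samples_per_subject)),
                      design$samples_per_subject))
  rows <- vector("list", n)
  n_resampled <- 0L
  for (s in seq_len(n)) {
    ni <- n_per[s]
    t_obs <- sort(stats::runif(ni, 0, design$tau))
    p <- pk_params(ind$ka[s], ind$cl[s], ind$v[s])
    cp <- conc_steady_state(p, design$dose, design$tau, t_obs)
    if (simulate_residual) {
      dv <- rep(-1, ni)
      todo <- rep(TRUE, ni)
      while (any(todo)) {
        m <- sum(todo)
        eps_p <- if (model$residual %in% c("proportional", "combined"))
          stats::rnorm(m, 0, model$sigma[["prop"]]) else 0
        eps_a <- if (model$residual %in% c("additive", "combined"))
          stats::rnorm(m, 0, model$sigma[["add"]]) else 0
        cand <- cp[todo] * (1 + eps_p) + eps_a
        dv[todo] <- cand
        redo <- todo
        redo[todo] <- cand < 0
        n_resampled <- n_resampled + sum(redo)
        todo <- redo
      }
    } else {
      dv <- cp
    }
    blq <- dv < design$lod
    dv[blq] <- design$lod
    cov_row <- covariates[s, setdiff(names(covariates), "ID"), drop = FALSE]
    subj <- dplyr::bind_rows(
      tibble::tibble(ID = s, TIME = 0, EVID = 1, AMT = design$dose, SS = 1,
                     II = design$tau, DV = NA_real_, BLQ = FALSE),
      tibble::tibble(ID = s, TIME = t_obs, EVID = 0, AMT = NA_real_, SS = 0,
                     II = 0, DV = dv, BLQ = blq)
    )
    rows[[s]] <- dplyr::bind_cols(subj, cov_row[rep(1, nrow(subj)), ])
  }
  out <- dplyr::bind_rows(rows)
  eta_tbl <- tibble::as_tibble(stats::setNames(as.data.frame(etas),
                                               paste0("eta_", names(model$omega))))
  attr(out, "truth") <- list(model = model, etas = dplyr::bind_cols(
    tibble::tibble(ID = seq_len(n)), eta_tbl),
    covariates = cov_truth, seed = seed, n_resampled = n_resampled)
  out
}
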