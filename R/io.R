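.validate_dataset <- function(data) {
  if (!is.data.frame(data)) stop("dataset must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.dataset_cols, names(data))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("TIME", "EVID", "AMT", "SS", "II", "DV")
  for (cc in num_cols) {
    if (!is.numeric(data[[cc]])) {
      stop("column ", cc, " must be numeric", call. = FALSE)
    }
  }
  if (!all(data$EVID %in% c(0, 1))) stop("EVID must be 0 or 1", call. = FALSE)
  bad <- which(data$EVID == 0 & !is.finite(data$DV))
  if (length(bad)) {
    stop("DV missing on observation row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(data$EVID == 1 & !(is.finite(data$AMT) & data$AMT > 0))
  if (length(bad)) {
    stop("AMT missing or non-positive on dose row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(data$SS == 1 & !(is.finite(data$II) & data$II > 0))
  if (length(bad)) {
    stop("SS=1 row(s) need II > 0: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(data$TIME < 0)) stop("TIME must be non-negative", call. = FALSE)
  # covariates must be constant within subject
  cov_cols <- setdiff(names(data), c(.dataset_cols, "BLQ"))
  for (cc in cov_cols) {
    n_per_id <- tapply(data[[cc]], data$ID, function(x) length(unique(x)))
    if (any(n_per_id > 1)) {
      stop("covariate ", cc, " varies within subject(s): ",
           paste(utils::head(names(n_per_id)[n_per_id > 1], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Read a pharmacokinetic dataset
#'
#' Reads a longitudinal concentration dataset in the conventional
#' dose/observation row layout: `ID`; `TIME` (h); `EVID` (0 observation,
#' 1 dose); `AMT` (mg, dose rows); `SS` (steady-state flag); `II`
#' (interdose interval, h); `DV` (concentration, mg/L — numerically equal
#' to the assay's ug/mL); optional `BLQ` flag for observations reported at
#' the assay detection limit; plus any covariate columns (constant within
#' subject). Validation errors name the offending rows and columns.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_pk_dataset <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  data <- tibble::as_tibble(data)
  if ("BLQ" %in% names(data)) data$BLQ <- as.logical(data$BLQ)
  .validate_dataset(data)
  data
}

#' Write a pharmacokinetic dataset
#'
#' @param data A dataset tibble (validated on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  .validate_dataset(data)
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
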