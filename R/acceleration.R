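#' Biological-age acceleration scores
#'
#' For each biological-age column, the acceleration is the residual from an
#' ordinary least-squares regression of biological age on chronological age
#' within the analysis sample (positive = biologically older than
#' expected), its z-score is standardized to mean 0 / SD 1 within the same
#' sample, and a tertile index is assigned from the sample tertile
#' cut-points (ties to the lower tertile).
#'
#' @param data Cohort with `age` and the biological-age columns.
#' @param ba_cols Named character vector: output prefix -> input column.
#' @return `data` with, per prefix, `<prefix>_accel`, `<prefix>_accel_z`
#'   and `<prefix>_accel_tertile` columns appended.
#' @export
#' @examples
#' df <- tibble::tibble(age = 50:59, kdm_age = 50:59 + rnorm(10))
#' ba_acceleration(df, c(kdm = "kdm_age"))
ba_acceleration <- function(data,
                            ba_cols = c(kdm = "kdm_age",
                                        pheno = "pheno_age")) {
  check_columns(data, c("age", unname(ba_cols)), "data")
  if (nrow(data) < 3L) abort("need at least 3 participants.")
  if (var(data$age) == 0) {
    abort("chronological age is constant; cannot residualize.")
  }
  out <- as_tibble(data)
  for (i in seq_along(ba_cols)) {
    prefix <- names(ba_cols)[i] %||% ba_cols[i]
    ba <- data[[ba_cols[i]]]
    if (any(is.na(ba))) abort(sprintf("missing values in '%s'.", ba_cols[i]))
    accel <- unname(resid(lm(ba ~ data$age)))
    out[[paste0(prefix, "_accel")]] <- accel
    out[[paste0(prefix, "_accel_z")]] <- z_standardize(accel)
    out[[paste0(prefix, "_accel_tertile")]] <- tertile_index(accel)
  }
  out
}
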