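#' Train a Klemera-Doubal biological-age clock
#'
#' For each panel biomarker, a simple linear regression of the (possibly
#' log-transformed) biomarker on chronological age in the reference cohort
#' yields the slope `k_j`, intercept `q_j` and root-mean-squared error
#' `s_j`. The chronological-age scaling factor `s_BA` is, by default, the
#' SD of the first-stage biomarker-only age estimate minus chronological
#' age, corrected downward for the estimator's own sampling noise
#' (`1 / sum((k_j/s_j)^2)`, the Klemera-Doubal characteristic variance);
#' mode `"explained"` instead uses the SD of chronological age explained by
#' the biomarker set (fitted values of age on the panel), and a numeric
#' value overrides both.
#'
#' @param reference Reference cohort (`age` plus panel biomarkers).
#' @param panel A [prepare_panel()] result.
#' @param s_ba `"corrected"`, `"explained"`, or a positive number.
#' @param convention Denominator convention for scoring:
#'   `"squared_ratio"` (default; `sum((k/s)^2)`, the form under which a
#'   biomarker profile exactly at its age expectation scores `BA = CA`) or
#'   `"as_printed"` (`sum(k/s^2)`, retained for audit).
#' @return An object of class `"kdm_clock"`.
#' @export
train_kdm <- function(reference, panel, s_ba = "corrected",
                      convention = c("squared_ratio", "as_printed")) {
  convention <- match.arg(convention)
  check_columns(reference, "age", "reference")
  x <- panel_matrix(reference, panel, "reference")
  age <- reference$age
  n <- length(age)
  if (n < 2L * nrow(panel)) {
    abort("reference must have at least 2 x panel-size complete records.")
  }

  coefs <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    if (var(xj) == 0) {
      abort(sprintf("biomarker '%s' is constant; cannot train.",
                    panel$biomarker[j]))
    }
    fit <- lm(xj ~ age)
    tibble(biomarker = panel$biomarker[j],
           log_transform = panel$log_transform[j],
           slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]),
           rmse = sqrt(sum(resid(fit)^2) / (n - 2L)))
  })
  if (any(!is.finite(c(coefs$slope, coefs$intercept, coefs$rmse))) ||
      any(coefs$rmse <= 0)) {
    abort("non-finite or degenerate regression parameters.")
  }

  w <- (coefs$slope / coefs$rmse)^2
  # first-stage (biomarker-only) estimate and its characteristic noise
  ba_e <- as.numeric(sweep(x, 2, coefs$intercept) %*%
                       (coefs$slope / coefs$rmse^2)) / sum(w)
  if (is.numeric(s_ba)) {
    if (s_ba <= 0) abort("numeric s_ba must be > 0.")
    s_ba_val <- s_ba
    s_ba_mode <- "fixed"
  } else if (identical(s_ba, "corrected")) {
    v <- var(ba_e - age) - 1 / sum(w)
    if (v <= 0) {
      warn("noise-corrected s_BA^2 non-positive; using uncorrected variance.")
      v <- var(ba_e - age)
    }
    s_ba_val <- sqrt(v)
    s_ba_mode <- "corrected"
  } else if (identical(s_ba, "explained")) {
    fit <- lm(age ~ x)
    s_ba_val <- sd(fitted(fit))
    s_ba_mode <- "explained"
  } else {
    abort("s_ba must be 'corrected', 'explained', or a positive number.")
  }

  structure(
    list(panel = panel, coefs = coefs, s_ba = s_ba_val,
         s_ba_mode = s_ba_mode, convention = convention, n = n),
    class = "kdm_clock")
}

#' Score a cohort with a trained Klemera-Doubal clock
#'
#' Computes, per record,
#' `KDMAge = (sum_j (x_j - q_j) k_j / s_j^2 + CA / s_BA^2) / (D + 1/s_BA^2)`
#' where `D` is `sum_j (k_j/s_j)^2` under the `squared_ratio` convention or
#' `sum_j k_j/s_j^2` under `as_printed`.
#'
#' @param data Cohort with `age` and the panel biomarkers (raw scale; the
#'   clock applies its own log transforms).
#' @param clock A [train_kdm()] object.
#' @param convention Optional override of the clock's stored convention.
#' @return `data` with a `kdm_age` column appended.
#' @export
score_kdm <- function(data, clock, convention = NULL) {
  stopifnot(inherits(clock, "kdm_clock"))
  convention <- convention %||% clock$convention
  convention <- match.arg(convention, c("squared_ratio", "as_printed"))
  check_columns(data, "age", "data")
  if (any(is.na(data$age))) abort("missing chronological age.")
  x <- panel_matrix(data, clock$panel, "data")
  co <- clock$coefs
  num <- as.numeric(sweep(x, 2, co$intercept) %*% (co$slope / co$rmse^2)) +
    data$age / clock$s_ba^2
  denom_bio <- switch(convention,
    squared_ratio = sum((co$slope / co$rmse)^2),
    as_printed = sum(co$slope / co$rmse^2))
  dplyr::mutate(as_tibble(data),
                kdm_age = num / (denom_bio + 1 / clock$s_ba^2))
}

#' @export
print.kdm_clock <- function(x, ...) {
  cat(sprintf(
    "<kdm_clock> %d biomarkers, n = %d, s_BA = %.2f y (%s), %s denominator\n",
    nrow(x$coefs), x$n, x$s_ba, x$s_ba_mode, x$convention))
  invisible(x)
}
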