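# Published calibration constants of the phenotypic-age transform.
PHENOAGE_CONSTANTS <- c(c0 = 141.50225, c1 = 0.00553, c2 = 0.09165)

#' Train a phenotypic-age (Gompertz mortality) clock
#'
#' Fits a Gompertz proportional-hazards model of all-cause mortality on
#' chronological age plus the panel biomarkers by right-censored maximum
#' likelihood. The fitted linear predictor `xb` (including the log-rate
#' intercept) and shape `gamma` (per month) define the 120-month mortality
#' score; the score-to-years calibration uses the published constants by
#' default, or constants re-derived from a univariate age-only Gompertz fit
#' on the same reference sample (`rederive_constants = TRUE`), in which
#' case phenotypic age is the chronological age at which the reference
#' age-only model predicts the same 120-month mortality risk.
#'
#' @param reference Reference cohort with `age`, panel biomarkers,
#'   `followup_months` and `event_allcause`.
#' @param panel A [prepare_panel()] result.
#' @param horizon Risk horizon in months (120).
#' @param rederive_constants Re-derive the calibration constants from an
#'   age-only Gompertz fit instead of using the published triplet.
#' @return An object of class `"phenoage_clock"`.
#' @export
train_phenoage <- function(reference, panel, horizon = 120,
                           rederive_constants = FALSE) {
  check_columns(reference, c("age", "followup_months", "event_allcause"),
                "reference")
  if (all(reference$event_allcause == 0)) {
    abort("all records censored; cannot fit a mortality model.")
  }
  x <- panel_matrix(reference, panel, "reference")
  df <- data.frame(time = reference$followup_months,
                   status = reference$event_allcause,
                   age = reference$age, x)
  colnames(df) <- c("time", "status", "age", panel$biomarker)
  fml <- as.formula(paste(
    "survival::Surv(time, status) ~ age +",
    paste(panel$biomarker, collapse = " + ")))
  fit <- tryCatch(
    flexsurv::flexsurvreg(fml, data = df, dist = "gompertz"),
    error = function(e) abort(paste0("Gompertz fit failed: ",
                                     conditionMessage(e))))
  cf <- fit$coefficients   # shape, rate (log scale), covariates
  gamma <- unname(cf["shape"])
  if (gamma <= 0) {
    warn("fitted Gompertz shape is non-positive; mortality-score mapping
          assumes gamma > 0.")
  }
  beta <- cf[setdiff(names(cf), "shape")]
  names(beta)[names(beta) == "rate"] <- "(Intercept)"
  se <- fit$res.t[setdiff(names(cf), "shape"), "se"]
  names(se) <- names(beta)

  if (rederive_constants) {
    fit0 <- flexsurv::flexsurvreg(survival::Surv(time, status) ~ age,
                                  data = df, dist = "gompertz")
    g0 <- unname(fit0$coefficients["shape"])
    b0 <- unname(fit0$coefficients["rate"])
    b1 <- unname(fit0$coefficients["age"])
    k0 <- (exp(horizon * g0) - 1) / g0
    constants <- c(c0 = -b0 / b1, c1 = 1 / k0, c2 = b1)
  } else {
    constants <- PHENOAGE_CONSTANTS
  }

  structure(
    list(panel = panel, gamma = gamma, beta = beta, beta_se = se,
         horizon = horizon,
         constants = constants, rederived = rederive_constants,
         n = nrow(df), events = sum(df$status),
         loglik = fit$loglik),
    class = "phenoage_clock")
}

#' Mortality score from a Gompertz linear predictor
#'
#' `1 - exp(-exp(xb) * (exp(horizon * gamma) - 1) / gamma)`: the Gompertz
#' cumulative probability of death within `horizon` months.
#'
#' @param xb Linear predictor (including intercept).
#' @param gamma Gompertz shape, per month.
#' @param horizon Months.
#' @return Probabilities in (0, 1).
#' @export
gompertz_mortality_score <- function(xb, gamma, horizon = 120) {
  1 - exp(-exp(xb) * (exp(horizon * gamma) - 1) / gamma)
}

#' Phenotypic age from a mortality score (and back)
#'
#' `phenoage_from_score()` maps a 120-month mortality score to years via
#' `c0 + log(-c1 * log(1 - score)) / c2`; `score_from_phenoage()` is its
#' exact inverse. When `-c1 * log(1 - score) = 1` the inner log vanishes
#' and the phenotypic age equals `c0` (141.50225 under the published
#' constants).
#'
#' @param score Mortality score in (0, 1).
#' @param years Phenotypic age in years.
#' @param constants Named vector `c(c0, c1, c2)`.
#' @param log1m_score Optional `log(1 - score)`, for scores too close to 1
#'   to represent in double precision; supply instead of `score`.
#' @return Years, or a score.
#' @export
phenoage_from_score <- function(score = NULL,
                                constants = PHENOAGE_CONSTANTS,
                                log1m_score = NULL) {
  if (is.null(log1m_score)) {
    if (is.null(score)) abort("supply `score` or `log1m_score`.")
    if (any(score <= 0 | score >= 1)) {
      abort("mortality score must lie strictly in (0, 1).")
    }
    log1m_score <- log(1 - score)
  } else if (any(log1m_score >= 0)) {
    abort("log1m_score must be negative.")
  }
  unname(constants["c0"] +
           log(-constants["c1"] * log1m_score) / constants["c2"])
}

#' @rdname phenoage_from_score
#' @export
score_from_phenoage <- function(years, constants = PHENOAGE_CONSTANTS) {
  unname(1 - exp(-exp(constants["c2"] * (years - constants["c0"])) /
                   constants["c1"]))
}

#' Score a cohort with a trained phenotypic-age clock
#'
#' @param data Cohort with `age` and the panel biomarkers (raw scale).
#' @param clock A [train_phenoage()] object.
#' @return `data` with `mortality_score` and `pheno_age` columns appended.
#'   Scores numerically at 0 or 1 are clamped into the open interval with
#'   a warning.
#' @export
score_phenoage <- function(data, clock) {
  stopifnot(inherits(clock, "phenoage_clock"))
  check_columns(data, "age", "data")
  x <- panel_matrix(data, clock$panel, "data")
  xb <- as.numeric(cbind(1, data$age, x) %*%
                     clock$beta[c("(Intercept)", "age",
                                  clock$panel$biomarker)])
  ms <- gompertz_mortality_score(xb, clock$gamma, clock$horizon)
  eps <- 1e-15
  if (any(ms <= eps | ms >= 1 - eps)) {
    warn("mortality scores at the numerical boundary were clamped.")
    ms <- pmin(pmax(ms, eps), 1 - eps)
  }
  dplyr::mutate(as_tibble(data),
                mortality_score = ms,
                pheno_age = phenoage_from_score(ms, clock$constants))
}

#' @export
print.phenoage_clock <- function(x, ...) {
  cat(sprintf(
    "<phenoage_clock> %d biomarkers + age, n = %d (%d deaths), gamma = %.5f /mo%s\n",
    nrow(x$panel), x$n, x$events, x$gamma,
    if (x$rederived) ", re-derived constants" else ""))
  invisible(x)
}
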