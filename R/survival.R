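# Tiered Cox and linear models, Kaplan-Meier/log-rank, subgroup analyses.

#' Adjustment-tier covariate sets
#'
#' Tier 1: sex, age. Tier 2: + drinking, smoking, hypertension, coronary
#' artery disease, diabetes, atrial fibrillation, stroke. Tier 3: +
#' lipid-lowering, antihypertensive, oral hypoglycemic and insulin use.
#' Tier `"3n"`: tier 3 + log NT-proBNP (sensitivity adjustment). The sets
#' are nested.
#'
#' @param tier 1, 2, 3 or `"3n"`.
#' @return Character vector of covariate column names.
#' @export
tier_covariates <- function(tier = 3) {
  tier <- as.character(tier)
  t1 <- c("age", "sex")
  t2 <- c(t1, "drinking", "smoking", "hypertension", "cad", "diabetes",
          "af", "stroke")
  t3 <- c(t2, "lipid_med", "antihtn_med", "oral_hypoglycemic", "insulin")
  switch(tier,
         "1" = t1, "2" = t2, "3" = t3, "3n" = c(t3, "ln_ntprobnp"),
         abort("tier must be 1, 2, 3 or '3n'."))
}

endpoint_column <- function(endpoint = c("allcause", "cv")) {
  endpoint <- match.arg(endpoint)
  c(allcause = "event_allcause", cv = "event_cv")[[endpoint]]
}

# fixed complete-case set over exposure, outcome and the *largest* tier
# requested, so that n and events are identical across tiers
complete_case_set <- function(data, exposure, extra, max_tier = 3) {
  data <- as_tibble(data)
  if ("ntprobnp" %in% names(data) && !("ln_ntprobnp" %in% names(data))) {
    data$ln_ntprobnp <- log(data$ntprobnp)
  }
  cols <- unique(c(exposure, extra, tier_covariates(max_tier)))
  check_columns(data, cols, "cohort")
  data[stats::complete.cases(data[cols]), , drop = FALSE]
}

wald_ci_p <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  list(low = est - z * se, high = est + z * se,
       p = 2 * pnorm(-abs(est) / se))
}

#' Cox proportional-hazards fit for a biological-age exposure
#'
#' Fits the tiered Cox model (Efron ties) of an endpoint on the exposure,
#' either per SD (the exposure is z-standardized within the complete-case
#' sample) or by sample tertile (tertile 1 as reference, plus a trend test
#' entering the ordinal tertile index as continuous). The complete-case
#' set is fixed over the tier-3 (or tier-"3n") covariates before fitting,
#' so `n` and `events` do not change across tiers.
#'
#' @param data Cohort table.
#' @param exposure Exposure column name (e.g. an acceleration column).
#' @param endpoint `"allcause"` or `"cv"`.
#' @param tier 1, 2, 3 or `"3n"`.
#' @param type `"per_sd"` or `"tertile"`.
#' @return A tibble of effect estimates (HR scale) with columns `exposure`,
#'   `endpoint`, `tier`, `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`, `events`.
#' @export
cox_fit <- function(data, exposure, endpoint = "allcause", tier = 3,
                    type = c("per_sd", "tertile")) {
  type <- match.arg(type)
  evcol <- endpoint_column(endpoint)
  covs <- tier_covariates(tier)
  max_tier <- if (identical(as.character(tier), "3n")) "3n" else 3
  df <- complete_case_set(data, exposure, c("followup_months", evcol),
                          max_tier)
  nev <- sum(df[[evcol]])
  if (nev < 1L) abort("no events in the complete-case sample.")
  if (nev < 10L * (length(covs) + 1L)) {
    warn(sprintf("only %d events for %d covariates (< 10 per covariate).",
                 nev, length(covs) + 1L))
  }

  df$.time <- df$followup_months
  df$.status <- df[[evcol]]
  base <- paste(covs, collapse = " + ")

  fit_one <- function(rhs, d) {
    fml <- as.formula(paste("survival::Surv(.time, .status) ~", rhs))
    survival::coxph(fml, data = d, ties = "efron")
  }

  if (type == "per_sd") {
    df$.exp_z <- z_standardize(df[[exposure]])
    fit <- fit_one(paste(".exp_z +", base), df)
    s <- summary(fit)
    est <- coef(fit)[".exp_z"]
    se <- sqrt(diag(vcov(fit))[".exp_z"])
    ci <- wald_ci_p(est, se)
    res <- tibble(term = "per_sd",
                  estimate = exp(unname(est)),
                  conf.low = exp(unname(ci$low)),
                  conf.high = exp(unname(ci$high)),
                  p.value = unname(ci$p))
  } else {
    df$.tert <- tertile_index(df[[exposure]])
    df$.tertf <- factor(df$.tert, levels = 1:3)
    fit <- fit_one(paste(".tertf +", base), df)
    est <- coef(fit)[c(".tertf2", ".tertf3")]
    se <- sqrt(diag(vcov(fit))[c(".tertf2", ".tertf3")])
    ci <- wald_ci_p(est, se)
    trend <- fit_one(paste(".tert +", base), df)
    tse <- sqrt(diag(vcov(trend))[".tert"])
    tp <- wald_ci_p(coef(trend)[".tert"], tse)$p
    res <- tibble(
      term = c("tertile1", "tertile2", "tertile3", "trend"),
      estimate = c(1, exp(unname(est)), NA),
      conf.low = c(NA, exp(unname(ci$low)), NA),
      conf.high = c(NA, exp(unname(ci$high)), NA),
      p.value = c(NA, unname(ci$p), unname(tp)))
  }
  dplyr::mutate(res, exposure = exposure, endpoint = endpoint,
                tier = as.character(tier), n = nrow(df), events = nev,
                .before = 1)
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' Right-censored Kaplan-Meier estimates per group and the log-rank
#' chi-square with (groups - 1) degrees of freedom.
#'
#' @param data Cohort table.
#' @param group Grouping column (e.g. a tertile index).
#' @param endpoint `"allcause"` or `"cv"`.
#' @return An object of class `"ba_km"`: list with `curves` (tibble of
#'   time, at-risk, survival, cumulative incidence, group), `chisq`, `df`,
#'   `p.value`, `n`, `events`.
#' @export
km_logrank <- function(data, group, endpoint = "allcause") {
  evcol <- endpoint_column(endpoint)
  check_columns(data, c(group, "followup_months", evcol), "cohort")
  df <- as_tibble(data)[stats::complete.cases(
    as_tibble(data)[c(group, "followup_months", evcol)]), ]
  g <- factor(df[[group]])
  if (nlevels(g) < 2L) abort("need at least 2 groups for a log-rank test.")
  if (sum(df[[evcol]]) < 1L) abort("no events.")
  sdf <- data.frame(time = df$followup_months, status = df[[evcol]], g = g)
  km <- survival::survfit(survival::Surv(time, status) ~ g, data = sdf)
  lr <- survival::survdiff(survival::Surv(time, status) ~ g, data = sdf)
  strata_lab <- sub("^g=", "", rep(names(km$strata), km$strata))
  curves <- tibble(group = strata_lab, time = km$time,
                   n.risk = km$n.risk, n.event = km$n.event,
                   surv = km$surv, cuminc = 1 - km$surv,
                   conf.low = km$lower, conf.high = km$upper)
  structure(
    list(curves = curves, chisq = lr$chisq, df = length(lr$n) - 1L,
         p.value = pchisq(lr$chisq, length(lr$n) - 1L, lower.tail = FALSE),
         n = nrow(sdf), events = sum(sdf$status), endpoint = endpoint,
         group = group),
    class = "ba_km")
}

#' @export
print.ba_km <- function(x, ...) {
  cat(sprintf(
    "<ba_km> %s by %s: n = %d, events = %d, log-rank chisq = %.2f (df %d), p = %.3g\n",
    x$endpoint, x$group, x$n, x$events, x$chisq, x$df, x$p.value))
  invisible(x)
}

#' Linear model of an echocardiographic outcome on acceleration
#'
#' Per-SD linear regression coefficient of a continuous LV
#' structure/function outcome on the exposure under the tier's covariates.
#'
#' @inheritParams cox_fit
#' @param outcome Continuous outcome column (e.g. `lvmi`, `rwt`, `lvef`,
#'   `ea_ratio`, `e_over_eprime`).
#' @return One-row tibble of the per-SD beta with 95% CI and p.
#' @export
linear_echo <- function(data, exposure, outcome, tier = 3) {
  covs <- tier_covariates(tier)
  max_tier <- if (identical(as.character(tier), "3n")) "3n" else 3
  df <- complete_case_set(data, exposure, outcome, max_tier)
  df$.exp_z <- z_standardize(df[[exposure]])
  df$.y <- df[[outcome]]
  fml <- as.formula(paste(".y ~ .exp_z +", paste(covs, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0("collinear covariate(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  est <- sm[".exp_z", "Estimate"]
  se <- sm[".exp_z", "Std. Error"]
  ci <- wald_ci_p(est, se)
  tibble(exposure = exposure, outcome = outcome, tier = as.character(tier),
         estimate = est, conf.low = ci$low, conf.high = ci$high,
         p.value = ci$p, n = nrow(df))
}

#' Subgroup hazard ratios with interaction tests
#'
#' Stratum-specific per-SD HRs and, per stratifier, a Wald test of the
#' exposure-by-stratifier product term in the pooled tiered model. When a
#' stratifier is itself a tier covariate (or derived from one, e.g. the
#' age or BMI dichotomy) it is dropped from the adjustment set of its own
#' analysis.
#'
#' @inheritParams cox_fit
#' @param strata Named list of stratifier definitions: each element is a
#'   function of the data returning a two-level factor, or a column name.
#' @return Tibble with one row per stratifier level plus the interaction p.
#' @export
subgroup_interactions <- function(data, exposure, endpoint = "allcause",
                                  tier = 3, strata = default_strata()) {
  evcol <- endpoint_column(endpoint)
  df <- complete_case_set(data, exposure, c("followup_months", evcol), 3)
  df$.exp_z <- z_standardize(df[[exposure]])
  df$.time <- df$followup_months
  df$.status <- df[[evcol]]

  purrr::imap_dfr(strata, function(def, nm) {
    s <- if (is.character(def)) factor(df[[def]]) else factor(def(df))
    if (any(table(s) == 0L) || nlevels(s) < 2L) {
      abort(sprintf("stratifier '%s' has an empty stratum.", nm))
    }
    drop <- attr(def, "drops") %||% (if (is.character(def)) def else NULL)
    covs <- setdiff(tier_covariates(tier), drop)
    base <- paste(covs, collapse = " + ")
    per_level <- purrr::map_dfr(levels(s), function(lv) {
      d <- df[s == lv, , drop = FALSE]
      if (sum(d$.status) < 1L) {
        abort(sprintf("stratum %s = %s has no events.", nm, lv))
      }
      fit <- survival::coxph(
        as.formula(paste("survival::Surv(.time, .status) ~ .exp_z +", base)),
        data = d, ties = "efron")
      est <- coef(fit)[".exp_z"]
      se <- sqrt(diag(vcov(fit))[".exp_z"])
      ci <- wald_ci_p(est, se)
      tibble(stratifier = nm, level = lv, n = nrow(d),
             events = sum(d$.status), estimate = exp(unname(est)),
             conf.low = exp(unname(ci$low)), conf.high = exp(unname(ci$high)),
             p.value = unname(ci$p))
    })
    df$.s <- s
    pooled <- survival::coxph(
      as.formula(paste(
        "survival::Surv(.time, .status) ~ .exp_z * .s +", base)),
      data = df, ties = "efron")
    iterm <- grep("^\\.exp_z:", names(coef(pooled)), value = TRUE)
    ip <- wald_ci_p(coef(pooled)[iterm],
                    sqrt(diag(vcov(pooled))[iterm]))$p
    dplyr::mutate(per_level, p.interaction = unname(ip))
  })
}

#' Default stratifier set for subgroup analyses
#'
#' Sex, age dichotomized at 70 years, BMI at 24 kg/m^2, smoking, diabetes,
#' oral hypoglycemic agents, hypertension.
#'
#' @return Named list usable as the `strata` argument of
#'   [subgroup_interactions()].
#' @export
default_strata <- function() {
  with_drop <- function(f, drops) { attr(f, "drops") <- drops; f }
  list(
    sex = with_drop(function(d) d$sex, "sex"),
    age_70 = with_drop(
      function(d) factor(ifelse(d$age > 70, ">70", "<=70"),
                         levels = c("<=70", ">70")), NULL),
    bmi_24 = function(d) factor(ifelse(d$bmi > 24, ">24", "<=24"),
                                levels = c("<=24", ">24")),
    smoking = with_drop(function(d) factor(d$smoking), "smoking"),
    diabetes = with_drop(function(d) factor(d$diabetes), "diabetes"),
    hypoglycemic = with_drop(function(d) factor(d$oral_hypoglycemic),
                             "oral_hypoglycemic"),
    hypertension = with_drop(function(d) factor(d$hypertension),
                             "hypertension")
  )
}
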