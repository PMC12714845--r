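# Regression-based causal mediation for survival outcomes with
# exposure-mediator interaction: linear mediator model + rare-outcome Cox
# outcome model, closed-form natural effects, percentile bootstrap.

#' Fit the mediator and outcome models for mediation analysis
#'
#' Fits, on one fixed complete-case set, (i) a linear model of the mediator
#' on the z-standardized exposure and the tier covariates, and (ii) a Cox
#' model (Efron ties) of the endpoint on exposure, mediator, their product
#' and the covariates.
#'
#' @inheritParams cox_fit
#' @param mediator Continuous mediator column (`lvmi` or `e_over_eprime`).
#' @return An object of class `"ba_medfit"` carrying the coefficients
#'   (`beta0`, `beta1`, `beta2`, `sigma2`; `theta1`, `theta2`, `theta3`),
#'   covariate conditioning means, and sample metadata.
#' @export
fit_mediation_models <- function(data, exposure, mediator,
                                 endpoint = "allcause", tier = 3) {
  evcol <- endpoint_column(endpoint)
  covs <- tier_covariates(tier)
  max_tier <- if (identical(as.character(tier), "3n")) "3n" else 3
  df <- complete_case_set(data, exposure, c("followup_months", evcol,
                                            mediator), max_tier)
  if (sum(df[[evcol]]) < 1L) abort("no events.")
  df$.a <- z_standardize(df[[exposure]])
  df$.m <- df[[mediator]]
  df$.time <- df$followup_months
  df$.status <- df[[evcol]]
  base <- if (length(covs) > 0) paste("+", paste(covs, collapse = " + "))
          else ""

  mfit <- lm(as.formula(paste(".m ~ .a", base)), data = df)
  ofit <- tryCatch(
    survival::coxph(
      as.formula(paste("survival::Surv(.time, .status) ~ .a * .m", base)),
      data = df, ties = "efron"),
    error = function(e) abort(paste0("outcome model failed: ",
                                     conditionMessage(e))))
  mc <- coef(mfit)
  oc <- coef(ofit)
  if (any(!is.finite(c(mc, oc)))) abort("non-finite model coefficients.")

  # conditioning values for covariates: sample means of the model-matrix
  # columns (so factors are held at observed level frequencies)
  mm <- model.matrix(mfit)
  cov_cols <- setdiff(colnames(mm), c("(Intercept)", ".a"))
  cov_means <- if (length(cov_cols)) colMeans(mm[, cov_cols, drop = FALSE])
               else numeric(0)

  structure(
    list(beta0 = unname(mc["(Intercept)"]), beta1 = unname(mc[".a"]),
         beta2 = mc[cov_cols],
         sigma2 = sum(resid(mfit)^2) / stats::df.residual(mfit),
         theta1 = unname(oc[".a"]), theta2 = unname(oc[".m"]),
         theta3 = unname(oc[".a:.m"]),
         cov_means = cov_means,
         exposure = exposure, mediator = mediator, endpoint = endpoint,
         tier = as.character(tier), n = nrow(df),
         events = sum(df$.status),
         mediator_fit = mfit, outcome_fit = ofit),
    class = "ba_medfit")
}

#' @export
print.ba_medfit <- function(x, ...) {
  cat(sprintf(
    "<ba_medfit> %s -> %s -> %s (tier %s): n = %d, events = %d\n",
    x$exposure, x$mediator, x$endpoint, x$tier, x$n, x$events))
  cat(sprintf("  beta1 = %.4g, theta1 = %.4g, theta2 = %.4g, theta3 = %.4g\n",
              x$beta1, x$theta1, x$theta2, x$theta3))
  invisible(x)
}

#' Closed-form natural direct and indirect effects
#'
#' Rare-outcome Cox mediation with exposure-mediator interaction and a
#' normal mediator: on the log hazard-ratio scale, for contrast
#' `(a, a*)`,
#' \deqn{NDE = [\theta_1 + \theta_3(\beta_0 + \beta_1 a^* + \beta_2'c +
#'   \theta_2\sigma^2)](a - a^*) +
#'   \tfrac12\theta_3^2\sigma^2(a^2 - a^{*2})}
#' \deqn{NIE = (\theta_2\beta_1 + \theta_3\beta_1 a)(a - a^*)}
#' with the total effect their sum (exact log-scale additivity). The
#' proportion mediated is `NIE / (NDE + NIE)` on the log-HR scale by
#' default, or `HR_NDE (HR_NIE - 1) / (HR_NDE HR_NIE - 1)` on the
#' excess-HR scale.
#'
#' @param models A [fit_mediation_models()] object.
#' @param contrast Exposure contrast `c(a, a_star)` in SD units.
#' @param scale Proportion-mediated scale, `"log_hr"` or `"excess_hr"`.
#' @return A one-row tibble of class `"ba_mediation"`: log and HR scale
#'   effects plus the proportion mediated.
#' @export
natural_effects <- function(models, contrast = c(1, 0),
                            scale = c("log_hr", "excess_hr")) {
  stopifnot(inherits(models, "ba_medfit"))
  scale <- match.arg(scale)
  a <- contrast[1]; a0 <- contrast[2]
  if (a == a0) abort("contrast must satisfy a != a_star.")
  m <- models
  cond <- m$beta0 + m$beta1 * a0 +
    (if (length(m$beta2)) sum(m$beta2 * m$cov_means) else 0)
  nde <- (m$theta1 + m$theta3 * (cond + m$theta2 * m$sigma2)) * (a - a0) +
    0.5 * m$theta3^2 * m$sigma2 * (a^2 - a0^2)
  nie <- (m$theta2 * m$beta1 + m$theta3 * m$beta1 * a) * (a - a0)
  te <- nde + nie
  prop <- proportion_mediated_value(nde, nie, scale)
  res <- tibble(
    exposure = m$exposure, mediator = m$mediator, endpoint = m$endpoint,
    tier = m$tier, log_te = te, log_nde = nde, log_nie = nie,
    hr_te = exp(te), hr_nde = exp(nde), hr_nie = exp(nie),
    prop_mediated = prop, prop_scale = scale,
    n = m$n, events = m$events)
  class(res) <- c("ba_mediation", class(res))
  res
}

# proportion mediated from log-scale direct/indirect effects
proportion_mediated_value <- function(log_nde, log_nie,
                                      scale = c("log_hr", "excess_hr")) {
  scale <- match.arg(scale)
  te <- log_nde + log_nie
  if (scale == "log_hr") {
    if (abs(te) < 1e-12) {
      warn("total effect ~ 0; proportion mediated undefined.")
      return(NA_real_)
    }
    log_nie / te
  } else {
    denom <- exp(log_nde + log_nie) - 1
    if (abs(denom) < 1e-12) {
      warn("total excess HR ~ 0; proportion mediated undefined.")
      return(NA_real_)
    }
    exp(log_nde) * (exp(log_nie) - 1) / denom
  }
}

#' Proportion mediated of a fitted mediation result
#'
#' @param result A [natural_effects()] (or [bootstrap_mediation()]) row.
#' @param scale `"log_hr"` (default) or `"excess_hr"`.
#' @return Scalar proportion (possibly `NA` when the total effect
#'   vanishes).
#' @export
proportion_mediated <- function(result, scale = c("log_hr", "excess_hr")) {
  check_columns(result, c("log_nde", "log_nie"), "result")
  proportion_mediated_value(result$log_nde[1], result$log_nie[1],
                            match.arg(scale))
}

#' Bootstrap confidence intervals for the mediation decomposition
#'
#' Nonparametric bootstrap over participants: refits both mediation models
#' on each resample and takes percentile intervals for the total, direct
#' and indirect hazard ratios and the proportion mediated. Deterministic
#' under a fixed seed.
#'
#' @inheritParams fit_mediation_models
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param contrast Exposure contrast in SD units.
#' @param scale Proportion-mediated scale.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A `"ba_mediation"` tibble with `*_low` / `*_high` percentile
#'   bounds, `n_boot`, `n_fail` and `seed` columns.
#' @export
bootstrap_mediation <- function(data, exposure, mediator,
                                endpoint = "allcause", tier = 3,
                                n_boot = 1000L, contrast = c(1, 0),
                                scale = c("log_hr", "excess_hr"),
                                seed = 1L, level = 0.95) {
  scale <- match.arg(scale)
  if (n_boot < 200L) abort("n_boot must be at least 200.")
  point <- natural_effects(
    fit_mediation_models(data, exposure, mediator, endpoint, tier),
    contrast, scale)

  set.seed(seed)
  n <- nrow(data)
  reps <- purrr::map(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(
      suppressWarnings(natural_effects(
        fit_mediation_models(data[idx, , drop = FALSE], exposure,
                             mediator, endpoint, tier),
        contrast, scale)),
      error = function(e) NULL)
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(!ok) > 0.10) {
    abort(sprintf("bootstrap failure rate %.1f%% exceeds 10%%.",
                  100 * mean(!ok)))
  }
  boot <- dplyr::bind_rows(reps[ok])
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qt <- function(v) unname(quantile(v, probs, na.rm = TRUE))
  ci_te <- qt(boot$hr_te); ci_nde <- qt(boot$hr_nde)
  ci_nie <- qt(boot$hr_nie); ci_pm <- qt(boot$prop_mediated)
  dplyr::mutate(point,
                hr_te_low = ci_te[1], hr_te_high = ci_te[2],
                hr_nde_low = ci_nde[1], hr_nde_high = ci_nde[2],
                hr_nie_low = ci_nie[1], hr_nie_high = ci_nie[2],
                prop_mediated_low = ci_pm[1], prop_mediated_high = ci_pm[2],
                n_boot = as.integer(n_boot), n_fail = sum(!ok),
                seed = as.integer(seed))
}
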