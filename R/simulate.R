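# Synthetic cohorts with known latent aging, mediation structure and
# censoring. Both generators are deterministic given config$seed.

# model-scale biomarker draws (log-scale markers stay on the log scale)
draw_biomarkers_model <- function(bt, latent_age) {
  n <- length(latent_age)
  x <- vapply(seq_len(nrow(bt)), function(j) {
    bt$intercept[j] + bt$slope[j] * latent_age + rnorm(n, 0, bt$noise_sd[j])
  }, numeric(n))
  colnames(x) <- bt$biomarker
  x
}

# raw-scale output columns; strictly positive analytes cannot go negative
biomarkers_to_raw <- function(bt, x) {
  out <- lapply(seq_len(nrow(bt)), function(j) {
    v <- if (bt$log_scale[j]) exp(x[, j]) else x[, j]
    pmax(v, 0.01)
  })
  names(out) <- bt$biomarker
  tibble::as_tibble(out)
}

# per-biomarker mortality weights: precision weights scaled so the linear
# predictor is 12 * shape * latent_age in expectation, i.e. the hazard is
# Gompertz in biomarker-measured latent age
mortality_weights <- function(bt, shape, override = NULL) {
  w <- 12 * shape * (bt$slope / bt$noise_sd^2) /
    sum(bt$slope^2 / bt$noise_sd^2)
  names(w) <- bt$biomarker
  if (!is.null(override)) {
    bad <- setdiff(names(override), bt$biomarker)
    if (length(bad)) abort(paste0("unknown biomarker in gompertz weights: ",
                                  paste(bad, collapse = ", ")))
    w[names(override)] <- override
  }
  w
}

# inverse-transform death time (months) under hazard a * exp(g * t), t >= 0
rgompertz_time <- function(n, rate, shape) {
  u <- runif(n)
  log1p(-shape * log(u) / rate) / shape
}

# inverse-transform death time under cumulative hazard rate * t^shape * e^lp
rweibull_time <- function(n, rate, shape, lp) {
  (-log(runif(n)) / (rate * exp(lp)))^(1 / shape)
}

censor_times <- function(n, cens) {
  runif(n, max(cens$horizon - cens$entry_window, 0), cens$horizon)
}

#' Simulate the clock-training reference cohort
#'
#' Each participant carries a latent biological age `CA + delta` with
#' `delta ~ N(0, accel_sd^2)`; every biomarker drifts linearly with latent
#' age plus Gaussian noise (log-scale markers on the log scale). Mortality
#' follows a Gompertz hazard in the biomarker-measured latent age: the
#' log-rate is a precision-weighted combination of the biomarker deviations
#' whose expectation is `12 * shape * latent_age` (per month), so the
#' hazard is proportional in the measured physiological state and the
#' Gompertz proportional-hazards model of mortality on the biomarkers is
#' correctly specified. Per-biomarker mortality weights may be overridden
#' via `config$gompertz$weights`. Censoring is administrative with uniform
#' study entry. Truth columns are prefixed `truth_`.
#'
#' @param config A [sim_config()].
#' @return A tibble, one row per participant.
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(n_reference = 200, seed = 7))
simulate_reference <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_reference
  age <- runif(n, config$age_range[1], config$age_range[2])
  delta <- rnorm(n, 0, config$accel_sd)
  latent <- age + delta
  bt <- config$biomarker_truth
  xm <- draw_biomarkers_model(bt, latent)
  bio <- biomarkers_to_raw(bt, xm)

  # Gompertz hazard a * exp(w'(x - q) + g*t): proportional in the measured
  # biomarker state, Gompertz in measured latent age in expectation
  g <- config$gompertz$shape
  w <- mortality_weights(bt, g, config$gompertz$weights)
  lp <- as.numeric(sweep(xm, 2, bt$intercept) %*% w)
  rate_i <- config$gompertz$rate * exp(lp)
  death <- rgompertz_time(n, rate_i, g)
  cens <- censor_times(n, config$ref_censoring)
  event <- as.integer(death <= cens)
  event_cv <- as.integer(event == 1L & runif(n) < config$cv_fraction)

  dplyr::bind_cols(
    tibble(id = seq_len(n),
           age = age,
           sex = factor(ifelse(runif(n) < 0.5, "male", "female"),
                        levels = c("male", "female"))),
    bio,
    tibble(followup_months = pmin(death, cens),
           event_allcause = event,
           event_cv = event_cv,
           truth_delta = delta,
           truth_latent_age = latent)
  )
}

#' Simulate the HFpEF analysis cohort
#'
#' Generates 1727-patient-scale cohorts that satisfy the HFpEF eligibility
#' criteria by construction (LVEF truncated at >= 50%, relative wall
#' thickness above 0.42 — a concentric-remodelling phenotype — so that
#' eligibility never selects on the mediator). Biomarkers follow the same
#' latent-age model as the reference cohort; LVMI (primary mediator) and
#' E/e' (secondary) are linear in the latent acceleration `delta`; survival
#' follows a Cox-Weibull hazard
#' `rate * shape * t^(shape-1) * exp(theta_a*delta_sd + theta_m*Mc +
#' theta_am*delta_sd*Mc)` with `Mc` the mediator centered at its intercept;
#' censoring is administrative with uniform entry; cardiovascular deaths
#' are an independent thinning of all deaths.
#'
#' @param config A [sim_config()].
#' @return A tibble, one row per patient, truth columns prefixed `truth_`.
#' @export
simulate_hfpef <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_analysis
  aa <- config$analysis_age
  age <- rtruncnorm(n, aa$mean, aa$sd, aa$range[1], aa$range[2])
  delta <- rnorm(n, 0, config$accel_sd)
  delta_sd <- if (config$accel_sd > 0) delta / config$accel_sd else delta
  bio <- biomarkers_to_raw(config$biomarker_truth,
                           draw_biomarkers_model(config$biomarker_truth,
                                                 age + delta))

  mt <- config$mediator_truth
  mediator <- mt$intercept + mt$slope * delta + rnorm(n, 0, mt$sd)
  mediator <- pmax(mediator, 30)
  et <- config$eprime_truth
  e_over_eprime <- pmax(et$intercept + et$slope * delta +
                          rnorm(n, 0, et$sd), 3)

  # echo block; RWT drawn above the 0.42 criterion so every record is
  # eligible without conditioning on LVMI or E/e'
  lvef <- rtruncnorm(n, 60, 5, 50, 75)
  rwt <- rtruncnorm(n, 0.50, 0.05, 0.43, 0.70)
  ea_ratio <- pmax(rnorm(n, 0.9, 0.3), 0.2)
  e_vel <- pmax(rnorm(n, 0.8, 0.15), 0.3)          # m/s
  ep_mean <- e_vel / e_over_eprime * 100           # cm/s
  e_prime_septal <- ep_mean * 0.9
  e_prime_lateral <- ep_mean * 1.1
  a_vel <- pmax(e_vel / ea_ratio, 0.2)
  pasp <- pmax(rnorm(n, 30, 8), 10)
  ntprobnp <- exp(rnorm(n, log(212), 1.1))

  # covariate and medication flags, prevalences at adult HFpEF-cohort scale
  flag <- function(p) as.integer(runif(n) < p)
  covar <- tibble(
    drinking = flag(0.142), smoking = flag(0.339),
    hypertension = flag(0.794), cad = flag(0.808),
    diabetes = flag(0.456), af = flag(0.141), stroke = flag(0.069),
    lipid_med = flag(0.937),
    n_antihtn = sample(0:4, n, replace = TRUE,
                       prob = c(0.021, 0.15, 0.38, 0.30, 0.149)),
    oral_hypoglycemic = flag(0.338), insulin = flag(0.251)
  )
  covar$antihtn_med <- as.integer(covar$n_antihtn > 0)

  height <- rnorm(n, 165, 8)
  weight <- bio$bmi * (height / 100)^2

  ct <- config$cox_truth
  m_c <- mediator - mt$intercept
  lp <- ct$theta_a * delta_sd + ct$theta_m * m_c +
    ct$theta_am * delta_sd * m_c
  death <- rweibull_time(n, config$weibull$rate, config$weibull$shape, lp)
  cens <- censor_times(n, config$censoring)
  event <- as.integer(death <= cens)
  event_cv <- as.integer(event == 1L & runif(n) < config$cv_fraction)

  out <- dplyr::bind_cols(
    tibble(id = seq_len(n), age = age,
           sex = factor(ifelse(runif(n) < 0.607, "male", "female"),
                        levels = c("male", "female"))),
    bio, covar,
    tibble(height = height, weight = weight,
           lvef = lvef, lvmi = mediator, rwt = rwt,
           e_vel = e_vel, a_vel = a_vel, ea_ratio = ea_ratio,
           e_prime_septal = e_prime_septal,
           e_prime_lateral = e_prime_lateral,
           e_over_eprime = e_over_eprime,
           pasp = pasp, ntprobnp = ntprobnp,
           followup_months = pmin(death, cens),
           event_allcause = event, event_cv = event_cv,
           truth_delta = delta, truth_delta_sd = delta_sd,
           truth_mediator = mt$intercept + mt$slope * delta)
  )
  elig <- hfpef_screen(out)
  if (!all(elig$hfpef_eligible)) {
    abort(sprintf(
      "simulated cohort violates HFpEF eligibility for %d record(s); %s",
      sum(!elig$hfpef_eligible),
      "check lvef/rwt truncation bounds in the config"))
  }
  out
}

#' Closed-form natural effects implied by the configured truth
#'
#' Evaluates the natural direct and indirect effects (log hazard-ratio
#' scale, rare-outcome Cox formulation with exposure-mediator interaction)
#' at the generator's true parameters, for an exposure contrast in SD units
#' of the latent acceleration. Serves as the ground-truth oracle for the
#' mediation estimator.
#'
#' @param config A [sim_config()].
#' @param contrast Exposure contrast `c(a, a_star)` in SD units.
#' @return A tibble with `log_nde`, `log_nie`, `log_te`, `prop_mediated`
#'   (log-HR scale).
#' @export
true_natural_effects <- function(config, contrast = c(1, 0)) {
  config <- validate_sim_config(config)
  a <- contrast[1]; a0 <- contrast[2]
  if (a == a0) abort("contrast must satisfy a != a_star.")
  ct <- config$cox_truth
  mt <- config$mediator_truth
  # mediator model on the centered scale used inside the hazard:
  # Mc = b1_sd * a + eps, b1_sd = slope * accel_sd, intercept 0
  b0 <- 0
  b1 <- mt$slope * config$accel_sd
  s2 <- mt$sd^2
  nde <- (ct$theta_a + ct$theta_am * (b0 + b1 * a0 + ct$theta_m * s2)) *
    (a - a0) + 0.5 * ct$theta_am^2 * s2 * (a^2 - a0^2)
  nie <- (ct$theta_m * b1 + ct$theta_am * b1 * a) * (a - a0)
  te <- nde + nie
  tibble(log_nde = nde, log_nie = nie, log_te = te,
         prop_mediated = if (te == 0) NA_real_ else nie / te)
}

#' Monte-Carlo g-formula oracle for the natural effects
#'
#' Independent check of [true_natural_effects()]: simulates mediator draws
#' under each exposure level and computes the counterfactual rare-outcome
#' hazard ratios by averaging `exp()` hazard multipliers over the draws,
#' never using the closed-form lognormal algebra.
#'
#' @inheritParams true_natural_effects
#' @param n_draws Number of Monte-Carlo mediator draws.
#' @param seed Seed for the draws.
#' @return A tibble like [true_natural_effects()].
#' @export
mc_natural_effects <- function(config, contrast = c(1, 0),
                               n_draws = 1e6, seed = 1L) {
  config <- validate_sim_config(config)
  a <- contrast[1]; a0 <- contrast[2]
  ct <- config$cox_truth
  mt <- config$mediator_truth
  b1 <- mt$slope * config$accel_sd
  set.seed(seed)
  eps <- rnorm(n_draws, 0, mt$sd)
  m_a <- b1 * a + eps        # centered mediator under exposure a
  m_a0 <- b1 * a0 + eps
  # counterfactual rare-outcome hazard ~ e^{theta_a * a} *
  #   E[exp((theta_m + theta_am * a) * M(a'))]
  lam <- function(ae, am) {
    ct$theta_a * ae + log(mean(exp((ct$theta_m + ct$theta_am * ae) * am)))
  }
  nde <- lam(a, m_a0) - lam(a0, m_a0)
  nie <- lam(a, m_a) - lam(a, m_a0)
  te <- nde + nie
  tibble(log_nde = nde, log_nie = nie, log_te = te,
         prop_mediated = if (te == 0) NA_real_ else nie / te)
}
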