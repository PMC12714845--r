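#' Default generative truth for the ten-biomarker panel
#'
#' One row per biomarker: the model-scale intercept (`intercept`, value at
#' age 0), the linear drift with latent biological age (`slope`, units per
#' year) and the residual noise SD (`noise_sd`). Biomarkers flagged
#' `log_scale` (blood urea nitrogen) follow the linear model on the natural
#' log scale and are exponentiated in the output table, so the observed
#' column is raw-scale and right-skewed. Values are plausible adult
#' clinical-unit magnitudes; they are the fixed study conditions of the
#' simulator, not tuning knobs.
#'
#' @return A tibble with columns `biomarker`, `units`, `log_scale`,
#'   `intercept`, `slope`, `noise_sd`.
#' @export
default_biomarker_truth <- function() {
  tibble::tribble(
    ~biomarker,      ~units,    ~log_scale, ~intercept, ~slope,  ~noise_sd,
    "bmi",           "kg/m2",   FALSE,      21.5,        0.045,  0.32,
    "sbp",           "mmHg",    FALSE,      92,          0.75,   5.3,
    "dbp",           "mmHg",    FALSE,      69,          0.10,   0.70,
    "albumin",       "g/L",     FALSE,      49.5,       -0.10,   0.70,
    "bun",           "mg/dL",   TRUE,       2.55,        0.011,  0.08,
    "hdl",           "mg/dL",   FALSE,      58,         -0.14,   1.0,
    "ldl",           "mg/dL",   FALSE,      88,          0.40,   2.8,
    "triglycerides", "mg/dL",   FALSE,      75,          0.85,   6.0,
    "wbc",           "1e9/L",   FALSE,      5.4,         0.022,  0.155,
    "rbc",           "1e12/L",  FALSE,      5.15,       -0.007,  0.05
  )
}

#' Simulation configuration for the synthetic cohorts
#'
#' Bundles every generative parameter of the two synthetic cohorts: the
#' reference sample used to train the biological-age clocks (biomarkers
#' drifting linearly with a latent biological age `CA + delta`,
#' `delta ~ N(0, accel_sd^2)`, Gompertz mortality in latent age) and the
#' HFpEF analysis cohort (echo mediators linear in `delta`, Cox-Weibull
#' survival in standardized acceleration and mediator, administrative
#' censoring with uniform entry).
#'
#' The defaults are the study conditions the package is validated under:
#' an analysis cohort of 1727 patients with roughly 19% all-cause deaths of
#' which about 56% are cardiovascular, a latent acceleration SD of 10
#' years, a per-SD log hazard ratio of 0.4, and a mediator (LVMI) pathway
#' carrying 5% of the total effect in closed form.
#'
#' @param n_reference Reference-cohort size.
#' @param n_analysis HFpEF analysis-cohort size.
#' @param age_range Reference-cohort chronological age range (years),
#'   sampled uniformly.
#' @param analysis_age Mean, SD and truncation range (years) of the
#'   analysis-cohort age distribution.
#' @param accel_sd SD tau (years) of the latent acceleration delta.
#' @param biomarker_truth Tibble as [default_biomarker_truth()].
#' @param gompertz Reference mortality: hazard
#'   `rate * exp(w'(x - q) + shape * t)` at `t` months after baseline,
#'   where `w` are precision weights over the model-scale biomarker
#'   deviations scaled so that `E[w'(x - q)] = 12 * shape * latent_age`;
#'   `shape` is per month. An optional named `weights` element overrides
#'   individual biomarker weights (e.g. to zero out a marker's mortality
#'   effect).
#' @param weibull Analysis-cohort baseline cumulative hazard
#'   `rate * t^shape` (t in months).
#' @param cox_truth Log hazard ratios in the analysis cohort:
#'   `theta_a` per SD of delta, `theta_m` per mediator unit (mediator
#'   centered at its intercept inside the hazard), `theta_am` interaction.
#' @param mediator_truth Linear model of the primary mediator (LVMI,
#'   g/m^2): `intercept + slope * delta + N(0, sd^2)`; `slope` per
#'   acceleration-year.
#' @param eprime_truth Same structure for the secondary mediator (E/e').
#' @param censoring Analysis-cohort administrative censoring:
#'   `C ~ Uniform(horizon - entry_window, horizon)` months.
#' @param ref_censoring Reference-cohort censoring, same form.
#' @param cv_fraction Fraction of deaths independently thinned to
#'   cardiovascular deaths.
#' @param seed Integer seed; the generators are deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_reference = 5000L,
                       n_analysis = 1727L,
                       age_range = c(30, 75),
                       analysis_age = list(mean = 68.2, sd = 10.6,
                                           range = c(40, 95)),
                       accel_sd = 10,
                       biomarker_truth = default_biomarker_truth(),
                       gompertz = list(rate = 6e-6, shape = 0.0075),
                       weibull = list(rate = 2.3e-3, shape = 1.1),
                       cox_truth = list(theta_a = 0.4, theta_m = 0.00421,
                                        theta_am = 0),
                       mediator_truth = list(intercept = 108, slope = 0.5,
                                             sd = 20),
                       eprime_truth = list(intercept = 11, slope = 0.12,
                                           sd = 3.5),
                       censoring = list(horizon = 84, entry_window = 48),
                       ref_censoring = list(horizon = 360,
                                            entry_window = 180),
                       cv_fraction = 0.56,
                       seed = 1L) {
  cfg <- list(
    n_reference = as.integer(n_reference),
    n_analysis = as.integer(n_analysis),
    age_range = age_range, analysis_age = analysis_age,
    accel_sd = accel_sd, biomarker_truth = biomarker_truth,
    gompertz = gompertz, weibull = weibull, cox_truth = cox_truth,
    mediator_truth = mediator_truth, eprime_truth = eprime_truth,
    censoring = censoring, ref_censoring = ref_censoring,
    cv_fraction = cv_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bt <- cfg$biomarker_truth
  need <- c("biomarker", "log_scale", "intercept", "slope", "noise_sd")
  check_columns(bt, need, "biomarker_truth")
  if (anyDuplicated(bt$biomarker)) {
    abort("biomarker_truth: biomarker names must be unique.")
  }
  if (cfg$n_reference < 2L * nrow(bt)) {
    abort("n_reference must be at least twice the number of biomarkers.")
  }
  if (any(bt$noise_sd <= 0)) abort("All biomarker noise SDs must be > 0.")
  if (cfg$age_range[1] >= cfg$age_range[2]) {
    abort("age_range must satisfy low < high.")
  }
  if (cfg$gompertz$shape <= 0) abort("Gompertz shape must be > 0.")
  if (cfg$accel_sd < 0) abort("accel_sd must be >= 0.")
  if (cfg$mediator_truth$sd <= 0) abort("mediator residual SD must be > 0.")
  if (cfg$cv_fraction < 0 || cfg$cv_fraction > 1) {
    abort("cv_fraction must lie in [0, 1].")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  reference n = %d (ages %g-%g), analysis n = %d\n",
              x$n_reference, x$age_range[1], x$age_range[2], x$n_analysis))
  cat(sprintf("  accel SD = %g y; theta_A = %g /SD; theta_M = %g; theta_AM = %g\n",
              x$accel_sd, x$cox_truth$theta_a, x$cox_truth$theta_m,
              x$cox_truth$theta_am))
  cat(sprintf("  mediator: %g + %g*delta (SD %g); seed = %d\n",
              x$mediator_truth$intercept, x$mediator_truth$slope,
              x$mediator_truth$sd, x$seed))
  invisible(x)
}
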