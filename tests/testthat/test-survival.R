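# Cox fits, KM/log-rank, splines, linear echo models, subgroups.

test_that("log-rank statistic matches the hand-computed 6-subject toy", {
  toy <- tibble::tibble(
    followup_months = c(1, 3, 5, 2, 4, 6),
    event_allcause = c(1, 1, 0, 1, 1, 1),
    grp = rep(c("A", "B"), each = 3))
  km <- km_logrank(toy, "grp", "allcause")
  # O_A = 2, E_A = 26/15, V = 433/450 worked over the five risk sets
  expect_equal(km$chisq, 0.0739030023094689, tolerance = 1e-9)
  expect_identical(km$df, 1L)
})

test_that("duplicated relabeled groups give a null log-rank statistic", {
  coh <- simulate_hfpef(small_config(seed = 71))
  dup <- dplyr::bind_rows(dplyr::mutate(coh, grp = "a"),
                          dplyr::mutate(coh, grp = "b"))
  km <- km_logrank(dup, "grp", "allcause")
  expect_lt(km$chisq, 1e-10)
  expect_error(km_logrank(dplyr::mutate(coh, grp = "x"), "grp"),
               "2 groups")
})

test_that("KM estimate with no censoring equals the empirical survival
           function", {
  cfg <- small_config(seed = 73,
                      censoring = list(horizon = 1e5, entry_window = 1))
  coh <- simulate_hfpef(cfg)
  coh$grp <- rep(c("a", "b"), length.out = nrow(coh))
  expect_equal(mean(coh$event_allcause), 1)
  km <- km_logrank(coh, "grp", "allcause")
  ca <- dplyr::filter(km$curves, group == "a")
  times_a <- sort(coh$followup_months[coh$grp == "a"])
  emp <- 1 - ecdf(times_a)(ca$time)
  expect_equal(ca$surv, emp, tolerance = 1e-12)
})

test_that("heavier-hazard groups show uniformly higher cumulative
           incidence", {
  cfg <- sim_config(n_analysis = 3000,
                    cox_truth = list(theta_a = 0.8, theta_m = 0,
                                     theta_am = 0), seed = 79)
  coh <- simulate_hfpef(cfg)
  coh$tert <- tertile_index(coh$truth_delta_sd)
  km <- km_logrank(coh, "tert", "allcause")
  top <- dplyr::filter(km$curves, group == "3")
  bot <- dplyr::filter(km$curves, group == "1")
  grid <- seq(12, 60, by = 12)
  s_at <- function(cv, t) {
    i <- findInterval(t, cv$time); ifelse(i == 0, 1, cv$surv[pmax(i, 1)])
  }
  expect_true(all(s_at(top, grid) < s_at(bot, grid)))
  expect_lt(km$p.value, 0.001)
})

test_that("cox with one binary covariate approaches the true rate ratio
           of two exponential groups", {
  set.seed(83)
  n <- 4000
  g <- rbinom(n, 1, 0.5)
  t_death <- rexp(n, 0.01 * ifelse(g == 1, 2, 1))
  cens <- runif(n, 50, 150)
  df <- tibble::tibble(followup_months = pmin(t_death, cens),
                       event_allcause = as.integer(t_death <= cens),
                       g = g)
  fit <- survival::coxph(survival::Surv(followup_months, event_allcause)
                         ~ g, data = df, ties = "efron")
  expect_equal(unname(coef(fit)), log(2), tolerance = 0.12)
})

test_that("tier nesting keeps n and events fixed across tiers", {
  coh <- simulate_hfpef(sim_config(seed = 87))
  coh$lipid_med[1:60] <- NA
  fits <- purrr::map(c("1", "2", "3"), function(ti) {
    cox_fit(coh, "truth_delta_sd", "allcause", tier = ti)
  })
  ns <- purrr::map_dbl(fits, ~ .x$n[1])
  evs <- purrr::map_dbl(fits, ~ .x$events[1])
  expect_identical(length(unique(ns)), 1L)
  expect_identical(length(unique(evs)), 1L)
  expect_equal(ns[1], nrow(coh) - 60)
})

test_that("tertile fits carry a reference row and an ordinal trend test", {
  coh <- simulate_hfpef(sim_config(seed = 89))
  tt <- cox_fit(coh, "truth_delta_sd", "allcause", tier = 1,
                type = "tertile")
  expect_identical(tt$term, c("tertile1", "tertile2", "tertile3", "trend"))
  expect_identical(tt$estimate[1], 1)
  expect_true(is.na(tt$estimate[4]))
  expect_lt(tt$p.value[4], 0.05)
  expect_gt(tt$estimate[3], tt$estimate[2])
  # CIs bracket estimates, p-values in range
  ps <- cox_fit(coh, "truth_delta_sd", "allcause", tier = 3)
  expect_true(ps$conf.low <= ps$estimate & ps$estimate <= ps$conf.high)
  expect_true(ps$p.value >= 0 & ps$p.value <= 1)
})

test_that("spline basis is linear beyond the boundary knots and the curve
           is anchored at the reference", {
  kn <- c(-1, 0, 2)
  x <- seq(3, 8, by = 0.25)
  b <- rcs_basis(x, kn)
  expect_equal(diff(diff(b[, "nonlin"])), rep(0, length(x) - 2),
               tolerance = 1e-9)
  expect_error(rcs_basis(x, c(1, 1, 2)), "increasing")

  coh <- simulate_hfpef(sim_config(seed = 91))
  sp <- rcs_dose_response(coh, "truth_delta_sd", "allcause", tier = 1)
  expect_equal(sp$curve$hr[sp$curve$exposure == sp$ref], 1)
  expect_true(all(sp$curve$conf.low <= sp$curve$hr + 1e-12))
  expect_true(sp$p_nonlinear >= 0 && sp$p_nonlinear <= 1)
  expect_error(
    rcs_dose_response(coh[1:60, ], "event_cv", "allcause", tier = 1),
    "distinct")
})

test_that("U-shaped log-hazard is detected by the nonlinearity test", {
  set.seed(93)
  n <- 2000
  x <- rnorm(n)
  lp <- 0.6 * x^2
  t_death <- (-log(runif(n)) / (2e-3 * exp(lp)))^(1 / 1.1)
  cens <- runif(n, 36, 84)
  df <- tibble::tibble(followup_months = pmin(t_death, cens),
                       event_allcause = as.integer(t_death <= cens),
                       x = x,
                       age = rnorm(n, 60, 5),
                       sex = factor(rep(c("male", "female"),
                                        length.out = n)))
  # minimal covariate columns for tier 3 completeness
  for (v in setdiff(tier_covariates(3), c("age", "sex"))) df[[v]] <- 0L
  sp <- rcs_dose_response(df, "x", "allcause", tier = 1)
  expect_lt(sp$p_nonlinear, 0.001)
})

test_that("linear echo model recovers the configured mediator slope and
           ignores irrelevant covariates", {
  coh <- simulate_hfpef(sim_config(seed = 95))
  f1 <- linear_echo(coh, "truth_delta_sd", "lvmi", tier = 1)
  # truth: 0.5 g/m^2 per year x 10 y per SD = 5 per SD
  se <- (f1$conf.high - f1$conf.low) / (2 * 1.96)
  expect_lt(abs(f1$estimate - 5), 3 * se)
  f3 <- linear_echo(coh, "truth_delta_sd", "lvmi", tier = 3)
  expect_lt(abs(f1$estimate - f3$estimate), 0.5)
  expect_identical(f1$n, f3$n)

  col <- coh
  col$insulin <- col$oral_hypoglycemic
  expect_error(linear_echo(col, "truth_delta_sd", "lvmi", tier = 3),
               "collinear")
})

test_that("subgroup analysis returns bracketed stratum HRs and a valid
           interaction p", {
  coh <- simulate_hfpef(sim_config(n_analysis = 2500, seed = 97))
  sub <- subgroup_interactions(coh, "truth_delta_sd", "allcause",
                               tier = 1,
                               strata = default_strata()[c("sex",
                                                           "age_70")])
  expect_identical(nrow(sub), 4L)
  expect_true(all(sub$p.interaction >= 0 & sub$p.interaction <= 1))
  pooled <- cox_fit(coh, "truth_delta_sd", "allcause", tier = 1)$estimate
  by_sex <- sub[sub$stratifier == "sex", ]
  expect_true(min(by_sex$estimate) < pooled + 0.25 &&
                max(by_sex$estimate) > pooled - 0.25)
  one_level <- dplyr::mutate(coh, sex = factor("male",
                                               levels = c("male",
                                                          "female")))
  expect_error(
    subgroup_interactions(one_level, "truth_delta_sd", "allcause",
                          tier = 1,
                          strata = default_strata()["sex"]),
    "empty stratum")
})
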