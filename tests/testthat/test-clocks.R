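# Panel selection, KDM and PhenoAge training/scoring, acceleration.

test_that("panel selection excludes age-flat biomarkers and keeps the
           default ten", {
  bt <- dplyr::bind_rows(
    default_biomarker_truth(),
    tibble::tibble(biomarker = "flat", units = "au", log_scale = FALSE,
                   intercept = 5, slope = 0, noise_sd = 1))
  cfg <- sim_config(n_reference = 2000, biomarker_truth = bt, seed = 31)
  ref <- simulate_reference(cfg)
  panel <- prepare_panel(ref, candidates = bt$biomarker)
  expect_false("flat" %in% panel$biomarker)
  expect_identical(nrow(panel), 10L)
  expect_true(panel$log_transform[panel$biomarker == "bun"])
  expect_false(any(panel$log_transform[panel$biomarker != "bun"]))
  expect_gt(abs(panel$cor_ca[panel$biomarker == "sbp"]), 0.5)
})

test_that("panel selection error handling", {
  ref <- trained_fixture()$ref
  expect_error(prepare_panel(ref, r_min = 0.999), "no biomarker")
  expect_error(prepare_panel(ref, r_min = 1.2), "r_min")
  bad <- ref
  bad$bun[5] <- 0
  expect_error(prepare_panel(bad), "bun")
  expect_error(prepare_panel(ref[1:10, ]), "30")
})

test_that("KDM training recovers the truth exactly in the zero-noise
           limit", {
  bt <- default_biomarker_truth()
  bt$noise_sd <- 1e-7
  cfg <- sim_config(n_reference = 500, accel_sd = 0,
                    biomarker_truth = bt, seed = 41)
  ref <- simulate_reference(cfg)
  clock <- suppressWarnings(
    train_kdm(ref, prepare_panel(ref, candidates = bt$biomarker)))
  ord <- match(clock$coefs$biomarker, bt$biomarker)
  expect_equal(clock$coefs$slope, bt$slope[ord], tolerance = 1e-4)
  expect_equal(clock$coefs$intercept, bt$intercept[ord], tolerance = 1e-4)
})

test_that("fitted residual RMSE matches the implied residual SD", {
  fx <- trained_fixture()
  bt <- fx$cfg$biomarker_truth
  ord <- match(fx$kdm$coefs$biomarker, bt$biomarker)
  implied <- sqrt(bt$noise_sd[ord]^2 +
                    bt$slope[ord]^2 * fx$cfg$accel_sd^2)
  expect_true(all(abs(fx$kdm$coefs$rmse / implied - 1) < 0.05))
})

test_that("a record at its age-expected biomarker profile scores
           KDMAge = CA", {
  fx <- trained_fixture()
  clock <- fx$kdm
  ages <- c(35.5, 50, 64.25, 72)
  rec <- purrr::map_dfr(ages, function(ca) {
    vals <- purrr::map2(clock$coefs$intercept, clock$coefs$slope,
                        function(q, k) q + k * ca)
    names(vals) <- clock$coefs$biomarker
    vals <- purrr::imap(vals, function(v, nm) {
      if (clock$coefs$log_transform[clock$coefs$biomarker == nm]) exp(v)
      else v
    })
    tibble::as_tibble(c(list(age = ca), vals))
  })
  scored <- score_kdm(rec, clock)
  expect_equal(scored$kdm_age, ages, tolerance = 1e-9)
})

test_that("KDM quotient matches the independent hand evaluation", {
  clock <- toy_kdm_clock()
  scored <- score_kdm(toy_kdm_record(), clock)
  expect_equal(scored$kdm_age, 60.58189813118358, tolerance = 1e-9)
  scored_pr <- score_kdm(toy_kdm_record(), clock,
                         convention = "as_printed")
  expect_equal(scored_pr$kdm_age, -4.5858204815266825, tolerance = 1e-9)
})

test_that("KDMAge approaches CA as the age scaling factor shrinks", {
  clock <- toy_kdm_clock(s_ba = 1e-6)
  scored <- score_kdm(toy_kdm_record(), clock)
  expect_equal(scored$kdm_age, 62, tolerance = 1e-6)
})

test_that("KDM score is invariant under consistent units rescaling", {
  clock <- toy_kdm_clock()
  base <- score_kdm(toy_kdm_record(), clock)$kdm_age
  resc <- clock
  resc$coefs$slope[2] <- clock$coefs$slope[2] * 10
  resc$coefs$intercept[2] <- clock$coefs$intercept[2] * 10
  resc$coefs$rmse[2] <- clock$coefs$rmse[2] * 10
  rec <- toy_kdm_record()
  rec$b2 <- rec$b2 * 10
  expect_equal(score_kdm(rec, resc)$kdm_age, base, tolerance = 1e-12)
})

test_that("KDM scoring reports the offending record and column", {
  fx <- trained_fixture()
  coh <- simulate_hfpef(small_config(seed = 43))
  coh$sbp[7] <- NA
  expect_error(score_kdm(coh, fx$kdm), "record 7.*sbp")
  expect_error(train_kdm(fx$ref[1:15, ], fx$panel), "2 x panel")
})

test_that("phenoage transform round-trips and hits the inner-log-zero
           anchor", {
  ms <- seq(0.001, 0.999, length.out = 201)
  back <- score_from_phenoage(phenoage_from_score(ms))
  expect_equal(back, ms, tolerance = 1e-9)
  # -c1 * log(1 - MS) = 1  =>  phenotypic age equals the additive constant
  expect_identical(phenoage_from_score(log1m_score = -1 / 0.00553),
                   141.50225)
  expect_error(phenoage_from_score(1.2), "strictly in")
})

test_that("mortality score is strictly monotone in the linear predictor
           with Gompertz limits", {
  xb <- seq(-20, -2, length.out = 400)
  ms <- gompertz_mortality_score(xb, gamma = 0.0075)
  expect_true(all(diff(ms) > 0))
  expect_equal(gompertz_mortality_score(-500, 0.0075), 0)
  expect_true(all(ms >= 0 & ms <= 1))
})

test_that("phenoage training recovers structure and flags null mortality
           effects", {
  cfg <- sim_config(n_reference = 2500,
                    gompertz = list(rate = 6e-6, shape = 0.0075,
                                    weights = c(ldl = 0)),
                    seed = 47)
  ref <- simulate_reference(cfg)
  clock <- train_phenoage(ref, prepare_panel(ref))
  expect_gt(clock$gamma, 0)
  # the zeroed-out biomarker's coefficient CI covers 0
  est <- clock$beta["ldl"]; se <- clock$beta_se["ldl"]
  expect_lt(abs(est / se), 1.96)
  # a strongly weighted biomarker is clearly non-null
  expect_gt(abs(clock$beta["sbp"] / clock$beta_se["sbp"]), 2)
})

test_that("proportional hazards: truncating follow-up leaves coefficients
           statistically unchanged", {
  fx <- trained_fixture()
  ref <- fx$ref
  half <- ref
  cut <- 180
  half$event_allcause[half$followup_months > cut] <- 0L
  half$followup_months <- pmin(half$followup_months, cut)
  c1 <- train_phenoage(ref, fx$panel)
  c2 <- train_phenoage(half, fx$panel)
  d <- abs(c1$beta["sbp"] - c2$beta["sbp"])
  expect_lt(d, 3 * sqrt(c1$beta_se["sbp"]^2 + c2$beta_se["sbp"]^2))
})

test_that("phenoage training rejects degenerate inputs", {
  fx <- trained_fixture()
  allcens <- fx$ref
  allcens$event_allcause <- 0L
  expect_error(train_phenoage(allcens, fx$panel), "censored")
})

test_that("acceleration residuals have the stated geometry", {
  fx <- trained_fixture()
  coh <- simulate_hfpef(sim_config(seed = 53))
  scored <- suppressWarnings(
    ba_acceleration(score_phenoage(score_kdm(coh, fx$kdm), fx$pheno)))
  for (p in c("kdm", "pheno")) {
    a <- scored[[paste0(p, "_accel")]]
    z <- scored[[paste0(p, "_accel_z")]]
    t <- scored[[paste0(p, "_accel_tertile")]]
    expect_lt(abs(mean(a)), 1e-10)
    expect_lt(abs(cor(a, scored$age)), 1e-10)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
    expect_true(max(table(t)) - min(table(t)) <= 1)
  }
})

test_that("identity clock gives zero acceleration; tertiles split 1..9", {
  df <- tibble::tibble(age = seq(40, 80, length.out = 9),
                       ba = seq(40, 80, length.out = 9))
  out <- ba_acceleration(df, c(ident = "ba"))
  expect_equal(out$ident_accel, rep(0, 9), tolerance = 1e-12)
  expect_identical(tertile_index(1:9), rep(1:3, each = 3))
  expect_error(ba_acceleration(df[1:2, ], c(ident = "ba")), "at least 3")
  dfc <- df; dfc$age <- 50
  expect_error(ba_acceleration(dfc, c(ident = "ba")), "constant")
})

test_that("repeated simulated references recover slopes and shape without
           bias", {
  # scaled-down estimator-consistency check: OLS slopes over 100
  # references, Gompertz shape over a smaller batch
  bt <- default_biomarker_truth()
  k_err <- matrix(NA_real_, 100, nrow(bt))
  for (r in 1:100) {
    cfg <- sim_config(n_reference = 2000, seed = 500 + r)
    ref <- simulate_reference(cfg)
    for (j in seq_len(nrow(bt))) {
      x <- ref[[bt$biomarker[j]]]
      if (bt$log_scale[j]) x <- log(x)
      k_err[r, j] <- coef(lm(x ~ ref$age))[2] / bt$slope[j] - 1
    }
  }
  expect_true(all(abs(colMeans(k_err)) < 0.02))

  g_hat <- vapply(1:12, function(r) {
    cfg <- sim_config(n_reference = 1500, seed = 700 + r)
    ref <- simulate_reference(cfg)
    train_phenoage(ref, prepare_panel(ref))$gamma
  }, numeric(1))
  expect_lt(abs(mean(g_hat) / 0.0075 - 1), 0.05)
})
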