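#' Run the full biological-age analysis pipeline on synthetic cohorts
#'
#' Simulates the reference and HFpEF cohorts, trains both clocks, screens
#' eligibility and scores the analysis cohort, and produces the four
#' standard result tables: baseline characteristics by sex, Cox hazard
#' ratios (per SD and by tertile, tiers 1-3), linear echo regressions, and
#' the mediation decomposition with bootstrap CIs, plus Kaplan-Meier and
#' spline dose-response curves and a machine-readable manifest. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param exposures Acceleration exposures: any of `"kdm"`, `"pheno"`.
#' @param mediators Mediator columns for mediation analysis.
#' @param endpoints Any of `"allcause"`, `"cv"`.
#' @param n_boot Bootstrap replicates for mediation CIs.
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV and the manifest as JSON.
#' @return A list of class `"ba_report"`: `baseline`, `cox_table`,
#'   `echo_table`, `mediation_table`, `km`, `splines`, `subgroups`,
#'   `manifest`, plus the scored cohort and trained clocks.
#' @export
run_pipeline <- function(config = sim_config(),
                         exposures = c("kdm", "pheno"),
                         mediators = c("lvmi", "e_over_eprime"),
                         endpoints = c("allcause", "cv"),
                         n_boot = 200L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  reference <- stage("simulate_reference", simulate_reference(config))
  cohort <- stage("simulate_hfpef", simulate_hfpef(config))

  panel <- stage("prepare_panel", prepare_panel(reference))
  kdm <- stage("train_kdm", train_kdm(reference, panel))
  pheno <- stage("train_phenoage", train_phenoage(reference, panel))

  cohort <- stage("screen", h2fpef_score(hfpef_screen(cohort)))
  n_eligible <- sum(cohort$hfpef_eligible)
  cohort <- dplyr::filter(cohort, .data$hfpef_eligible)

  scored <- stage("score", ba_acceleration(
    score_phenoage(score_kdm(cohort, kdm), pheno)))

  exp_cols <- setNames(paste0(exposures, "_accel"), exposures)

  baseline <- stage("baseline_table", baseline_table(scored, by = "sex"))

  grid <- tidyr::expand_grid(exposure = unname(exp_cols),
                             endpoint = endpoints,
                             tier = c("1", "2", "3"))
  cox_table <- stage("cox", dplyr::bind_rows(
    purrr::pmap(grid, function(exposure, endpoint, tier) {
      dplyr::bind_rows(
        cox_fit(scored, exposure, endpoint, tier, type = "per_sd"),
        cox_fit(scored, exposure, endpoint, tier, type = "tertile"))
    })))

  km <- stage("km", purrr::map(
    setNames(nm = as.vector(outer(exposures, endpoints, paste,
                                  sep = "_"))),
    function(key) {
      parts <- strsplit(key, "_")[[1]]
      km_logrank(scored, paste0(parts[1], "_accel_tertile"), parts[2])
    }))

  splines <- stage("rcs", purrr::map(
    setNames(nm = as.vector(outer(exposures, endpoints, paste,
                                  sep = "_"))),
    function(key) {
      parts <- strsplit(key, "_")[[1]]
      rcs_dose_response(scored, exp_cols[[parts[1]]], parts[2], tier = 3)
    }))

  echo_outcomes <- c("lvmi", "rwt", "lvef", "ea_ratio", "e_over_eprime")
  egrid <- tidyr::expand_grid(exposure = unname(exp_cols),
                              outcome = echo_outcomes,
                              tier = c("1", "2", "3"))
  echo_table <- stage("linear_echo", dplyr::bind_rows(
    purrr::pmap(egrid, function(exposure, outcome, tier) {
      linear_echo(scored, exposure, outcome, tier)
    })))

  mgrid <- tidyr::expand_grid(mediator = mediators,
                              exposure = unname(exp_cols),
                              endpoint = endpoints)
  mediation_table <- stage("mediation", dplyr::bind_rows(
    purrr::pmap(mgrid, function(mediator, exposure, endpoint) {
      bootstrap_mediation(scored, exposure, mediator, endpoint, tier = 3,
                          n_boot = n_boot,
                          seed = config$seed + 101L)
    })))

  subgroups <- stage("subgroups", purrr::map_dfr(
    unname(exp_cols),
    function(e) dplyr::mutate(
      subgroup_interactions(scored, e, "allcause", tier = 3),
      exposure = e, .before = 1)))

  manifest <- list(
    package = "bioagehf",
    version = as.character(utils::packageVersion("bioagehf")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_reference = nrow(reference),
    n_analysis = nrow(cohort),
    n_eligible = n_eligible,
    events_allcause = sum(scored$event_allcause),
    events_cv = sum(scored$event_cv),
    panel_size = nrow(panel),
    n_boot = as.integer(n_boot)
  )

  report <- structure(
    list(baseline = baseline, cox_table = cox_table,
         echo_table = echo_table, mediation_table = mediation_table,
         km = km, splines = splines, subgroups = subgroups,
         manifest = manifest, cohort = scored, reference = reference,
         panel = panel, kdm = kdm, phenoage = pheno),
    class = "ba_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits the four result tables, the KM and spline curve grids as CSV, and
#' the manifest as JSON.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "ba_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) {
    write.csv(x, file.path(out_dir, nm), row.names = FALSE)
  }
  wr(report$baseline, "table1_baseline.csv")
  wr(report$cox_table, "table2_cox.csv")
  wr(report$echo_table, "table3_echo.csv")
  wr(report$mediation_table, "table4_mediation.csv")
  wr(dplyr::bind_rows(purrr::imap(
    report$km, function(k, nm) dplyr::mutate(k$curves, analysis = nm,
                                             .before = 1))),
    "km_curves.csv")
  wr(dplyr::bind_rows(purrr::imap(
    report$splines, function(s, nm) dplyr::mutate(s$curve, analysis = nm,
                                                  .before = 1))),
    "spline_curves.csv")
  wr(report$subgroups, "subgroup_analysis.csv")
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.ba_report <- function(x, ...) {
  m <- x$manifest
  cat("<ba_report>\n")
  cat(sprintf("  reference n = %d; analysis n = %d (eligible %d)\n",
              m$n_reference, m$n_analysis, m$n_eligible))
  cat(sprintf("  events: %d all-cause, %d cardiovascular; panel = %d biomarkers\n",
              m$events_allcause, m$events_cv, m$panel_size))
  cat(sprintf("  seed = %d, config hash %s\n", m$seed, m$config_hash))
  invisible(x)
}
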