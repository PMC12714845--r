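# Small shared fixtures, all generated in code.

small_config <- function(seed = 1L, ...) {
  sim_config(n_reference = 600L, n_analysis = 400L, seed = seed, ...)
}

# trained clocks on a mid-sized reference, shared across tests
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_reference = 2000L, seed = 101L)
      ref <- simulate_reference(cfg)
      panel <- prepare_panel(ref)
      cache <<- list(cfg = cfg, ref = ref, panel = panel,
                     kdm = train_kdm(ref, panel),
                     pheno = train_phenoage(ref, panel))
    }
    cache
  }
})

# hand-built 3-biomarker KDM clock for oracle checks
toy_kdm_clock <- function(s_ba = 9, convention = "squared_ratio") {
  panel <- structure(
    tibble::tibble(biomarker = c("b1", "b2", "b3"),
                   log_transform = FALSE, cor_ca = NA_real_),
    class = c("ba_panel", "tbl_df", "tbl", "data.frame"))
  structure(
    list(panel = panel,
         coefs = tibble::tibble(
           biomarker = c("b1", "b2", "b3"), log_transform = FALSE,
           slope = c(0.05, 0.9, -0.01),
           intercept = c(2.0, 60.0, 1.5),
           rmse = c(0.8, 12.0, 0.15)),
         s_ba = s_ba, s_ba_mode = "fixed", convention = convention,
         n = 100L),
    class = "kdm_clock")
}

toy_kdm_record <- function() {
  tibble::tibble(age = 62, b1 = 5.2, b2 = 110.0, b3 = 0.9)
}
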