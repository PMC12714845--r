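#' Prepare the biomarker panel from a reference cohort
#'
#' Applies the log-transform rule (forced for blood urea nitrogen; otherwise
#' triggered when the reference-sample skewness exceeds `skew_threshold` in
#' magnitude) and retains biomarkers whose Pearson correlation with
#' chronological age exceeds `r_min` in magnitude.
#'
#' @param reference Reference cohort with an `age` column and the candidate
#'   biomarker columns.
#' @param candidates Candidate biomarker column names.
#' @param r_min Minimum `|r|` with chronological age for retention.
#' @param force_log Biomarkers always log-transformed regardless of the
#'   skewness rule.
#' @param skew_threshold `|skewness|` above which a biomarker is
#'   log-transformed.
#' @return A tibble of class `"ba_panel"` with columns `biomarker`,
#'   `log_transform`, `cor_ca`, ordered as given.
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(n_reference = 500, seed = 2))
#' prepare_panel(ref)
prepare_panel <- function(reference,
                          candidates = default_biomarker_truth()$biomarker,
                          r_min = 0.1,
                          force_log = "bun",
                          skew_threshold = 1) {
  check_columns(reference, c("age", candidates), "reference")
  if (nrow(reference) < 30L) abort("reference must have at least 30 rows.")
  if (r_min <= 0 || r_min >= 1) abort("r_min must lie in (0, 1).")
  if (anyDuplicated(candidates)) abort("candidate names must be unique.")

  rows <- purrr::map_dfr(candidates, function(nm) {
    x <- reference[[nm]]
    take_log <- nm %in% force_log ||
      isTRUE(abs(sample_skewness(x)) > skew_threshold)
    if (take_log) {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(sprintf(
          "column '%s' has non-positive values; cannot log-transform.", nm))
      }
      x <- log(x)
    }
    tibble(biomarker = nm, log_transform = take_log,
           cor_ca = cor(x, reference$age, use = "complete.obs"))
  })
  panel <- dplyr::filter(rows, abs(.data$cor_ca) > r_min)
  if (nrow(panel) == 0L) {
    abort(sprintf("no biomarker reached |r| > %g with chronological age.",
                  r_min))
  }
  structure(panel, class = c("ba_panel", class(panel)))
}

# transformed biomarker matrix in panel order
panel_matrix <- function(data, panel, what = "data") {
  check_columns(data, panel$biomarker, what)
  x <- as.matrix(data[panel$biomarker])
  for (j in seq_len(nrow(panel))) {
    if (panel$log_transform[j]) {
      if (any(x[, j] <= 0, na.rm = TRUE)) {
        abort(sprintf(
          "column '%s' has non-positive values; cannot log-transform.",
          panel$biomarker[j]))
      }
      x[, j] <- log(x[, j])
    }
  }
  bad <- which(!stats::complete.cases(x) | !apply(is.finite(x), 1, all))
  if (length(bad) > 0L) {
    j <- which(!is.finite(x[bad[1], ]))[1]
    abort(sprintf(
      "missing or non-finite biomarker value: record %d, column '%s'.",
      bad[1], panel$biomarker[j]))
  }
  x
}
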