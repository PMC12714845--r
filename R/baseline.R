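#' Baseline-characteristics summary table
#'
#' Continuous variables are shown as mean +/- SD when approximately normal
#' (|skewness| <= 1) with a t-test (two groups) or one-way ANOVA between
#' groups, and as median \[IQR\] with a rank-sum / Kruskal-Wallis test when
#' skewed (NT-proBNP is always summarised this way); binary/categorical
#' variables as n (%) with a chi-square test.
#'
#' @param data Cohort table.
#' @param by Grouping column (e.g. `"sex"`).
#' @param vars Variables to summarise; defaults to every column except
#'   identifiers, survival columns and truth columns.
#' @param force_median Variables always summarised as median \[IQR\].
#' @return A tibble: `variable`, `summary_type`, `overall`, one column per
#'   group level, `p.value`, `test`.
#' @export
baseline_table <- function(data, by = "sex", vars = NULL,
                           force_median = "ntprobnp") {
  check_columns(data, by, "data")
  data <- as_tibble(data)
  g <- factor(data[[by]])
  if (any(table(g) == 0L) || nlevels(g) < 2L) {
    abort("grouping variable must have at least 2 non-empty levels.")
  }
  if (is.null(vars)) {
    skip <- c("id", by, "followup_months", "event_allcause", "event_cv",
              grep("^truth_", names(data), value = TRUE))
    vars <- setdiff(names(data), skip)
  }

  fmt_mean <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
  fmt_med <- function(x) sprintf("%.1f [%.1f, %.1f]", median(x),
                                 quantile(x, 0.25), quantile(x, 0.75))
  fmt_np <- function(x) sprintf("%d (%.1f)", sum(x == 1),
                                100 * mean(x == 1))

  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    keep <- !is.na(x)
    if (!any(keep)) return(tibble())
    xv <- x[keep]; gv <- g[keep]
    if (is.character(xv)) xv <- factor(xv)
    is_binary <- is.logical(xv) || is.factor(xv) ||
      (is.numeric(xv) && all(xv %in% c(0, 1)))
    if (is_binary) {
      if (is.factor(xv)) xv <- as.integer(xv == levels(xv)[1])
      if (is.logical(xv)) xv <- as.integer(xv)
      p <- tryCatch(
        suppressWarnings(chisq.test(table(xv, gv))$p.value),
        error = function(e) NA_real_)
      row <- c(overall = fmt_np(xv),
               vapply(levels(gv), function(l) fmt_np(xv[gv == l]),
                      character(1)))
      tibble(variable = v, summary_type = "n (%)", !!!as.list(row),
             p.value = p, test = "chi-square")
    } else {
      skewed <- v %in% force_median ||
        isTRUE(abs(sample_skewness(xv)) > 1)
      if (skewed) {
        p <- if (nlevels(droplevels(gv)) == 2L) {
          suppressWarnings(wilcox.test(xv ~ droplevels(gv))$p.value)
        } else kruskal.test(xv, droplevels(gv))$p.value
        row <- c(overall = fmt_med(xv),
                 vapply(levels(gv), function(l) fmt_med(xv[gv == l]),
                        character(1)))
        tibble(variable = v, summary_type = "median [IQR]",
               !!!as.list(row), p.value = p, test = "rank-sum")
      } else {
        p <- if (nlevels(droplevels(gv)) == 2L) {
          t.test(xv ~ droplevels(gv))$p.value
        } else {
          summary(aov(xv ~ droplevels(gv)))[[1]][["Pr(>F)"]][1]
        }
        row <- c(overall = fmt_mean(xv),
                 vapply(levels(gv), function(l) fmt_mean(xv[gv == l]),
                        character(1)))
        tibble(variable = v, summary_type = "mean ± SD",
               !!!as.list(row), p.value = p, test = "t-test/ANOVA")
      }
    }
  })
}
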