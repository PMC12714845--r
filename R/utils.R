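#' Sample skewness
#'
#' Third standardized moment, used to decide which biomarkers are
#' log-transformed and which baseline variables are summarised as
#' median \[IQR\] rather than mean +/- SD.
#'
#' @param x Numeric vector; `NA`s dropped.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Tertile index with ties assigned downward
#'
#' Cut-points are the sample 1/3 and 2/3 quantiles; values tied with a
#' cut-point fall in the lower tertile, so the partition is deterministic.
#'
#' @param x Numeric vector.
#' @return Integer vector in `{1, 2, 3}` (`NA` preserved).
#' @export
tertile_index <- function(x) {
  if (all(is.na(x))) abort("`x` has no non-missing values.")
  br <- quantile(x, probs = c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  idx <- 1L + (x > br[1]) + (x > br[2])
  as.integer(idx)
}

z_standardize <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("Cannot z-standardize a constant vector.")
  (x - mean(x, na.rm = TRUE)) / s
}

# draw from a normal truncated to [lo, hi] by inverse CDF (vectorized, exact)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

# stop unless all columns are present in `data`
check_columns <- function(data, cols, what = "data") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(data)
}
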