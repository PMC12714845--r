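# ggplot2 autoplot methods for the result objects.

#' Plot cumulative-incidence curves by group
#'
#' Step curves of cumulative incidence per group with the log-rank p in
#' the subtitle.
#'
#' @param object A [km_logrank()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_km <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$time, y = .data$cuminc,
                            colour = .data$group)) +
    geom_step(linewidth = 0.7) +
    labs(x = "Follow-up (months)", y = "Cumulative incidence",
         colour = object$group,
         title = sprintf("Cumulative incidence (%s mortality)",
                         object$endpoint),
         subtitle = sprintf("log-rank p = %.3g", object$p.value)) +
    theme_minimal()
}

#' Plot a restricted-cubic-spline dose-response curve
#'
#' Hazard-ratio curve with its 95% band, reference line at HR = 1 and
#' knot positions marked.
#'
#' @param object A [rcs_dose_response()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_spline <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$exposure, y = .data$hr)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                fill = "red", alpha = 0.15) +
    geom_line(colour = "red") +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "red") +
    geom_rug(data = tibble(exposure = object$knots, hr = 1),
             sides = "b") +
    scale_y_continuous(trans = "log") +
    labs(x = object$exposure, y = "Hazard ratio",
         title = sprintf("Dose-response (%s mortality, tier %s)",
                         object$endpoint, object$tier),
         subtitle = sprintf("nonlinearity p = %.3g", object$p_nonlinear)) +
    theme_minimal()
}

#' Plot a mediation decomposition
#'
#' Forest-style display of the total, direct and indirect hazard ratios
#' (with bootstrap CIs when present).
#'
#' @param object A [natural_effects()] or [bootstrap_mediation()] row.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_mediation <- function(object, ...) {
  eff <- tibble(
    effect = factor(c("Total", "Direct", "Mediation"),
                    levels = c("Mediation", "Direct", "Total")),
    hr = c(object$hr_te[1], object$hr_nde[1], object$hr_nie[1]),
    low = if ("hr_te_low" %in% names(object)) {
      c(object$hr_te_low[1], object$hr_nde_low[1], object$hr_nie_low[1])
    } else NA_real_,
    high = if ("hr_te_high" %in% names(object)) {
      c(object$hr_te_high[1], object$hr_nde_high[1], object$hr_nie_high[1])
    } else NA_real_)
  p <- ggplot(eff, aes(x = .data$hr, y = .data$effect)) +
    geom_point() +
    geom_vline(xintercept = 1, linetype = "dashed") +
    labs(x = "Hazard ratio", y = NULL,
         title = sprintf("%s -> %s -> %s", object$exposure[1],
                         object$mediator[1], object$endpoint[1]),
         subtitle = sprintf("proportion mediated = %.1f%%",
                            100 * object$prop_mediated[1])) +
    theme_minimal()
  if (all(is.finite(eff$low))) {
    p <- p + geom_errorbarh(aes(xmin = .data$low, xmax = .data$high),
                            height = 0.15)
  }
  p
}
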