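# broom-style accessors for the fitted objects.

#' @export
tidy.kdm_clock <- function(x, ...) {
  as_tibble(x$coefs)
}

#' @export
glance.kdm_clock <- function(x, ...) {
  tibble(n = x$n, n_biomarkers = nrow(x$coefs), s_ba = x$s_ba,
         s_ba_mode = x$s_ba_mode, convention = x$convention)
}

#' @export
tidy.phenoage_clock <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @export
glance.phenoage_clock <- function(x, ...) {
  tibble(n = x$n, events = x$events, gamma = x$gamma,
         horizon = x$horizon, logLik = x$loglik,
         rederived_constants = x$rederived)
}

#' @export
tidy.ba_medfit <- function(x, ...) {
  tibble(
    model = c(rep("mediator", 2L + length(x$beta2)), rep("outcome", 3L)),
    term = c("(Intercept)", "exposure", names(x$beta2),
             "exposure", "mediator", "exposure:mediator"),
    estimate = c(x$beta0, x$beta1, unname(x$beta2),
                 x$theta1, x$theta2, x$theta3))
}

#' @export
glance.ba_medfit <- function(x, ...) {
  tibble(n = x$n, events = x$events, sigma2 = x$sigma2,
         exposure = x$exposure, mediator = x$mediator,
         endpoint = x$endpoint, tier = x$tier)
}

#' @export
tidy.ba_spline <- function(x, ...) {
  as_tibble(x$curve)
}

#' @export
glance.ba_spline <- function(x, ...) {
  tibble(n = x$n, events = x$events, p_nonlinear = x$p_nonlinear,
         ref = x$ref, knot1 = x$knots[1], knot2 = x$knots[2],
         knot3 = x$knots[3], exposure = x$exposure, endpoint = x$endpoint,
         tier = x$tier)
}

#' @export
tidy.ba_km <- function(x, ...) {
  as_tibble(x$curves)
}

#' @export
glance.ba_km <- function(x, ...) {
  tibble(n = x$n, events = x$events, chisq = x$chisq, df = x$df,
         p.value = x$p.value, endpoint = x$endpoint, group = x$group)
}
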