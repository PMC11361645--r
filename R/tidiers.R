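#' Tidy and glance methods for fitted kinetics objects
#'
#' broom-style accessors: `tidy()` returns one row per model term with
#' estimates and standard errors; `glance()` returns a one-row model summary.
#'
#' @param x An `exp_fit` or `linear_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("rate", "amplitude", "offset"),
         estimate = c(x$rate, x$amplitude, x$offset),
         std.error = c(x$rate_stderr, NA_real_, NA_real_))
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(rate = x$rate, rate_stderr = x$rate_stderr,
         converged = x$converged, residual_rms = x$residual_rms,
         model = x$model, nobs = x$n)
}

#' @rdname tidy.exp_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_stderr, x$slope_stderr))
}

#' @rdname tidy.exp_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(k_on = x$slope, k_on_stderr = x$slope_stderr,
         intercept = x$intercept, r.squared = x$r_squared,
         flagged = x$flagged, nobs = x$n)
}

#' @rdname tidy.exp_fit
#' @export
tidy.kinetics_table <- function(x, ...) x$table
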