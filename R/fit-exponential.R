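new_exp_fit <- function(rate, amplitude, offset, rate_stderr, converged,
                        residual_rms, model, n) {
  structure(
    list(rate = rate, amplitude = amplitude, offset = offset,
         rate_stderr = rate_stderr, converged = converged,
         residual_rms = residual_rms, model = model, n = n),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: %s>\n", x$model))
  cat(sprintf("  rate      %.6g s^-1 (se %.3g)\n", x$rate, x$rate_stderr))
  cat(sprintf("  amplitude %.4g   offset %.4g\n", x$amplitude, x$offset))
  cat(sprintf("  converged %s   residual rms %.3g   n %d\n",
              x$converged, x$residual_rms, x$n))
  invisible(x)
}

# Direction of the noiseless trend, judged from the ends of the trace so that
# per-sample noise does not flip the sign: mean of the first vs last 10%.
trace_direction <- function(y) {
  k <- max(3L, ceiling(length(y) * 0.1))
  head_m <- mean(y[seq_len(k)])
  tail_m <- mean(y[seq.int(length(y) - k + 1L, length(y))])
  tail_m - head_m
}

# Log-linearized starting value for the rate of an exponential approach.
# w(t) = |plateau - y(t)| decays as e^(-k t); regress log w on t over the
# early part of the trace where w is well above the noise floor.
init_rate <- function(time_s, w, amplitude) {
  keep <- w > 0.05 * amplitude
  if (sum(keep) < 3L) return(NA_real_)
  fit <- lm(log(w[keep]) ~ time_s[keep])
  k <- -unname(coef(fit)[2])
  if (!is.finite(k) || k <= 0) NA_real_ else k
}

finish_exp_fit <- function(fit_obj, y, model) {
  if (is.null(fit_obj)) {
    return(new_exp_fit(NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                       NA_real_, model, length(y)))
  }
  est <- coef(fit_obj)
  se <- tryCatch(sqrt(diag(vcov(fit_obj))), error = function(e) est * NA)
  res <- stats::residuals(fit_obj)
  new_exp_fit(
    rate = unname(est[["k"]]),
    amplitude = unname(est[["A"]]),
    offset = unname(est[["F0"]]),
    rate_stderr = unname(se[["k"]]),
    converged = TRUE,
    residual_rms = sqrt(mean(res^2)),
    model = model, n = length(y))
}

check_trace_input <- function(trace, expected_mode) {
  if (!all(c("time_s", "signal_au") %in% names(trace))) {
    abort_input("A trace needs `time_s` and `signal_au` columns.")
  }
  if (nrow(trace) < 10L) abort_input("Need at least 10 samples to fit.")
  mode <- attr(trace, "mode")
  if (!is.null(mode) && !identical(mode, expected_mode)) {
    abort_mode(sprintf("Trace mode is '%s' but a %s fit was requested.",
                       mode, expected_mode))
  }
}

#' Fit a single-exponential association trace
#'
#' Least-squares estimate of the pseudo-first-order observation model
#' \eqn{F(t) = F_0 + A (1 - e^{-k t})} by Levenberg–Marquardt, giving the
#' observed rate constant `k_obs` of a stopped-flow association trace.
#' Starting values: offset from the first sample, amplitude from the signal
#' range, rate from a log-linearized regression of the remaining approach to
#' plateau.
#'
#' @param trace A [fluor_trace] (or any tibble with `time_s`, `signal_au`)
#'   in association mode with at least 10 samples.
#' @return An `exp_fit` with fields `rate` (k_obs, s⁻¹), `amplitude`,
#'   `offset`, `rate_stderr`, `converged`, `residual_rms`. A flat
#'   (zero-amplitude) trace returns `converged = FALSE` rather than an error;
#'   a clearly decreasing signal raises a mode-mismatch error.
#' @seealso [fit_exponential_decay()], [fit_kon()], [tidy.exp_fit()]
#' @export
fit_exponential_association <- function(trace) {
  check_trace_input(trace, "association")
  t <- trace$time_s; y <- trace$signal_au
  rng <- diff(range(y))
  if (rng == 0 || sd(y) < 1e-12 * max(abs(y), 1)) {
    return(new_exp_fit(NA_real_, 0, y[1], NA_real_, FALSE, 0,
                       "association", length(y)))
  }
  dir <- trace_direction(y)
  if (dir < -0.25 * rng) {
    abort_mode("Signal decreases over the trace; expected an association (increasing) trace.")
  }
  F0 <- y[1]; A <- rng
  plateau <- max(y) + 0.05 * rng
  k0 <- init_rate(t, plateau - y, A)
  if (!is.finite(k0)) k0 <- 1 / (max(t) / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ F0 + A * (1 - exp(-k * t)),
                      start = list(F0 = F0, A = A, k = k0),
                      lower = c(-Inf, 0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  finish_exp_fit(fit, y, "association")
}

#' Fit a single-exponential dissociation trace
#'
#' Least-squares estimate of \eqn{F(t) = F_\infty + A e^{-k t}}, giving the
#' intrinsic dissociation rate constant `k_off` of a chase experiment.
#'
#' @inheritParams fit_exponential_association
#' @return An `exp_fit`; `offset` is the terminal fluorescence
#'   \eqn{F_\infty}. A clearly increasing signal raises a mode-mismatch
#'   error.
#' @export
fit_exponential_decay <- function(trace) {
  check_trace_input(trace, "dissociation")
  t <- trace$time_s; y <- trace$signal_au
  rng <- diff(range(y))
  if (rng == 0 || sd(y) < 1e-12 * max(abs(y), 1)) {
    return(new_exp_fit(NA_real_, 0, y[1], NA_real_, FALSE, 0,
                       "dissociation", length(y)))
  }
  dir <- trace_direction(y)
  if (dir > 0.25 * rng) {
    abort_mode("Signal increases over the trace; expected a dissociation (decreasing) trace.")
  }
  floor_est <- min(y) - 0.05 * rng
  A <- y[1] - floor_est
  k0 <- init_rate(t, y - floor_est, A)
  if (!is.finite(k0)) k0 <- 1 / (max(t) / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ F0 + A * exp(-k * t),
                      start = list(F0 = floor_est, A = A, k = k0),
                      lower = c(-Inf, 0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  finish_exp_fit(fit, y, "dissociation")
}

#' Fit the intrinsic GTP hydrolysis rate from an HPLC time course
#'
#' Single-parameter least-squares fit of the first-order decay
#' \eqn{f_{GTP}(t) = e^{-k_{cat} t}} to a GTP-fraction time course. The
#' amplitude is fixed at 1 because the data are fractions of an initially
#' fully GTP-loaded pool.
#'
#' @param tc A tibble with `time_s` and `gtp_fraction` columns (>= 3 points,
#'   fractions within \[0, 1\]), e.g. from
#'   [simulate_hydrolysis_timecourse()].
#' @return An `exp_fit` with `rate` = k_cat (s⁻¹), `amplitude = 1`,
#'   `offset = 0`. A course with no decay (all fractions equal) returns
#'   `rate = 0` with `converged = FALSE`.
#' @export
fit_kcat <- function(tc) {
  if (!all(c("time_s", "gtp_fraction") %in% names(tc))) {
    abort_input("A hydrolysis time course needs `time_s` and `gtp_fraction`.")
  }
  if (nrow(tc) < 3L) abort_input("Need at least 3 time points to fit k_cat.")
  y <- tc$gtp_fraction; t <- tc$time_s
  if (any(y < 0 | y > 1)) abort_input("GTP fractions must lie in [0, 1].")
  if (any(diff(t) <= 0)) abort_format("`time_s` must be strictly increasing.")
  if (diff(range(y)) < 1e-12) {
    return(new_exp_fit(0, 1, 0, NA_real_, FALSE, 0, "hydrolysis", length(y)))
  }
  pos <- y > 1e-6
  k0 <- if (sum(pos) >= 2L) {
    max(-unname(coef(lm(log(y[pos]) ~ 0 + t[pos]))[1]), 1e-8)
  } else 1 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-k * t), start = list(k = k0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_exp_fit(NA_real_, 1, 0, NA_real_, FALSE, NA_real_,
                       "hydrolysis", length(y)))
  }
  k <- unname(coef(fit)[["k"]])
  se <- tryCatch(sqrt(vcov(fit)[1, 1]), error = function(e) NA_real_)
  res <- stats::residuals(fit)
  new_exp_fit(k, 1, 0, se, TRUE, sqrt(mean(res^2)), "hydrolysis", length(y))
}
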