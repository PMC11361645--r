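#' Assemble an observed-rate series from fitted association traces
#'
#' Fits each trace of a concentration ladder with
#' [fit_exponential_association()] and collects the observed rate constants
#' into the `k_obs`-versus-concentration series that [fit_kon()] regresses.
#'
#' @param traces List of association-mode [fluor_trace] objects with
#'   `protein_conc_uM` metadata.
#' @return A `kobs_series` tibble with columns `protein_conc_uM`, `kobs`,
#'   `kobs_stderr`.
#' @export
kobs_series <- function(traces) {
  rows <- purrr::map(traces, function(tr) {
    conc <- attr(tr, "protein_conc_uM")
    if (is.null(conc)) {
      abort_input("Every trace needs `protein_conc_uM` metadata.")
    }
    f <- fit_exponential_association(tr)
    tibble(protein_conc_uM = conc, kobs = f$rate, kobs_stderr = f$rate_stderr)
  })
  out <- dplyr::bind_rows(rows)
  validate_kobs_series(out)
  class(out) <- c("kobs_series", class(out))
  out
}

#' @rdname kobs_series
#' @param x A data frame with columns `protein_conc_uM` and `kobs`
#'   (optionally `kobs_stderr`).
#' @export
as_kobs_series <- function(x) {
  x <- as_tibble(x)
  if (!"kobs_stderr" %in% names(x)) x$kobs_stderr <- NA_real_
  validate_kobs_series(x)
  class(x) <- c("kobs_series", setdiff(class(x), "kobs_series"))
  x
}

validate_kobs_series <- function(x) {
  if (!all(c("protein_conc_uM", "kobs") %in% names(x))) {
    abort_input("A kobs series needs `protein_conc_uM` and `kobs` columns.")
  }
  if (nrow(x) < 3L) abort_input("A kobs series needs >= 3 concentrations.")
  if (any(x$protein_conc_uM <= 0) || anyDuplicated(x$protein_conc_uM)) {
    abort_input("Concentrations must be positive and distinct.")
  }
  invisible(x)
}

#' Estimate k_on by linear regression of k_obs on protein concentration
#'
#' Under pseudo-first-order conditions the observed association rate is
#' affine in the protein concentration,
#' \eqn{k_{obs} = k_{on} [\mathrm{protein}] + k_{off}}, so the slope of an
#' ordinary least-squares line through the `(concentration, k_obs)` points is
#' the second-order association rate constant `k_on` and the intercept is a
#' consistency check against the directly measured `k_off`. The intercept is
#' left free rather than constrained.
#'
#' @param series A `kobs_series` (or data frame with `protein_conc_uM`,
#'   `kobs`) with >= 3 distinct concentrations.
#' @param strict If `TRUE`, a negative fitted slope is an error; otherwise it
#'   is returned flagged (`flagged = TRUE`).
#' @return A `linear_fit`: `slope` (k_on, µM⁻¹s⁻¹), `intercept` (s⁻¹),
#'   `slope_stderr`, `intercept_stderr`, `r_squared`, `flagged`, `n`.
#' @export
#' @examples
#' traces <- simulate_kobs_ladder(k_on = 0.044, k_off = 0.012,
#'                                noise_sd_frac = 0, seed = 1)
#' fit_kon(kobs_series(traces))
fit_kon <- function(series, strict = FALSE) {
  series <- if (inherits(series, "kobs_series")) series else
    as_kobs_series(series)
  fit <- lm(kobs ~ protein_conc_uM, data = series)
  # noiseless ladders fit perfectly; summary.lm warns about that, harmlessly
  s <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  flagged <- is.na(slope) || slope < 0
  if (flagged && strict) {
    abort_input("Negative fitted slope: k_obs does not increase with concentration.")
  }
  r2 <- s$r.squared
  structure(
    list(slope = slope,
         intercept = unname(coef(fit)[1]),
         slope_stderr = unname(s$coefficients[2, 2]),
         intercept_stderr = unname(s$coefficients[1, 2]),
         r_squared = min(max(r2, 0), 1),
         flagged = flagged,
         n = nrow(series)),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit: k_obs ~ protein concentration>\n")
  cat(sprintf("  slope (k_on) %.6g uM^-1 s^-1 (se %.3g)\n",
              x$slope, x$slope_stderr))
  cat(sprintf("  intercept    %.6g s^-1 (se %.3g)\n",
              x$intercept, x$intercept_stderr))
  cat(sprintf("  R^2 %.4f   n %d%s\n", x$r_squared, x$n,
              if (x$flagged) "   [flagged]" else ""))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' \eqn{K_d = k_{off} / k_{on}}, in µM when `k_off` is in s⁻¹ and `k_on` in
#' µM⁻¹s⁻¹. Lower `K_d` means higher affinity. When no association rate could
#' be measured (`k_on` absent or non-positive) the affinity is undefined and
#' a classed error is raised — mirroring "no binding observed" entries, which
#' are recorded as missing rather than zero.
#'
#' @param k_off Dissociation rate constant, s⁻¹ (>= 0).
#' @param k_on Association rate constant, µM⁻¹s⁻¹ (> 0).
#' @return `K_d` in µM.
#' @export
#' @examples
#' compute_kd(0.012, 0.044) # 0.273 uM
compute_kd <- function(k_off, k_on) {
  check_number(k_off, "k_off", min = 0)
  if (is.null(k_on) || length(k_on) != 1L || is.na(k_on)) {
    abort_affinity("K_d undefined: no association rate available (no binding observed).")
  }
  if (!is.numeric(k_on) || !is.finite(k_on) || k_on <= 0) {
    abort_affinity("K_d undefined: k_on must be > 0.")
  }
  k_off / k_on
}
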