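#' Parameter-recovery experiments: simulate, fit, summarize
#'
#' Replicated end-to-end simulations of the three kinetic experiments, each
#' run with a known generating constant and refitted by the package's own
#' estimators. These drive the recovery checks: at realistic noise the median
#' recovered constant should sit within a few percent of the generating one.
#'
#' * `recover_kon()` — per seed, simulates an association-trace concentration
#'   ladder, fits every trace, regresses `k_obs` on concentration and records
#'   the slope.
#' * `recover_koff()` — per seed, simulates one dissociation chase trace and
#'   fits the decay rate.
#' * `recover_kcat()` — per seed, simulates one hydrolysis time course
#'   (default six points out to three half-lives) and fits the decay.
#'
#' @param k_on,k_off,k_cat Generating rate constants.
#' @param seeds Integer seeds, one replicate per seed.
#' @param ladder_uM Protein concentrations for the association ladder.
#' @param reporter_conc Reporter concentration, µM.
#' @param noise_sd_frac Trace noise (fraction of amplitude).
#' @param noise_sd Absolute noise on GTP fractions.
#' @param n_points,t_max Hydrolysis sampling design (defaults: 6 points to
#'   three half-lives).
#' @return A tibble with one row per seed: `seed`, `estimate`,
#'   `rel_error` (signed, relative to the generating value).
#' @export
#' @examples
#' recover_koff(0.149, seeds = 1:5)
recover_kon <- function(k_on, k_off = 0.012, seeds = 1:20,
                        ladder_uM = c(1, 2, 4, 6, 8, 10),
                        reporter_conc = 0.2, noise_sd_frac = 0.01) {
  purrr::map_dfr(seeds, function(s) {
    traces <- simulate_kobs_ladder(
      k_on = k_on, k_off = k_off, ladder_uM = ladder_uM,
      reporter_conc = reporter_conc, noise_sd_frac = noise_sd_frac,
      seed = s * 1000L)
    est <- fit_kon(kobs_series(traces))$slope
    tibble(seed = s, estimate = est, rel_error = (est - k_on) / k_on)
  })
}

#' @rdname recover_kon
#' @export
recover_koff <- function(k_off, seeds = 1:20, noise_sd_frac = 0.01) {
  purrr::map_dfr(seeds, function(s) {
    tr <- simulate_dissociation_trace(k_off = k_off,
                                      noise_sd_frac = noise_sd_frac,
                                      seed = s * 1000L)
    est <- fit_exponential_decay(tr)$rate
    tibble(seed = s, estimate = est, rel_error = (est - k_off) / k_off)
  })
}

#' @rdname recover_kon
#' @export
recover_kcat <- function(k_cat, seeds = 1:20, noise_sd = 0.02, n_points = 6,
                         t_max = NULL) {
  if (is.null(t_max)) t_max <- 3 * log(2) / k_cat
  purrr::map_dfr(seeds, function(s) {
    tc <- simulate_hydrolysis_timecourse(k_cat = k_cat, t_max = t_max,
                                         n_points = n_points,
                                         noise_sd = noise_sd,
                                         seed = s * 1000L)
    est <- fit_kcat(tc)$rate
    tibble(seed = s, estimate = est, rel_error = (est - k_cat) / k_cat)
  })
}
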