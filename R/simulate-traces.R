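#' @rdname simulate_association_trace
#' @param time_s,signal_au Numeric vectors of equal length (seconds, arbitrary
#'   fluorescence units).
#' @param mode `"association"` or `"dissociation"`.
#' @param meta Named list of metadata stored as attributes
#'   (`protein_conc_uM`, `reporter_conc_uM`, `variant_label`, `seed`,
#'   `generating` — the ground-truth parameters for simulated traces).
#' @export
fluor_trace <- function(time_s, signal_au, mode, meta = list()) {
  if (!is.numeric(time_s) || !is.numeric(signal_au)) {
    abort_input("`time_s` and `signal_au` must be numeric.")
  }
  if (length(time_s) != length(signal_au)) {
    abort_input("`time_s` and `signal_au` must have equal length.")
  }
  if (length(time_s) < 10L) {
    abort_input("A fluorescence trace needs at least 10 samples.")
  }
  if (time_s[1] < 0) abort_input("`time_s` must start at >= 0 s.")
  if (any(diff(time_s) <= 0)) {
    abort_format("`time_s` must be strictly increasing.")
  }
  mode <- match.arg(mode, c("association", "dissociation"))
  out <- tibble(time_s = as.double(time_s), signal_au = as.double(signal_au))
  class(out) <- c("fluor_trace", class(out))
  attr(out, "mode") <- mode
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace: %s, %d samples, %.3g-%.3g s>\n",
              attr(x, "mode"), nrow(x), x$time_s[1], x$time_s[nrow(x)]))
  NextMethod()
}

#' Simulate a stopped-flow nucleotide association trace
#'
#' Generates the fluorescence increase observed when a fluorescent nucleotide
#' reporter (e.g. mdGDP or mGppNHp) binds a nucleotide-free GTPase under
#' pseudo-first-order conditions (protein in large excess over the reporter).
#' The noiseless observation model is
#' \deqn{F(t) = F_0 + A (1 - e^{-k_{obs} t}), \quad
#'       k_{obs} = k_{on} \cdot [\mathrm{protein}] + k_{off}}
#' with additive Gaussian noise of standard deviation
#' `noise_sd_frac * amplitude`.
#'
#' @param k_on Association rate constant, µM⁻¹s⁻¹ (>= 0).
#' @param k_off Dissociation rate constant, s⁻¹ (>= 0). `k_obs` must be > 0.
#' @param protein_conc Protein concentration, µM. Must be at least
#'   `5 * reporter_conc` for the pseudo-first-order approximation to hold;
#'   violating this raises a validity error.
#' @param reporter_conc Fluorescent reporter concentration, µM (default
#'   0.2 µM, the standard stopped-flow reporter concentration).
#' @param duration Acquisition window, s. Defaults to `5 / k_obs`, by which
#'   time >99% of the amplitude has developed.
#' @param n_samples Number of uniformly spaced samples (default 500).
#' @param noise_sd_frac Noise standard deviation as a fraction of the
#'   amplitude (default 0.01, i.e. 1%).
#' @param seed Integer seed; identical seeds give bitwise-identical traces.
#'   `NULL` uses (and advances) the caller's RNG stream.
#' @param f0 Baseline fluorescence, arbitrary units.
#' @param amplitude Fluorescence amplitude `A`, arbitrary units.
#' @param variant_label Free-text label carried in the metadata.
#'
#' @return A [fluor_trace] tibble (`time_s`, `signal_au`) with mode
#'   `"association"` and a `generating` attribute recording the ground truth
#'   (`k_on`, `k_off`, `k_obs`, `f0`, `amplitude`, `noise_sd_frac`).
#' @export
#' @examples
#' tr <- simulate_association_trace(k_on = 0.044, k_off = 0.012,
#'                                  protein_conc = 10, seed = 1)
#' attr(tr, "generating")$k_obs # 0.044 * 10 + 0.012 = 0.452
simulate_association_trace <- function(k_on, k_off, protein_conc,
                                       reporter_conc = 0.2,
                                       duration = NULL, n_samples = 500,
                                       noise_sd_frac = 0.01, seed = NULL,
                                       f0 = 0.5, amplitude = 1,
                                       variant_label = NA_character_) {
  check_number(k_on, "k_on", min = 0)
  check_number(k_off, "k_off", min = 0)
  check_number(protein_conc, "protein_conc", min = 0, strict_min = TRUE)
  check_number(reporter_conc, "reporter_conc", min = 0, strict_min = TRUE)
  check_number(noise_sd_frac, "noise_sd_frac", min = 0)
  check_number(amplitude, "amplitude", min = 0, strict_min = TRUE)
  n_samples <- check_count(n_samples, "n_samples", min = 10L)
  if (protein_conc < 5 * reporter_conc) {
    abort_validity(sprintf(
      "Pseudo-first-order condition violated: protein_conc (%g uM) must be >= 5 x reporter_conc (%g uM).",
      protein_conc, reporter_conc))
  }
  k_obs <- k_on * protein_conc + k_off
  if (k_obs <= 0) abort_input("k_obs = k_on*protein_conc + k_off must be > 0.")
  if (is.null(duration)) duration <- 5 / k_obs
  check_number(duration, "duration", min = 0, strict_min = TRUE)

  time_s <- seq(0, duration, length.out = n_samples)
  clean <- f0 + amplitude * (1 - exp(-k_obs * time_s))
  signal <- with_seed_scope(seed, {
    if (noise_sd_frac > 0) {
      clean + rnorm(n_samples, sd = noise_sd_frac * amplitude)
    } else clean
  })
  fluor_trace(time_s, signal, "association", meta = list(
    protein_conc_uM = protein_conc, reporter_conc_uM = reporter_conc,
    variant_label = variant_label, seed = seed,
    generating = list(k_on = k_on, k_off = k_off, k_obs = k_obs,
                      f0 = f0, amplitude = amplitude,
                      noise_sd_frac = noise_sd_frac)
  ))
}

#' Simulate a stopped-flow nucleotide dissociation (chase) trace
#'
#' Generates the fluorescence decay observed when GTPase pre-loaded with a
#' fluorescent nucleotide is mixed with a large (typically 200-fold) molar
#' excess of unlabeled nucleotide. Rebinding of the labeled nucleotide is
#' negligible, so the decay is single-exponential:
#' \deqn{F(t) = F_\infty + A e^{-k_{off} t}}
#' The half-life of the decaying component is `ln(2)/k_off`.
#'
#' @param k_off Dissociation rate constant, s⁻¹ (> 0).
#' @param duration Acquisition window, s (default `5 / k_off`).
#' @param f_inf Terminal fluorescence, arbitrary units.
#' @inheritParams simulate_association_trace
#' @return A [fluor_trace] with mode `"dissociation"` and ground truth in the
#'   `generating` attribute.
#' @export
simulate_dissociation_trace <- function(k_off, duration = NULL,
                                        n_samples = 500,
                                        noise_sd_frac = 0.01, seed = NULL,
                                        f_inf = 0.2, amplitude = 1,
                                        variant_label = NA_character_) {
  check_number(k_off, "k_off", min = 0, strict_min = TRUE)
  check_number(noise_sd_frac, "noise_sd_frac", min = 0)
  check_number(amplitude, "amplitude", min = 0, strict_min = TRUE)
  n_samples <- check_count(n_samples, "n_samples", min = 10L)
  if (is.null(duration)) duration <- 5 / k_off
  check_number(duration, "duration", min = 0, strict_min = TRUE)

  time_s <- seq(0, duration, length.out = n_samples)
  clean <- f_inf + amplitude * exp(-k_off * time_s)
  signal <- with_seed_scope(seed, {
    if (noise_sd_frac > 0) {
      clean + rnorm(n_samples, sd = noise_sd_frac * amplitude)
    } else clean
  })
  fluor_trace(time_s, signal, "dissociation", meta = list(
    variant_label = variant_label, seed = seed,
    generating = list(k_off = k_off, f_inf = f_inf, amplitude = amplitude,
                      noise_sd_frac = noise_sd_frac)
  ))
}

#' Simulate a stopped-flow concentration ladder
#'
#' Convenience wrapper generating one association trace per protein
#' concentration, the raw material of the `k_obs`-versus-concentration
#' regression from which `k_on` is read off as the slope. The default ladder
#' is \{1, 2, 4, 6, 8, 10\} µM with the reporter at 0.2 µM.
#'
#' @param ladder_uM Protein concentrations, µM (>= 3 distinct values).
#' @param seed Integer seed; trace `i` uses `seed + i - 1` so ladders are
#'   reproducible as a unit.
#' @inheritParams simulate_association_trace
#' @return A list of [fluor_trace] objects, one per concentration.
#' @export
simulate_kobs_ladder <- function(k_on, k_off, ladder_uM = c(1, 2, 4, 6, 8, 10),
                                 reporter_conc = 0.2, n_samples = 500,
                                 noise_sd_frac = 0.01, seed = NULL,
                                 variant_label = NA_character_) {
  if (length(ladder_uM) < 3L || anyDuplicated(ladder_uM) ||
      any(ladder_uM <= 0)) {
    abort_input("`ladder_uM` needs >= 3 distinct positive concentrations.")
  }
  purrr::map(seq_along(ladder_uM), function(i) {
    simulate_association_trace(
      k_on = k_on, k_off = k_off, protein_conc = ladder_uM[i],
      reporter_conc = reporter_conc, n_samples = n_samples,
      noise_sd_frac = noise_sd_frac,
      seed = if (is.null(seed)) NULL else seed + i - 1L,
      variant_label = variant_label)
  })
}

#' Simulate an HPLC GTP-hydrolysis time course
#'
#' Emulates the HPLC assay in which GTP-loaded GTPase is incubated and the
#' remaining GTP fraction measured at a handful of time points (six by
#' default, matching the assay design). Intrinsic hydrolysis is modeled as
#' first-order decay of the bound-GTP fraction,
#' \deqn{f_{GTP}(t) = e^{-k_{cat} t},}
#' ignoring nucleotide re-exchange during the assay (the assay itself is
#' summarized by a single observed rate constant per condition). Noise is
#' additive Gaussian on the fractions, clipped to \[0, 1\].
#'
#' @param k_cat Hydrolysis rate constant, s⁻¹ (>= 0).
#' @param t_max Last time point, s. Defaults to three half-lives
#'   (`3 * ln(2) / k_cat`); must be supplied when `k_cat = 0`.
#' @param n_points Number of time points including t = 0 (default 6, >= 3).
#' @param noise_sd Absolute Gaussian noise sd on the fractions (default 0.02).
#' @param seed Integer seed.
#' @return A tibble (`time_s`, `gtp_fraction`) of class `hydrolysis_tc` with
#'   a `generating` attribute.
#' @export
#' @examples
#' tc <- simulate_hydrolysis_timecourse(k_cat = 0.0015, noise_sd = 0, seed = 1)
#' tc # fraction 0.5 at t = ln(2)/0.0015 = 462.1 s
simulate_hydrolysis_timecourse <- function(k_cat, t_max = NULL, n_points = 6,
                                           noise_sd = 0.02, seed = NULL) {
  check_number(k_cat, "k_cat", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  n_points <- check_count(n_points, "n_points", min = 3L)
  if (is.null(t_max)) {
    if (k_cat <= 0) abort_input("`t_max` must be supplied when k_cat = 0.")
    t_max <- 3 * log(2) / k_cat
  }
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) ||
      t_max <= 0) {
    abort_input("`t_max` must be a single positive number of seconds.")
  }
  time_s <- seq(0, t_max, length.out = n_points)
  clean <- exp(-k_cat * time_s)
  frac <- with_seed_scope(seed, {
    if (noise_sd > 0) {
      pmin(pmax(clean + rnorm(n_points, sd = noise_sd), 0), 1)
    } else clean
  })
  out <- tibble(time_s = time_s, gtp_fraction = frac)
  class(out) <- c("hydrolysis_tc", class(out))
  attr(out, "generating") <- list(k_cat = k_cat, noise_sd = noise_sd)
  attr(out, "seed") <- seed
  out
}
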