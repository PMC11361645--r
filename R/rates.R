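#' Published TTN5 nucleotide-kinetics rate constants
#'
#' Returns the published rate constants for the Arabidopsis ARL2-like small
#' GTPase TTN5 and its classical switch mutants T30N (dominant-negative-type)
#' and Q70L (hydrolysis-impaired-type), transcribed from the printed values of
#' the source study. One row per variant x nucleotide:
#'
#' * `k_on_per_uM_s` — second-order association rate constant of the
#'   fluorescent nucleotide analog (mdGDP for GDP, mGppNHp for GTP), in
#'   µM⁻¹s⁻¹. `NA` for T30N with GppNHp, where no association could be
#'   observed in the stopped-flow experiment ("n.b.o."); this is a
#'   measurement limit, not a zero rate.
#' * `k_off_per_s` — intrinsic dissociation rate constant under a 200-fold
#'   excess unlabeled-nucleotide chase, in s⁻¹. Two different values were
#'   printed for T30N/mGppNHp dissociation (0.026 s⁻¹ in the association
#'   context, 0.004 s⁻¹ in the dissociation context); this table carries
#'   0.004 s⁻¹, the value paired with the dissociation measurements.
#' * `kcat_per_s` — intrinsic GTP hydrolysis rate constant from six-point
#'   HPLC GTP time courses, in s⁻¹ (one value per variant, repeated across
#'   nucleotide rows).
#' * `kd_printed_uM` — the printed equilibrium dissociation constant
#'   K_d = k_off/k_on, in µM. Kept alongside the rates because the printed
#'   K_d values were computed from unrounded rates: re-deriving K_d from the
#'   rounded printed rates reproduces them only to within a few percent.
#'
#' These values are a transcription of printed numbers, suitable as inputs to
#' [build_kinetics_table()], [cycle_parameters()] and the simulators; they are
#' not re-measured by this package.
#'
#' @return A tibble with columns `variant`, `nucleotide`, `k_on_per_uM_s`,
#'   `k_off_per_s`, `kcat_per_s`, `kd_printed_uM`.
#' @export
#' @examples
#' ttn5_rates()
ttn5_rates <- function() {
  path <- system.file("extdata", "ttn5_printed_rates.csv",
                      package = "gtpasekin", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    variant = readr::col_character(),
                    nucleotide = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

ttn5_rate_row <- function(variant, nucleotide) {
  rates <- ttn5_rates()
  row <- rates[rates$variant == variant & rates$nucleotide == nucleotide, ]
  if (nrow(row) != 1L) {
    abort_input(sprintf("No packaged rates for variant '%s' / nucleotide '%s'.",
                        variant, nucleotide))
  }
  row
}
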