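#' Rate constants of the three-state nucleotide cycle
#'
#' Bundles the five rate constants of the minimal GTPase nucleotide cycle
#' with states F (nucleotide-free), D (GDP-bound) and T (GTP-bound):
#' F + GDP ⇌ D (`k_on_gdp`, `k_off_gdp`), F + GTP ⇌ T (`k_on_gtp`,
#' `k_off_gtp`), and intrinsic hydrolysis T → D (`k_cat`; the product GDP
#' stays bound, the standard single-turnover scheme). Units: `k_on_*` in
#' µM⁻¹s⁻¹, the rest in s⁻¹.
#'
#' @param k_on_gdp,k_off_gdp,k_on_gtp,k_off_gtp,k_cat Nonnegative rate
#'   constants; both `k_on` values must be strictly positive.
#' @return A `cycle_parameters` list.
#' @export
#' @examples
#' cycle_parameters(0.044, 0.012, 0.029, 0.001, 0.0015) # wild-type TTN5
cycle_parameters <- function(k_on_gdp, k_off_gdp, k_on_gtp, k_off_gtp,
                             k_cat) {
  check_number(k_on_gdp, "k_on_gdp", min = 0, strict_min = TRUE)
  check_number(k_off_gdp, "k_off_gdp", min = 0)
  check_number(k_on_gtp, "k_on_gtp", min = 0, strict_min = TRUE)
  check_number(k_off_gtp, "k_off_gtp", min = 0)
  check_number(k_cat, "k_cat", min = 0)
  structure(list(k_on_gdp = k_on_gdp, k_off_gdp = k_off_gdp,
                 k_on_gtp = k_on_gtp, k_off_gtp = k_off_gtp, k_cat = k_cat),
            class = "cycle_parameters")
}

#' @rdname cycle_parameters
#' @param variant A variant in [ttn5_rates()] (`"WT"`, `"T30N"`, `"Q70L"`).
#'   The GppNHp rates stand in for the GTP state. Variants without a measured
#'   GTP-state association rate cannot be converted.
#' @export
ttn5_cycle_parameters <- function(variant = "WT") {
  gdp <- ttn5_rate_row(variant, "GDP")
  gtp <- ttn5_rate_row(variant, "GppNHp")
  if (is.na(gtp$k_on_per_uM_s)) {
    abort_input(sprintf(
      "Variant '%s' has no measured GTP-state association rate; cycle parameters undefined.",
      variant))
  }
  cycle_parameters(gdp$k_on_per_uM_s, gdp$k_off_per_s,
                   gtp$k_on_per_uM_s, gtp$k_off_per_s, gdp$kcat_per_s)
}

#' Cellular nucleotide pools
#'
#' Free GTP and GDP concentrations (µM), treated as constant: the nucleotide
#' pools are in vast excess over the protein, so binding does not deplete
#' them. Defaults of 500 µM GTP and 50 µM GDP reflect the roughly 10:1
#' GTP:GDP ratio of resting cells.
#'
#' @param gtp_uM,gdp_uM Nonnegative concentrations, not both zero.
#' @return A `nucleotide_pools` list.
#' @export
nucleotide_pools <- function(gtp_uM = 500, gdp_uM = 50) {
  check_number(gtp_uM, "gtp_uM", min = 0)
  check_number(gdp_uM, "gdp_uM", min = 0)
  if (gtp_uM == 0 && gdp_uM == 0) {
    abort_input("At least one nucleotide pool must be nonzero.")
  }
  structure(list(gtp_uM = gtp_uM, gdp_uM = gdp_uM),
            class = "nucleotide_pools")
}

state_distribution <- function(f_free, f_gdp, f_gtp) {
  out <- tibble(f_free = f_free, f_gdp = f_gdp, f_gtp = f_gtp)
  class(out) <- c("state_distribution", class(out))
  out
}

#' Closed-form steady state of the nucleotide cycle
#'
#' Solves the linear balance equations of the three-state cycle for the
#' stationary fractions of nucleotide-free (`f_free`), GDP-bound (`f_gdp`)
#' and GTP-bound (`f_gtp`) protein. With pseudo-first-order binding rates
#' \eqn{a_T = k_{on}^{GTP}[GTP]} and \eqn{a_D = k_{on}^{GDP}[GDP]}:
#' \deqn{T/F = a_T / (k_{off}^{GTP} + k_{cat}), \quad
#'       D/F = (a_D + k_{cat} \, T/F) / k_{off}^{GDP},}
#' normalized to sum to one. A GTPase with fast GDP release and slow
#' hydrolysis accumulates in the GTP-bound state even without GEF
#' stimulation; this function quantifies that prediction.
#'
#' Degenerate limits are handled explicitly: `k_off_gdp = 0` with any influx
#' into D makes D absorbing (`f_gdp = 1`); `k_off_gtp + k_cat = 0` with GTP
#' influx makes T absorbing (`f_gtp = 1`).
#'
#' @param p [cycle_parameters()].
#' @param pools [nucleotide_pools()].
#' @return A one-row `state_distribution` tibble (`f_free`, `f_gdp`,
#'   `f_gtp`), summing to 1.
#' @export
#' @examples
#' steady_state_distribution(ttn5_cycle_parameters("WT"))
steady_state_distribution <- function(p, pools = nucleotide_pools()) {
  stopifnot(inherits(p, "cycle_parameters"),
            inherits(pools, "nucleotide_pools"))
  a_t <- p$k_on_gtp * pools$gtp_uM
  a_d <- p$k_on_gdp * pools$gdp_uM
  out_t <- p$k_off_gtp + p$k_cat

  if (out_t == 0 && a_t > 0) return(state_distribution(0, 0, 1))
  tf <- if (a_t == 0) 0 else a_t / out_t
  influx_d <- a_d + p$k_cat * tf
  if (p$k_off_gdp == 0) {
    if (influx_d > 0) return(state_distribution(0, 1, 0))
    df <- 0
  } else {
    df <- influx_d / p$k_off_gdp
  }
  tot <- 1 + df + tf
  state_distribution(1 / tot, df / tot, tf / tot)
}

cycle_rate_matrix <- function(p, pools) {
  a_t <- p$k_on_gtp * pools$gtp_uM
  a_d <- p$k_on_gdp * pools$gdp_uM
  # d/dt (F, D, T) = M %*% (F, D, T)
  matrix(c(-(a_d + a_t), p$k_off_gdp,              p$k_off_gtp,
           a_d,          -p$k_off_gdp,             p$k_cat,
           a_t,          0,                        -(p$k_off_gtp + p$k_cat)),
         nrow = 3, byrow = TRUE)
}

#' Integrate the nucleotide-cycle ODE
#'
#' Numerically integrates the three-state cycle from an initial distribution,
#' serving as an independent oracle for [steady_state_distribution()]: for
#' any initial condition the trajectory relaxes to the closed-form steady
#' state. Mass is conserved (fractions sum to 1 along the whole trajectory).
#'
#' @inheritParams steady_state_distribution
#' @param init Numeric vector `(f_free, f_gdp, f_gtp)` summing to 1.
#' @param t_end End time, s. `NULL` picks a horizon long enough for complete
#'   relaxation (40 times the slowest relaxation time, from the eigenvalues
#'   of the rate matrix).
#' @param n_steps Number of saved time points.
#' @return A `cycle_trajectory` tibble (`time_s`, `f_free`, `f_gdp`,
#'   `f_gtp`).
#' @export
integrate_cycle <- function(p, pools = nucleotide_pools(),
                            init = c(1, 0, 0), t_end = NULL, n_steps = 200) {
  stopifnot(inherits(p, "cycle_parameters"),
            inherits(pools, "nucleotide_pools"))
  if (length(init) != 3L || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    abort_input("`init` must be 3 nonnegative fractions summing to 1.")
  }
  m <- cycle_rate_matrix(p, pools)
  if (is.null(t_end)) {
    ev <- Re(eigen(m, only.values = TRUE)$values)
    relax <- abs(ev[abs(ev) > 1e-14])
    t_end <- if (length(relax) == 0) 1 else 40 / min(relax)
  }
  check_number(t_end, "t_end", min = 0, strict_min = TRUE)
  times <- seq(0, t_end, length.out = n_steps)
  deriv <- function(t, y, parms) list(as.vector(m %*% y))
  sol <- deSolve::lsoda(y = init, times = times, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    abort(paste0("ODE integration failed: ",
                 paste(attr(sol, "istate"), collapse = " ")),
          class = c("gtpasekin_ode_error", "gtpasekin_error"))
  }
  out <- tibble(time_s = sol[, 1], f_free = sol[, 2], f_gdp = sol[, 3],
                f_gtp = sol[, 4])
  class(out) <- c("cycle_trajectory", class(out))
  out
}

#' Classify a GTPase as classical or non-classical (GTP-loaded)
#'
#' Operationalizes the qualitative criterion that a GTPase with fast
#' intrinsic GDP release and slow intrinsic hydrolysis accumulates in the
#' active GTP-bound form without GEF stimulation. Reports:
#' * `r1 = k_off_gdp / k_cat` — exchange-versus-hydrolysis ratio;
#' * `r2 = K_d(GDP) / K_d(GTP)` — relative nucleotide affinity;
#' * `f_gtp` — steady-state GTP-bound fraction under the given pools.
#'
#' The label is `"non_classical_GTP_loaded"` when `r1 >= thresholds$r1`
#' (default 5) and `f_gtp > thresholds$f_gtp` (default 0.5), else
#' `"classical"`. `k_cat = 0` makes `r1` undefined; the label is then forced
#' non-classical with reason `"hydrolysis_rate_zero"`. The thresholds are
#' package definitions operationalizing a verbal criterion, not measured
#' quantities.
#'
#' @inheritParams steady_state_distribution
#' @param thresholds List with elements `r1` and `f_gtp`.
#' @return A one-row tibble: `label`, `r1`, `r2`, `f_gtp`, `reason`.
#' @export
#' @examples
#' classify_gtpase(ttn5_cycle_parameters("WT")) # non_classical_GTP_loaded
classify_gtpase <- function(p, pools = nucleotide_pools(),
                            thresholds = list(r1 = 5, f_gtp = 0.5)) {
  stopifnot(inherits(p, "cycle_parameters"))
  ss <- steady_state_distribution(p, pools)
  r2 <- (p$k_off_gdp / p$k_on_gdp) / (p$k_off_gtp / p$k_on_gtp)
  if (p$k_cat == 0) {
    return(tibble(label = "non_classical_GTP_loaded", r1 = NA_real_,
                  r2 = r2, f_gtp = ss$f_gtp,
                  reason = "hydrolysis_rate_zero"))
  }
  r1 <- p$k_off_gdp / p$k_cat
  non_classical <- r1 >= thresholds$r1 && ss$f_gtp > thresholds$f_gtp
  tibble(label = if (non_classical) "non_classical_GTP_loaded" else
           "classical",
         r1 = r1, r2 = r2, f_gtp = ss$f_gtp, reason = NA_character_)
}
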