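test_that("steady state handles symmetry and degenerate limits", {
  # no hydrolysis + symmetric rates + equal pools: D and T equally occupied
  sym <- cycle_parameters(0.05, 0.01, 0.05, 0.01, 0)
  ss <- steady_state_distribution(sym, nucleotide_pools(100, 100))
  expect_equal(ss$f_gdp, ss$f_gtp, tolerance = 1e-12)
  expect_equal(ss$f_free + ss$f_gdp + ss$f_gtp, 1, tolerance = 1e-12)
  # no GTP influx and no hydrolysis: nothing reaches T
  ss0 <- steady_state_distribution(cycle_parameters(0.05, 0.01, 0.05, 0.01, 0),
                                   nucleotide_pools(0, 100))
  expect_equal(ss0$f_gtp, 0)
  # absorbing GDP state when k_off_gdp = 0 with GDP influx
  ssd <- steady_state_distribution(cycle_parameters(0.05, 0, 0.05, 0.01, 0),
                                   nucleotide_pools(100, 100))
  expect_equal(ssd$f_gdp, 1)
})

test_that("wild-type TTN5 parameters predict a mostly GTP-loaded steady state", {
  ss <- steady_state_distribution(wt_params(), nucleotide_pools(500, 50))
  expect_equal(ss$f_gtp, 0.86, tolerance = 0.01)
  expect_equal(ss$f_free + ss$f_gdp + ss$f_gtp, 1, tolerance = 1e-12)
})

test_that("closed form equals long-horizon ODE integration over a random sweep", {
  set.seed(20260101)
  for (i in 1:100) {
    rates <- 10^runif(5, -4, 0) # log-uniform in [1e-4, 1]
    p <- cycle_parameters(rates[1], rates[2], rates[3], rates[4], rates[5])
    pools <- nucleotide_pools(10^runif(1, 0, 3), 10^runif(1, 0, 3))
    init <- c(1, 0, 0)
    traj <- integrate_cycle(p, pools, init = init, n_steps = 5)
    ss <- steady_state_distribution(p, pools)
    terminal <- unlist(traj[nrow(traj), c("f_free", "f_gdp", "f_gtp")])
    expect_equal(unname(terminal),
                 c(ss$f_free, ss$f_gdp, ss$f_gtp), tolerance = 1e-6)
    # mass conserved along the whole trajectory
    expect_true(all(abs(rowSums(traj[, -1]) - 1) < 1e-9))
  }
})

test_that("the steady state is a fixed point of the dynamics", {
  p <- wt_params()
  ss <- steady_state_distribution(p)
  traj <- integrate_cycle(p, init = c(ss$f_free, ss$f_gdp, ss$f_gtp),
                          t_end = 1000, n_steps = 20)
  expect_true(all(abs(traj$f_gtp - ss$f_gtp) < 1e-8))
  expect_true(all(abs(traj$f_gdp - ss$f_gdp) < 1e-8))
})

test_that("hydrolysis-only transfer from T to D is monotone", {
  # negligible binding/release: the only live channel is T -> D at k_cat
  p <- cycle_parameters(1e-9, 0, 1e-9, 0, 0.05)
  traj <- integrate_cycle(p, nucleotide_pools(1e-3, 1e-3),
                          init = c(0, 0, 1), t_end = 200, n_steps = 50)
  expect_true(all(diff(traj$f_gtp) <= 1e-12))
  expect_true(all(diff(traj$f_gdp) >= -1e-12))
  expect_equal(traj$f_gtp, exp(-0.05 * traj$time_s), tolerance = 1e-6)
})

test_that("steady-state occupancy respects physical limits and monotonicity", {
  base <- wt_params()
  # k_cat -> large drains T
  fast_hydro <- cycle_parameters(0.044, 0.012, 0.029, 0.001, 1e4)
  expect_lt(steady_state_distribution(fast_hydro)$f_gtp, 1e-3)
  # [GTP] -> large saturates T only up to the hydrolysis-recycling limit:
  # bound GTP keeps converting to bound GDP, so the ceiling is
  # k_off_gdp / (k_off_gdp + k_cat); with hydrolysis off the ceiling is 1
  big_gtp <- steady_state_distribution(base, nucleotide_pools(1e9, 50))
  ceiling_wt <- 0.012 / (0.012 + 0.0015)
  expect_equal(big_gtp$f_gtp, ceiling_wt, tolerance = 1e-4)
  no_hydro <- cycle_parameters(0.044, 0.012, 0.029, 0.001, 0)
  expect_gt(steady_state_distribution(no_hydro,
                                      nucleotide_pools(1e9, 50))$f_gtp,
            0.999)
  # monotone in [GTP] and in k_cat
  f_gtp_at <- function(gtp) {
    steady_state_distribution(base, nucleotide_pools(gtp, 50))$f_gtp
  }
  gtp_grid <- c(1, 10, 100, 1000, 1e4)
  expect_true(all(diff(vapply(gtp_grid, f_gtp_at, numeric(1))) >= 0))
  f_gtp_kcat <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(kc) {
    p <- cycle_parameters(0.044, 0.012, 0.029, 0.001, kc)
    steady_state_distribution(p)$f_gtp
  }, numeric(1))
  expect_true(all(diff(f_gtp_kcat) <= 0))
})

test_that("classification separates GTP-loaded from classical kinetics", {
  wt <- classify_gtpase(wt_params())
  expect_equal(wt$label, "non_classical_GTP_loaded")
  expect_equal(wt$r1, 8)
  expect_gt(wt$f_gtp, 0.5)

  slow <- classify_gtpase(slow_exchange_params())
  expect_equal(slow$label, "classical")
  expect_gt(steady_state_distribution(slow_exchange_params())$f_gdp, 0.95)

  nohydro <- classify_gtpase(cycle_parameters(0.044, 0.012, 0.029, 0.001, 0))
  expect_equal(nohydro$label, "non_classical_GTP_loaded")
  expect_true(is.na(nohydro$r1))
  expect_equal(nohydro$reason, "hydrolysis_rate_zero")
})

test_that("cycle inputs are validated", {
  expect_error(cycle_parameters(0, 0.01, 0.05, 0.01, 0),
               class = "gtpasekin_input_error")
  expect_error(nucleotide_pools(0, 0), class = "gtpasekin_input_error")
  expect_error(integrate_cycle(wt_params(), init = c(0.5, 0.5, 0.5)),
               class = "gtpasekin_input_error")
})
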