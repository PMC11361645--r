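test_that("noiseless association traces follow the pseudo-first-order model exactly", {
  cases <- list(
    list(k_on = 0.044, k_off = 0.012, conc = 10, k_obs = 0.452),
    list(k_on = 0,     k_off = 0.012, conc = 10, k_obs = 0.012),
    list(k_on = 0.401, k_off = 0.025, conc = 4,  k_obs = 0.401 * 4 + 0.025))
  for (cs in cases) {
    tr <- simulate_association_trace(cs$k_on, cs$k_off, cs$conc,
                                     noise_sd_frac = 0, seed = 1)
    g <- attr(tr, "generating")
    expect_equal(g$k_obs, cs$k_obs, tolerance = 1e-15)
    expected <- g$f0 + g$amplitude * (1 - exp(-g$k_obs * tr$time_s))
    expect_equal(tr$signal_au, expected, tolerance = 1e-12)
    expect_true(all(diff(tr$signal_au) >= 0))
    expect_gte(tr$time_s[1], 0)
    expect_gte(nrow(tr), 10)
  }
})

test_that("noiseless dissociation trace decays with the stated half-life", {
  tr <- simulate_dissociation_trace(0.149, noise_sd_frac = 0, seed = 1,
                                    n_samples = 2000, duration = 40)
  g <- attr(tr, "generating")
  expect_equal(tr$signal_au, g$f_inf + g$amplitude * exp(-0.149 * tr$time_s),
               tolerance = 1e-12)
  expect_true(all(diff(tr$signal_au) <= 0))
  # half of the decaying amplitude remains at t = ln2/k = 4.652 s
  t_half <- log(2) / 0.149
  idx <- which.min(abs(tr$time_s - t_half))
  expect_equal(tr$signal_au[idx] - g$f_inf, g$amplitude / 2, tolerance = 1e-2)
  # long-horizon limit: terminal signal within 0.1% of A above F_inf
  tr2 <- simulate_dissociation_trace(0.012, duration = 1000,
                                     noise_sd_frac = 0, seed = 1)
  g2 <- attr(tr2, "generating")
  expect_lt(abs(tr2$signal_au[nrow(tr2)] - g2$f_inf), 1e-3 * g2$amplitude)
})

test_that("generators are pure functions of their arguments including seed", {
  a1 <- simulate_association_trace(0.044, 0.012, 10, seed = 7)
  a2 <- simulate_association_trace(0.044, 0.012, 10, seed = 7)
  expect_identical(a1$signal_au, a2$signal_au)
  d1 <- simulate_dissociation_trace(0.149, seed = 7)
  d2 <- simulate_dissociation_trace(0.149, seed = 7)
  expect_identical(d1$signal_au, d2$signal_au)
  h1 <- simulate_hydrolysis_timecourse(0.0015, seed = 7)
  h2 <- simulate_hydrolysis_timecourse(0.0015, seed = 7)
  expect_identical(h1$gtp_fraction, h2$gtp_fraction)
  p1 <- generate_image_pair(10, 0.5, seed = 7)
  p2 <- generate_image_pair(10, 0.5, seed = 7)
  expect_identical(p1$channel_a, p2$channel_a)
  # different seeds differ
  expect_false(identical(
    a1$signal_au,
    simulate_association_trace(0.044, 0.012, 10, seed = 8)$signal_au))
  # and the caller's RNG stream is untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_association_trace(0.044, 0.012, 10, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("trace noise is additive Gaussian scaled by the amplitude", {
  tr <- simulate_dissociation_trace(0.149, noise_sd_frac = 0.01, seed = 42,
                                    n_samples = 5000)
  g <- attr(tr, "generating")
  clean <- g$f_inf + g$amplitude * exp(-0.149 * tr$time_s)
  resid <- tr$signal_au - clean
  expect_equal(sd(resid), 0.01 * g$amplitude, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 3 * 0.01 / sqrt(5000))
})

test_that("generating k_obs is affine in concentration with slope k_on over a ladder", {
  for (k_on in c(0.02, 0.044, 0.1, 0.25, 0.401)) {
    traces <- simulate_kobs_ladder(k_on, 0.012, noise_sd_frac = 0, seed = 1)
    kobs <- vapply(traces, function(tr) attr(tr, "generating")$k_obs,
                   numeric(1))
    conc <- vapply(traces, function(tr) attr(tr, "protein_conc_uM"),
                   numeric(1))
    fit <- ols_by_hand(conc, kobs)
    expect_equal(unname(fit["slope"]), k_on, tolerance = 1e-12)
    expect_equal(unname(fit["intercept"]), 0.012, tolerance = 1e-12)
  }
})

test_that("hydrolysis time courses lie on the exponential and respect bounds", {
  tc <- simulate_hydrolysis_timecourse(0.0015, noise_sd = 0, seed = 1)
  expect_equal(nrow(tc), 6)
  expect_equal(tc$gtp_fraction, exp(-0.0015 * tc$time_s), tolerance = 1e-12)
  # fraction 0.5 at one half-life (462.1 s); default t_max is 3 half-lives
  expect_equal(exp(-0.0015 * log(2) / 0.0015), 0.5, tolerance = 1e-12)
  expect_equal(max(tc$time_s), 3 * log(2) / 0.0015, tolerance = 1e-9)
  # zero hydrolysis: flat at 1
  tc0 <- simulate_hydrolysis_timecourse(0, t_max = 100, noise_sd = 0)
  expect_true(all(tc0$gtp_fraction == 1))
  # noisy fractions stay in [0, 1]
  tcn <- simulate_hydrolysis_timecourse(0.0015, noise_sd = 0.5, seed = 2)
  expect_true(all(tcn$gtp_fraction >= 0 & tcn$gtp_fraction <= 1))
})

test_that("generator preconditions are enforced with classed errors", {
  expect_error(simulate_association_trace(0.044, 0.012, protein_conc = 0.5,
                                          reporter_conc = 0.2),
               class = "gtpasekin_validity_error")
  expect_error(simulate_association_trace(0.044, 0.012, 10, duration = -1),
               class = "gtpasekin_input_error")
  expect_error(simulate_association_trace(-0.1, 0.012, 10),
               class = "gtpasekin_input_error")
  expect_error(simulate_dissociation_trace(0),
               class = "gtpasekin_input_error")
  expect_error(simulate_hydrolysis_timecourse(0.0015, t_max = -5),
               class = "gtpasekin_input_error")
  expect_error(simulate_hydrolysis_timecourse(0.0015, n_points = 2),
               class = "gtpasekin_input_error")
})
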