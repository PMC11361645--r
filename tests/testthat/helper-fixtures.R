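# Shared fixtures, all generated in code at test time.

wt_params <- function() cycle_parameters(0.044, 0.012, 0.029, 0.001, 0.0015)

# Slow-exchange comparator: GDP release orders of magnitude slower than
# hydrolysis, the classical-GTPase regime.
slow_exchange_params <- function() {
  cycle_parameters(0.044, 1e-5, 0.029, 0.001, 1e-3)
}

noiseless_ladder <- function(k_on = 0.044, k_off = 0.012) {
  simulate_kobs_ladder(k_on, k_off, noise_sd_frac = 0, seed = 1)
}

# Closed-form OLS slope/intercept, independent of lm(): the brute-force
# normal-equation solution.
ols_by_hand <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(slope = slope, intercept = yb - slope * xb)
}
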