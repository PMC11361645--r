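# gtpasekin

Kinetic analysis of small-GTPase nucleotide exchange and hydrolysis, built
around the Arabidopsis ARL2-like GTPase **TTN5** and its switch mutants
T30N and Q70L.

Small GTPases cycle between an inactive GDP-bound and an active GTP-bound
state. Which state dominates in a resting cell is set by four intrinsic rate
constants per nucleotide plus the hydrolysis rate:

- **k_on** (µM⁻¹s⁻¹): nucleotide association. Measured by stopped-flow
  fluorimetry — a fluorescent nucleotide analog (mdGDP or mGppNHp) is mixed
  with nucleotide-free protein in excess, so the fluorescence rise is a
  single exponential with observed rate `k_obs = k_on·[protein] + k_off`;
  `k_on` is the slope of `k_obs` over a protein-concentration ladder.
- **k_off** (s⁻¹): intrinsic nucleotide dissociation, measured as the
  exponential fluorescence decay under a 200-fold unlabeled-nucleotide chase.
- **K_d = k_off / k_on** (µM): nucleotide affinity.
- **k_cat** (s⁻¹): intrinsic GTP hydrolysis, fitted as first-order decay of
  the GTP fraction in an HPLC time course (six points by default).

A GTPase whose GDP release is much faster than its hydrolysis
(`k_off(GDP)/k_cat` large) accumulates GTP-loaded without any GEF — the
"non-classical" regime TTN5 falls into (`k_off/k_cat = 0.012/0.0015 = 8`).
The package formalizes that argument as a three-state cycle model
(free ⇌ GDP-bound, free ⇌ GTP-bound, GTP→GDP hydrolysis) with a closed-form
steady state, an ODE oracle, and a classifier.

The package provides, as tidyverse-style functions over tibbles:

- **Simulators** for association/dissociation traces, hydrolysis time
  courses, and two-channel punctate images with known ground-truth
  colocalization — all seeded and exact in the noiseless limit.
- **Estimators**: exponential trace fits (`fit_exponential_association()`,
  `fit_exponential_decay()`), the `k_obs` regression (`fit_kon()`),
  hydrolysis fits (`fit_kcat()`), affinities (`compute_kd()`), and a
  kinetics summary table with fold changes (`build_kinetics_table()`).
- **Cycle model**: `steady_state_distribution()`, `integrate_cycle()`,
  `classify_gtpase()`.
- **Colocalization**: `pearson_coefficient()`, `overlap_coefficient()`,
  `segment_objects()` (mean + 2·sd threshold, 8-connectivity),
  `object_based_colocalization()` (greedy centroid matching, both
  directions), `coloc_analyze()`.
- The published TTN5 rate constants as a packaged table (`ttn5_rates()`),
  broom-style `tidy()`/`glance()` methods, `autoplot()` methods, and a CLI
  (`run_cli()`, wrapper script in `inst/cli/`).

## Worked example

Simulate a wild-type mdGDP association ladder at 1% noise, recover `k_on`,
and classify the nucleotide cycle:

```r
library(gtpasekin)

traces <- simulate_kobs_ladder(k_on = 0.044, k_off = 0.012, seed = 1)
series <- kobs_series(traces)   # fit each trace, collect k_obs
fit_kon(series)
#> <linear_fit: k_obs ~ protein concentration>
#>   slope (k_on) 0.0438313 uM^-1 s^-1 (se 0.000138)
#>   intercept    0.0123505 s^-1 (se 0.000837)
#>   R^2 1.0000   n 6

compute_kd(k_off = 0.012, k_on = 0.0438)
#> [1] 0.274

classify_gtpase(ttn5_cycle_parameters("WT"))
#>                      label r1   r2 f_gtp reason
#> 1 non_classical_GTP_loaded  8 7.91 0.864   <NA>
```

The recovered slope (0.0438 µM⁻¹s⁻¹) sits within 0.4% of the generating
`k_on`; the fitted intercept (0.0124 s⁻¹) agrees with the generating
`k_off`, the built-in consistency check of the free-intercept regression.
The derived affinity (0.274 µM) matches the published wild-type mdGDP K_d
(0.267 µM) to within the rounding of the printed rates. Under resting-cell
nucleotide pools (500 µM GTP, 50 µM GDP) the cycle model predicts 86% of the
protein GTP-loaded, hence the non-classical label.

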