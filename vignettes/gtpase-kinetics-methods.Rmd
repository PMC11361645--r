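---
title: "Models and methods behind gtpasekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gtpasekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtpasekin)
```

gtpasekin packages the quantitative core of an in vitro characterization of
the Arabidopsis ARL2-like small GTPase TTN5: stopped-flow nucleotide binding
kinetics, HPLC hydrolysis kinetics, a nucleotide-cycle occupancy model, and
the colocalization statistics applied to its imaging data. This vignette
explains each model, the assumptions behind it, the defaults we chose where
the experimental protocol leaves freedom, and what the synthetic-data tests
do and do not establish.

## Stopped-flow observation models

**Association.** Nucleotide-free GTPase in excess over a fluorescent
nucleotide reporter binds under pseudo-first-order conditions, so the
fluorescence rise is a single exponential

$$F(t) = F_0 + A\,(1 - e^{-k_{obs} t}), \qquad
  k_{obs} = k_{on}\,[\text{protein}] + k_{off}.$$

`simulate_association_trace()` enforces the excess condition
([protein] ≥ 5 × [reporter]) as a hard validity error: below it the
pseudo-first-order linearization is not trustworthy and a fitted $k_{obs}$
would be biased. The reporter default is 0.2 µM, the concentration used in
the stopped-flow protocol.

**Dissociation.** A chase with a large (200-fold) excess of unlabeled
nucleotide makes rebinding of the labeled nucleotide negligible, so the decay
is $F(t) = F_\infty + A e^{-k_{off} t}$ with half-life $\ln 2 / k_{off}$.
The chase is modeled as fully irreversible; no rebinding correction is
applied.

**Concentration ladder.** The exact protein concentrations used per variant
are not part of the printed protocol, so the default ladder is
{1, 2, 4, 6, 8, 10} µM — six points spanning one order of magnitude, the
shape a stopped-flow titration typically takes — and it is configurable
everywhere it is used. `fit_kon()` regresses $k_{obs}$ on concentration with
a **free intercept**: theory predicts the intercept equals $k_{off}$, and
leaving it free both avoids biasing the slope if the intercept is slightly
off and turns the intercept into a consistency check against the directly
measured dissociation rate.

**Noise model.** Instrument noise is not quantified in the protocol. We use
additive Gaussian noise with standard deviation proportional to the
amplitude, default 1%, chosen so that parameter recovery is a nontrivial
statistical problem (fits have meaningful standard errors) while remaining
stable across seeds. Real stopped-flow noise has shot-noise and drift
components this ignores; see "What the synthetic data does not emulate".

**Sampling schedule.** Default acquisition window 5/$k_{obs}$ (≥ 99% of the
amplitude developed) with 500 uniform samples; the protocol states no
acquisition rate. Recovery quality depends mainly on the window covering the
curvature of the exponential, not on the sample count.

## Fitting

All exponential fits are Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`, up to 200 iterations). Starting values are derived
from the data: offset from the first (association) or an underestimate of
the terminal (dissociation) sample, amplitude from the signal range, and
rate from a log-linear regression of the remaining distance to plateau —
the standard linearization of an exponential. Fits that fail to converge
are returned flagged (`converged = FALSE`) rather than raised as errors, so
ladder pipelines can skip bad traces; zero-amplitude (flat) traces are
flagged without attempting a fit. A trace whose trend contradicts the
requested direction (decreasing signal passed to the association fit, or
vice versa) raises a mode-mismatch error, judged from the first versus last
10% of samples so single-sample noise cannot flip the decision.

Standard errors come from the local curvature of the least-squares
objective (the usual asymptotic covariance of `nls`), matching how fitted
rate errors are commonly reported by commercial fitting software.

The hydrolysis fit is single-parameter: GTP fractions start at 1 by
construction, so `fit_kcat()` fits $e^{-k_{cat} t}$ with fixed unit
amplitude. Hydrolysis is modeled as single-exponential decay of total GTP,
ignoring re-exchange of nucleotide during the assay — consistent with the
assay itself being summarized by one observed rate constant per condition.

**Affinities.** $K_d = k_{off}/k_{on}$ exactly (`compute_kd()`). A condition
where no association could be observed (TTN5^T30N with mGppNHp) is stored as
a missing $k_{on}$ — never as zero — and forces a missing $K_d$; asking for
it raises a classed undefined-affinity error.

**The kinetics table.** `build_kinetics_table()` derives the $K_d$ column
strictly as $k_{off}/k_{on}$ from its rate entries. Fold changes are
quotients of table entries, with one deliberate refinement: affinity ratios
use the *published* $K_d$ entries (`kd_printed_uM` in `ttn5_rates()`) when
both operands have one. Published affinities were computed from unrounded
rates, so a ratio of re-derived affinities compounds the rounding of four
printed rates; the wild-type GDP-versus-GppNHp affinity ratio, for example,
is 9.2 from the published affinities but 7.9 from the rounded printed rates.
Where a published affinity is unavailable the computed one is used. When
"matches the published value" is asserted in tests, the tolerance is 5%
relative, because printed rate constants carry 2–3 significant figures
before ratios are formed.

A note on the packaged data: two different dissociation rates are printed
for TTN5^T30N with mGppNHp (0.026 s⁻¹ in the association context, 0.004 s⁻¹
in the dissociation context). `ttn5_rates()` carries 0.004 s⁻¹, the value
belonging to the dissociation measurements whose ratios (the 37-fold
GDP/GppNHp difference) the table reproduces; the discrepancy is documented
rather than reconciled.

## The three-state nucleotide cycle

States: nucleotide-free (F), GDP-bound (D), GTP-bound (T), with
pseudo-first-order binding from clamped nucleotide pools:

$$F \xrightleftharpoons[k_{off}^{GDP}]{k_{on}^{GDP}[GDP]} D, \qquad
  F \xrightleftharpoons[k_{off}^{GTP}]{k_{on}^{GTP}[GTP]} T, \qquad
  T \xrightarrow{k_{cat}} D.$$

Assumptions: (i) pools are constant — protein is scarce relative to cellular
nucleotide, so binding does not deplete the pools; (ii) hydrolysis routes T
directly to D — the product GDP stays bound, the standard single-turnover
scheme; (iii) no GEF or GAP terms — the model isolates *intrinsic* kinetics.
Pool defaults are [GTP] = 500 µM, [GDP] = 50 µM, a representative ~10:1
ratio for resting cells; the qualitative GTP-loading conclusion is
insensitive to the exact ratio because the wild-type affinity for GTP is
itself ~8-fold higher.

The stationary state solves the linear balance equations:
$T/F = k_{on}^{GTP}[GTP] / (k_{off}^{GTP} + k_{cat})$ and
$D/F = (k_{on}^{GDP}[GDP] + k_{cat}\,T/F)/k_{off}^{GDP}$, normalized to sum
to one. Degenerate cases are handled explicitly: a zero denominator with
nonzero influx makes the corresponding state absorbing. One limit worth
spelling out because it is easy to get wrong: as $[GTP] \to \infty$ with
hydrolysis active, the free state empties and the D/T balance becomes
$k_{cat} T = k_{off}^{GDP} D$, so $f_{GTP}$ saturates at
$k_{off}^{GDP}/(k_{off}^{GDP} + k_{cat})$ — about 0.89 for wild-type TTN5 —
and reaches 1 only when $k_{cat} = 0$.

`integrate_cycle()` (deSolve's `lsoda`, rtol 1e-10) is the numerical oracle:
for any initial condition it must relax to the closed form, and the test
suite checks agreement to 1e-6 over 100 random parameter draws (rates
log-uniform on $[10^{-4}, 1]$). The default horizon is 40 times the slowest
relaxation time, computed from the eigenvalues of the rate matrix, so the
check is honest even for nearly-singular parameter draws.

**Classification.** `classify_gtpase()` operationalizes the verbal
criterion "fast exchange plus slow hydrolysis ⇒ accumulates GTP-loaded" as:
label `non_classical_GTP_loaded` iff $r_1 = k_{off}^{GDP}/k_{cat} \ge 5$
and steady-state $f_{GTP} > 0.5$. These thresholds are package definitions,
not measured quantities: $r_1 \ge 5$ requires exchange to outrun hydrolysis
by a clear margin (wild-type TTN5 sits at 8), and $f_{GTP} > 0.5$ says the
active form is the majority species. $k_{cat} = 0$ makes $r_1$ undefined and
forces the non-classical label with an explicit reason code.

## Colocalization

The intensity statistics are the standard ones: Pearson product-moment
correlation over (optionally masked) pixels, and the Manders-type overlap
coefficient $\sum ab / \sqrt{\sum a^2 \sum b^2}$.

Object-based analysis follows the centroid-distance approach used for
punctate structures: threshold at mean + 2·sd of the image intensities,
8-connectivity components, drop components under 4 px, intensity-weighted
centroids, then greedy one-to-one nearest-neighbor matching with a 3 px
tolerance, reported as a percentage in both channel directions. The
reference plugin publishes neither its exact threshold nor its distance
tolerance, so all three values are explicit, configurable defaults chosen
for Gaussian spots of width ~2 px: the threshold sits well above background
at the default noise level, 4 px removes single-pixel noise components, and
3 px ≈ 1.5 spot widths separates true co-placement from neighboring
structures. Greedy matching (candidate pairs sorted by distance) rather
than optimal assignment is deterministic, matches common plugin behavior,
and differs from the optimal matching only in contrived geometries.

Published coefficients from the original imaging data (Pearson 0.63–0.78,
object overlaps of 15–75% depending on marker and variant) depend on
micrographs that are not redistributable; they are context, not reproduction
targets. What the package demonstrates is *correctness of the statistics*:
on synthetic pairs with known ground truth, the recovered percentage is
within one object of the truth across 20 seeds.

## What the synthetic data does and does not emulate

The generators reproduce the *structure* of the assays — exponential
observation models, the concentration-ladder design, six-point hydrolysis
sampling, punctate two-channel images with a controllable true
colocalization fraction — with seeded, bitwise-reproducible noise. They do
not emulate: stopped-flow instrument dead time (the first milliseconds of a
fast trace are unobservable in reality), photobleaching or baseline drift,
shot-noise scaling, multi-exponential traces from heterogeneous protein
preparations, HPLC integration error structure, optical blur beyond an
isotropic Gaussian, chromatic shift between channels, or structured
(non-Gaussian) image background. Passing recovery tests therefore shows the
estimators are unbiased and precise *under the stated observation models*,
not that they are robust to every instrument artifact.

## Problem sizes and numerical choices

Defaults used by the tests and the reproduction script: 500 samples per
trace, 6-point ladders, 20 seeded replicates per recovery experiment,
100 random draws for the steady-state/ODE equivalence, 128×128 px images
with 20 objects. These sizes give stable medians (recovery medians move by
well under a percent between seed sets) while keeping a full run in the
seconds range. Noiseless round-trips are asserted to 1e-6 relative error
(fit convergence tolerance), generator closed forms to 1e-12 (pure floating
point), and the OLS slope against a hand-computed normal-equation solution
to 1e-10.

## Known limitations

- Single-exponential fits only; no global (shared-parameter) fitting across
  a ladder, and no GEF/GAP-stimulated kinetics.
- The cycle model has no nucleotide-free degradation or chaperone terms and
  clamps pools; it predicts occupancy, not flux.
- Segmentation is threshold-based; dense or overlapping puncta beyond the
  generator's separation guarantees will merge.
- The packaged rates are transcriptions of printed (rounded) values; derived
  quantities inherit that rounding, which is why ratio checks carry a 5%
  band.
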