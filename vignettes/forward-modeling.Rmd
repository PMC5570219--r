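---
title: "Forward modeling of murine respiratory impedance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of murine respiratory impedance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murilung)
```

## The problem

Respiratory input impedance `Z_rs(f)` — the complex ratio of airway-opening
pressure to flow under a broad-band forced oscillation — is a sensitive but
indirect readout of lung structure.  Inverse modeling compresses a spectrum
into a handful of parameters; when several pathologic processes coexist
(septal destruction, elastic fiber thinning, airspace obstruction,
derecruitment), those parameters confound them.  `murilung` takes the
forward direction instead: it simulates `Z_rs` from an anatomic airway tree
whose terminal tissue properties are driven by measured (or synthetic)
histology distributions, and asks which structural perturbations are
required to reproduce a measured spectrum.  Model ranking uses likelihood
ratios of total spectral error against a control-driven null simulation.

## The airway tree

Geometry is hybrid. Airways wider than 1 mm in diameter (in the mouse:
trachea and main bronchi) are represented explicitly with fixed mean
dimensions ("CT part").  Below that threshold the tree is statistical: each
branching order `n` carries a mean and SD of radius and length, and
branches dichotomously into orders `n - 1` and `n - 1 - delta_n` until the
terminal order is reached.  At the CT/cast junction each CT leaf is matched
to the nearest order by relative Euclidean distance in `(log r, log l)` —
a scale-free metric appropriate for geometry spanning an order of
magnitude — with ties broken toward the lower order.

Per-segment radii and lengths are drawn from a normal distribution
truncated below at 10% of the order mean.  The sampling law is a design
choice (cast studies report only means and SDs): a truncated normal keeps
geometry positive and near the reported values without introducing skew
that the source tables could not support.

Segment volume is `V_seg = pi r^2 l`, and the total tree volume is
accumulated by the branching recursion
`V_n = V_seg(n) + V_(n-1) + V_(n-1-delta_n)` from the terminal bronchioles
to the trachea.

### The packaged morphometry fixture

Published mouse morphometry tables are not redistributed here; the package
ships a documented synthetic approximation (`generate_morphometry_fixture()`,
also as CSVs under `inst/extdata/`).  It was calibrated once so that the
mean total tree volume over stochastic builds sits at 0.152 mL, the
airway-tree volume of the mouse lung at total lung capacity (25 cmH2O);
`tests/testthat/test-acceptance.R` recomputes this calibration.  The fixture
has 15 cast orders, daughter offsets of 2 for the top three orders and 1
below, and 1398 terminal bronchioles (~2800 segments).  Relative SDs are 8%
of the mean for orders 12 and above and 15% below, reflecting that large
cast orders are few and well defined while terminal measurements scatter
more.  Users with literature tables should load them via
`read_morphometry()`; the fixture is a calibrated stand-in, not a
reproduction, and its absolute airway resistance is higher than that of a
real mouse lung (it has fewer parallel pathways than a monopodial rodent
tree), which is immaterial for the self-consistent recovery experiments the
package is tested on but matters if you compare simulated `R_N` against
experimental values directly.

## Impedance of the network

Each segment carries, in the cmH2O/mL/s unit system:

* a Poiseuille resistance `R_seg = 8 mu l / (pi r^4)`;
* a gas inertance `I_seg = rho l / (pi r^2)`;
* a gas-compression shunt, adiabatic: compliance `C_g = V_seg / (gamma P0)`
  with `gamma = 1.4`, `P0 = 1033` cmH2O;
* a viscoelastic wall-distension shunt: a constant-phase element whose
  compliance is proportional to the lateral surface area `2 pi r l`.

Shunts act at the segment midpoint.  The input impedance is evaluated from
the terminals upward: daughters combine in parallel, in series with the
distal half of the longitudinal impedance, in parallel with the shunts,
in series with the proximal half.  The recursion is implemented in C++ as a
single reverse sweep over a parent-indexed segment table; an independent
top-down ladder enumeration written in R serves as the oracle in the test
suite (agreement to 1e-9 relative on trees up to 3 generations).

Air properties default to body temperature, humidified:
`mu = 1.9e-5` Pa·s, `rho = 1.12` kg/m³.  The wall-shunt constant
(`wall_compliance_per_area = 1e-7` mL/cmH2O/mm², hysteresivity 0.2) was
chosen so the wall pathway perturbs a healthy simulated lung by under 1% at
1 Hz — wall and gas shunts matter during pathology, not at control — and
both shunts are toggleable in every simulation entry point.  A
non-communicating branch (all terminals collapsed) is pruned whole, shunts
included: derecruited regions do not exchange gas with the airway opening.

The sign convention is `exp(+j w t)`: elastic reactance is negative and the
elastance spectrum is `E(f) = -2 pi f X(f)`.

## Terminal tissue and the eight candidate models

Terminal tissue elements follow the constant-phase model
`Z = (G - jH)/w^alpha` with `alpha = (2/pi) atan(H/G)` and hysteresivity
`eta = G/H`.  Each terminal unit `i` receives a lung-scale elastance

`H_i = H0(model) × (lambda_i / lambda_0) × Gamma_i`, or `Inf` with
probability `p_collapse` (and permanently with the obstruction fraction,
which is applied first — obstruction by debris is stationary, collapse is
PEEP-dependent).

* the fiber factor draws a thickness `lambda_i` from the condition's pooled
  fiber distribution and scales linearly against the control mean
  `lambda_0` (fiber thickness assumed linearly related to stiffness);
* the septal factor `Gamma_i` draws a radial alveolar count and compares it
  to a critical value: variant 1 (fixed threshold 12, 0.5 below), variant 2
  (threshold redrawn per unit from the control distribution), variant 3
  (fixed threshold, hyperbolic `RAC_i/RAC_crit` below).  Ties at the
  threshold map to 1; the published rules cover only the strict
  inequalities, so this choice is flagged rather than asserted.

Crossing `{no RAC, variants 1-3}` with `{fibers off, on}` yields the eight
models.  All draws are with replacement from pooled empirical
distributions, independent across units (no spatial correlation).

One normalization choice deserves emphasis: `H_i` is organ-scale (the
baseline `H0` for the control mouse is ~51 cmH2O/mL), so the terminal
element of unit `i` receives elastance `H_i × N_total`.  A homogeneous,
fully recruited lung then aggregates back to exactly `H0`, and the
heterogeneous aggregate is the harmonic mean the parallel network implies.
This is isolated in `simulate_lung_spectrum()`.  The shared `eta` comes
from the control constant-phase fit (`G_i = eta H_i`); per-unit damping is
not separately specified.  The default `eta = 0.18` is a mid-range murine
value, set once in the synthetic defaults.

## The analysis pipeline

* `zrs_from_signals()` forms `Z_rs` as the ratio of Fourier-transformed
  pressure and flow at the stimulus lines only.  The default grid holds 17
  mutually prime non-integer frequencies between 0.5 and 20 Hz,
  constructed as the first seventeen primes times 0.25 Hz (the published
  grid lists only its constraints, not its values; the constructed grid is
  shipped in `default_frequencies()` and overridable everywhere).
* `fit_constant_phase()` minimizes the summed squared complex residual by
  Nelder-Mead, seeded by an alternating linear least-squares pass (at
  fixed `alpha` the model is linear in all four parameters) and polished
  from two perturbed restarts; non-convergence is flagged, never silent.
  On noise-free realizable spectra it recovers parameters to near machine
  precision.
* `pv_elastances()` computes whole-loop and per-step elastances from the
  inflation limb only — the nadir `E_min` estimates the fully recruited
  elastance "during progressive recruitment", and deflation mixes in
  closure.  Zero-volume steps report infinite elastance and are excluded
  from the nadir.
* `estimate_fopen()` is the hyperbolic relation `f_open = E_min / H_CP`,
  clipped to [0, 1].  The conceptual 1000-parallel-unit model enters only
  through this relation; the unit count is not a free parameter.  No
  special-casing at extreme PEEP (0 and 9 cmH2O), where the estimate is
  known to degrade with strain stiffening and extensive collapse —
  per-PEEP values are returned so the degradation is visible.
* `estimate_radius_scale()` estimates a single multiplier `r/r0` in (0, 1]
  applied to all radii (geometry is defined at total lung capacity) by
  bisection on the sign of the numerical SSR derivative, interval width
  1e-3 or 60 iterations, repeated over 100 stochastic trees; estimates
  pinned at the interval ends carry a boundary flag.
* `estimate_H0()` is a scalar least-squares fit of the baseline elastance
  against a maximally recruited control spectrum, repeated over stochastic
  trees and tissue draws; `H0` is then frozen per model for all other
  conditions.
* `run_model_comparison()` evaluates `phi_M`, the sum over the grid of
  squared R and X residuals, for every condition × model × replicate, and
  the likelihood ratio `L_M = -2 ln(phi_M) + 2 ln(phi_0)` against the
  null simulation (the same model driven by control distributions and
  recruitment).  The logarithm is natural — the `-2 log` convention —
  which only rescales, never reorders.  `L_M` is replicate-matched (each
  replicate's model and null simulations share a tree); the summary also
  reports the ratio-of-mean-errors form, since the published description
  does not disambiguate the two.  No complexity penalty is applied by
  design.
* `peep_variance_ratio()` quantifies how much PEEP dependence of the model
  error disappears when PV-derived recruitment is simulated, as a ratio of
  error variances across the five PEEPs.

The master seed of every Monte-Carlo entry point spawns deterministic
per-replicate sub-seeds, so any replicate is reproducible in isolation.

## The synthetic cohort generator

The generator emulates the study design this class of experiment uses: two
genotypes × three ages × 8 subjects, five PEEPs (0, 1, 3, 6, 9 cmH2O),
forced oscillation plus an 8-step quasi-static PV loop to PEEP + 10.

* **Histology.** Pooled RAC values are a shifted binomial (discrete,
  positive, unimodal); pathological conditions subtract a configured shift
  and are therefore stochastically dominated by control by construction.
  Fiber thicknesses are gamma with condition-scaled mean.  The published
  record pools only empirical histograms, so these families are package
  choices, configurable in `cohort_config()`.  The knockout obstruction
  series is progressive with age (3.4, 6.8, 13.8%).
* **Spectra.** Forward simulation at the true `H0`, `eta`, per-PEEP `r/r0`
  and `f_open`, plus multiplicative Gaussian noise (default 3%) applied
  independently to R and X at each frequency.
* **PV loops.** 1000 parallel units with opening pressures drawn from the
  truth's recruitment curve and closing thresholds a fixed gap (1 cmH2O)
  lower — hysteresis is non-negative whenever closing does not exceed
  opening.  Open units inflate with elastance `H0 × n_units` and
  exponential strain stiffening above a 12 cmH2O knee (e-folding 5 cmH2O),
  so the inflation step-elastance nadir lands on the fully recruited
  elastance before stiffening takes over.
* Every dataset carries its `ground_truth` object; the recovery tests
  score pipeline estimates against it.

What the generator does **not** emulate: chest-wall impedance (negligible
in mice and omitted), amplitude-dependent airway mechanics, intra-breath
(dynamic) recruitment, spatially correlated tissue properties,
surfactant biochemistry, and sigmoidal PV curve fitting.  Passing recovery
tests therefore demonstrate internal consistency of the estimation
pipeline under the stated noise model, not fidelity to every feature of
real murine data.

## Numerical choices and degenerate inputs

* Volumes accumulate in double precision; recursive and flat summation
  agree to 1e-12 relative on trees of ~10^4 segments.
* A fully non-ventilated lung (all terminals infinite) raises an explicit
  error rather than returning an unbounded impedance.
* An all-zero spectrum is flagged as a degenerate constant-phase fit.
* `G = H = 0` sets `alpha = 1` (the pure-elastance limit of
  `(2/pi) atan(H/G)`).
* Bisection tolerance 1e-3 on `r/r0` is an order below the replicate SD of
  the estimator, so optimizer error never dominates the reported spread.

## Problem sizes

Routine use in this package's tests and acceptance script runs 100
Monte-Carlo replicates per condition (the study-scale figure), ~2800
segments per tree, 8 subjects per synthetic group, and 20 repeated cohort
draws for the model-selection recovery experiment.  All of these complete
in minutes on a single core; the C++ network sweep evaluates one spectrum
in about a millisecond.

## Known limitations

* The fixture's airway resistance scale is not calibrated to murine
  plethysmography (see above); only its volume is.
* Recruitment in the PV generator is quasi-static and threshold-based;
  `E_min` carries a small negative bias (recruitment volume inflates the
  apparent step compliance near full recruitment), which propagates into
  `f_open` estimates at the few-percent level.
* The wall-shunt constants are package defaults chosen by their stated
  perturbation bound, not values traceable to a specific experimental
  source.
* Likelihood ratios compare error magnitudes only; with no complexity
  penalty, nested models can only be ranked, not tested.
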