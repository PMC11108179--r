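---
title: "Modelling and measuring biological phenazine oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring biological phenazine oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenazox)
```

## The process being modelled

Phenazine-1-carboxylic acid (PCA) is a secreted redox-active metabolite.
Its reduced form is fluorescent, so the oxidation of a reduced PCA stock by
a bacterial culture can be followed in a plate reader as fluorescence
decay. Soil bacteria with branched anaerobic electron transport chains
(ETCs) re-oxidize PCA while respiring nitrate, fumarate, DMSO or TMAO.
Three routes can carry the electrons:

1. **Category 1** — reduced PCA donates its two electrons directly to a
   terminal reductase complex (it substitutes for a quinol at the
   quinol-oxidizing site);
2. **Category 2** — reduced PCA reduces an oxidized membrane quinone,
   replenishing the quinol pool that the reductases then turn over;
3. **Category 3** — reduced PCA reacts with the terminal electron acceptor
   (TEA) directly, with no enzyme involved (the abiotic route).

`phenazox` implements a mechanistic flux model of these routes with
genotype knockouts, the LOWESS-based kinetic feature extraction used on
plate-reader curves, Bonferroni-corrected pairwise comparison of the
resulting metrics, an electron-tower screen of which couplings are
thermodynamically permitted, and a synthetic-data generator that makes the
whole pipeline testable against known ground truth.

## The flux model

State variables (concentrations in micromolar, time in hours): reduced
phenazine $P$, the reduced fraction $Q^{red}_q$ of each quinone pool
$q \in \{UQ, MQ, DMQ\}$ with fixed totals $Q^{tot}_q$, the TEA
concentration $A$, and the accumulated reduced product (e.g. nitrite).
All transfers are two-electron quanta, so one oxidized phenazine
corresponds to one reduced quinone or one reduced TEA molecule. The
fluxes are

$$v_{2,q} = k_{2,q}\, P\, (Q^{tot}_q - Q^{red}_q), \qquad
  v_{1,r} = k_{1,r}\, e_r\, P \frac{A}{A + K_A}, \qquad
  v_3 = k_3\, P A,$$

$$v_{resp,r,q} = V_{max,r}\, e_r\, \mathrm{compat}[r,q]\,
  \frac{Q^{red}_q}{Q^{tot}_q} \frac{A}{A + K_A},$$

where $e_r \in [0,1]$ is the pregrowth-dependent expression weight of
reductase $r$ and $\mathrm{compat}$ is the quinone–reductase compatibility
matrix (respiratory nitrate reductases NarG/NarZ accept all three quinols;
the periplasmic NapA accepts ubiquinol and menaquinol but not
demethylmenaquinol; the fumarate reductase FrdA does not engage ubiquinol;
the DMSO/TMAO reductases default to the (demethyl)menaquinols). Mass action
for the phenazine couplings and Michaelis–Menten saturation in the acceptor
for reductase turnover is the minimal scheme that reproduces the knockout
phenotypes and the nitrate-limitation behaviour; no rate laws are claimed
beyond that. Knocked-out genes contribute zero flux, and quinone
availability follows the biosynthesis genes deterministically (`menA` loss
removes MQ and DMQ, `ubiC` loss removes UQ, `ubiE` loss removes UQ and
DMQ).

Integration uses `deSolve::lsoda` at `rtol = atol = 1e-8`; mid-run TEA
additions are handled by piecewise re-initialization at the spike times,
and the electrode (chronoamperometry) mode clamps $P$ at its initial value
to emulate a working electrode that instantly re-reduces any oxidized
phenazine, reporting current $I = 2F \times \text{flux} \times V$.

### Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| $P_0$ | 100 µM | reduced-PCA assay stock, order of the wet assays |
| $A_0$ | 10 000 µM | 10 mM TEA, the assay concentration |
| $Q^{tot}_q$ | 0.3 µM each | membrane quinone pools are ~10^2–10^3-fold smaller than the phenazine stock at assay cell densities |
| $k_{2,q}$ | 0.15 /µM/h | fast phenazine–quinone exchange; makes respiration, not the exchange, rate-limiting |
| $V_{max,r}$ | 4 µM/h | sets the wild-type maximum oxidation rate (~9 µM/h, half-oxidation in ~7 h over a 48 h assay) |
| $k_{1,r}$ | 0.004 /h | direct reductase route an order of magnitude below the quinone route, the regime in which oxidation by quinones is the main component of the rate |
| $k_3$ | 1e-7 /µM/h | a barely-drifting abiotic control (~0.1 µM/h) |
| $K_A$ | 100 µM | low half-saturation: the permissible TEA threshold is small |
| `q_red_frac0` | 1 | pools start reduced after hypoxic carryover with the phenazine as the only added donor; this also makes a reductase-null genotype identical to the abiotic model, with no transient phenazine absorption into an oxidized pool |

Pregrowth expression weights encode which nitrate reductases are active:
oxic (shaking) pregrowth leaves the stationary-phase regulated NarZ
dominant (`narZ = 1, narG = 0.2, napA = 0`), hypoxic (standing) pregrowth
the Fnr-regulated NarG (`narG = 1, narZ = 0.75, napA = 0.75`). These are
free calibration knobs, not measured quantities. The hypoxic values were
calibrated so that, after accounting for the compatibility matrix (NapA
serves only two of the three quinone pools), the summed quinol-turnover
capacity of every single knockout strictly exceeds that of every double
knockout — the qualitative ordering the model is required to reproduce —
while NarG remains the dominant contributor. A plain
narG:narZ:napA = 1:0.4:0.4 weighting fails that ordering: removing `narG`
leaves less capacity than the NarG-only double knockout.

Two behaviours are deliberately *not* fitted: the model does not reproduce
the observed speed-up of DMSO-driven oxidation when ubiquinone alone is
lost (an open mechanistic question), and the additional TMAO reductases
are aggregated into a single TorYZ-like flag.

## Kinetic feature extraction

The measurement pipeline mirrors standard plate-reader practice for these
assays: smooth each well's fluorescence decay with locally weighted
scatterplot smoothing (LOWESS), read the oxidation rate off the local
slopes, and report (i) the maximum oxidation rate with its time and (ii)
the first time the smoothed curve indicates half the phenazine stock has
been oxidized ($T_{1/2}$), linearly interpolated between grid points.

The smoother fits, at every observed point, a straight line by weighted
least squares over the `ceiling(fraction * N)` nearest neighbours in time,
with tricube weights on distance scaled by the span of the neighbour
window and ties broken toward earlier time points. The default window
fraction is 0.05 — the minimal window that gives stable outputs, which
`scan_fraction()` lets you verify on your own data — with no robustness
iterations by default (they are available and use the standard bisquare
rule). The derivative comes from the local fit's slope rather than finite
differences of the smoothed values: the local regression already estimates
the derivative and is robust to uneven grids (a finite-difference mode is
retained for cross-checking). The implementation is checked against a
brute-force per-point weighted `lm()` oracle to 1e-8.

Choices a user should know about:

* **Baseline anchor.** The 100%-reduced anchor is the mean of the first 3
  smoothed values by default (resists a noisy first read); `"first"` and
  `"max"` anchors are available. On a curve that starts decaying at $t=0$
  the default anchor sits ~one cadence step late; the `"first"` anchor
  recovers the closed-form half-life exactly in that situation. For wells
  with an initial net-reduction rise the anchor deliberately stays at the
  early-time value, so such wells report negative maximum oxidation rates
  and a not-detected $T_{1/2}$.
* **Not-detected is a sentinel.** A well that never crosses the threshold
  reports `t_half = NA` with `detected = FALSE`; it is never coerced to 0
  or to the assay end time.
* **Replicate structure.** Metrics are computed per well; technical
  replicates are averaged into their biological replicate (curve-averaging
  before fitting is available as an option), and the biological replicate
  is the unit carried to statistics. A biological replicate's $T_{1/2}$ is
  reported only if all its technical wells detected the threshold.

## The synthetic-data generator

Synthetic wells follow
$F(t) = F_0\,[\phi + (1-\phi)\,(w e^{-k_f u} + (1-w) e^{-k_s u})] + \mathrm{rise}(t)$
with $u$ the time since the end of the lag phase: a lag, a biphasic decay
to a floor fraction $\phi$, and an optional transient rise modelling wells
in which cells further reduce the provided phenazine. The lag transition
is a softplus time warp of width `lag_smooth` (default 1.5 h; width 0
reproduces a hard switch exactly). The smooth default is deliberate: with
a 15-minute cadence over 48 h (193 points) the 5% window spans ±1.1 h, and
a hard kink at the lag end would carry an irreducible ~20% downward
smoothing bias on the peak rate — no estimator at that window could
recover it — whereas the smooth transition keeps the analytic bias below
1%, which is what real growth-history lags look like anyway. Ground truth
(the analytic maximum of $-F'$ and the root of the half-oxidation
crossing) is computed from the closed form per biological replicate after
parameter jitter; technical replicates share the draw and differ only in
measurement noise.

Noise is independent per time point, multiplicative CV plus additive
Gaussian, clipped at zero; the default (CV 0.2%, additive 0.5 a.u. on
$F_0 = 1000$) corresponds to a well-gained reader on a strong signal.
The level matters for one subtle reason: the reported metric is the
*maximum* of a noisy derivative series, which is biased upward by roughly
the slope-noise standard deviation. At CV 0.5% that bias alone pushes
~15–20% of slow-decaying wells outside a 10% recovery band; at the default
CV the pipeline recovers the ground-truth maximum rate within 10% (and
$T_{1/2}$ within one cadence step) for >99% of wells across 50 simulated
plates, and within 2% on noiseless wells. The generator does **not**
emulate well-position effects, evaporation, optical crosstalk, or
non-Gaussian outliers — so passing recovery tests demonstrates the
pipeline's correctness on its stated noise model, not robustness to every
real-plate artefact (the robustness iterations exist for the latter).

The chronoamperometry generator runs the flux model in electrode mode and
converts flux to current; the trapezoidal integral of a noiseless trace
equals $2F$ times the moles of phenazine equivalents oxidized, which
`integrate_current()` inverts (1 µA·h = 3.6e-3 C).

## Statistics

Group comparison follows the two-tier convention used for these panels:
every unordered pair of strains is tested, the per-comparison threshold is
$\alpha/m$ with $m = \binom{k}{2}$ (8 groups at $\alpha = 0.05$ print as
p < 0.00179, 4 groups as p < 0.00833 — reported at 3 significant figures,
decided at full precision), cells below the corrected threshold are
double-flagged, cells below $\alpha$ but not the corrected threshold are
single-flagged. The default test is Welch's unequal-variance t on
biological replicates: with $n = 3$ per group an exact permutation test
cannot go below a two-sided p of 0.1 and could never clear a corrected
threshold of 0.00179, so parametric testing is the only consistent choice
at this design size; Student and permutation (exact enumeration up to
20 000 assignments, seeded Monte Carlo beyond) are available. Degenerate
inputs follow stated conventions: two constant equal groups give p = 1
(logged), and groups with fewer than two values are flagged
`insufficient-n` in the matrix rather than dropped. An all-null simulation
harness (`type_i_error_check()`) verifies the family-wise double-flag rate
stays at or below $\alpha$.

## Thermodynamic screen

The electron tower orders half-reactions by midpoint potential at pH 7;
a coupling (donor oxidized, acceptor reduced) is favorable iff
$\Delta E = E^{0\prime}_{acceptor} - E^{0\prime}_{donor} > 0$ (ties count
as unfavorable), with $\Delta G = -nF\,\Delta E$ and a Nernst adjustment
available for non-standard pH and redox ratios. The shipped table holds
literature potentials (PCA −0.240 V, pyocyanin −0.040 V, menaquinone
−0.074 V, demethylmenaquinone +0.036 V, ubiquinone +0.100 V,
fumarate/succinate +0.033 V, TMAO/TMA +0.130 V, DMSO/DMS +0.160 V,
nitrate/nitrite +0.433 V) and can be overridden from CSV.

`favorable_acceptors()` is the raw pairwise screen. `oxidant_screen()` is
the biologically meaningful one for TEAs: respiration-driven phenazine
oxidation runs phenazine → quinone → reductase → TEA, so a TEA counts only
if some quinone is both downhill of the phenazine and uphill of the TEA
*and* compatible with a reductase for that TEA. The distinction matters
for pyocyanin: the raw pyocyanin/fumarate pair is (weakly) downhill, but
no quinone route exists — menaquinone cannot oxidize pyocyanin, ubiquinone
is not used by the fumarate reductase, and demethylmenaquinone sits just
above fumarate — so the screen correctly predicts fumarate cannot drive
pyocyanin oxidation while ubiquinone and demethylmenaquinone can oxidize
it directly and nitrate respiration can drive it.

## Problem sizes and numerical conventions in the shipped tests

The test-suite simulations are sized for a desk machine: 50 seeded plates
of 18 wells for noisy recovery, 100 random parameter draws for the
conservation suite (checked to 1e-6 relative, solver at 1e-8), 2000
all-null simulations for the type-I harness, and oracle comparisons on
instances up to 50 points. "Triple knockout equals abiotic" is asserted
within 5% of the wild-type rate (under the defaults the two models are
numerically identical; the band covers randomized-parameter runs).

## Known limitations

* The flux model is deliberately minimal: no proton-motive force, ATP or
  growth coupling, no downstream denitrification, no spatial resolution
  beyond the compatibility matrix.
* Pregrowth weights and rate constants are calibration knobs chosen to
  reproduce qualitative orderings, not fitted to data; `phenazox` does no
  inverse fitting of the mechanistic model.
* The DMSO/ubiquinone-loss speed-up is not reproduced (open question), and
  TMAO reduction beyond TorA/DmsA is a single aggregate flag.
* Fluorescence is assumed linear in reduced-phenazine concentration with a
  configurable calibration factor; inner-filter effects are out of scope.
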