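---
title: "MigFlux: model, assumptions and design choices"
author: "MigFlux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MigFlux: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MigFlux)
```

## The biological question

When budding yeast meets glucose, the AMPK-family kinase Snf1 is
inactivated and the transcriptional repressor Mig1 is dephosphorylated
and accumulates in the nucleus, shutting down genes for alternative
carbon sources.  Single-cell imaging of Mig1-GFP in microfluidic
chambers shows that the strength of this response tracks the *flux* of
glucose into the cell rather than the outside concentration: strains
that import glucose only through the low-affinity, high-capacity
transporter Hxt1 respond in a graded way over upshifts from 0 mM to
2.75–220 mM, while strains restricted to the high-affinity,
low-capacity Hxt7 respond identically at every upshift because their
uptake is already saturated at 2.75 mM.  The same data show marked
cell-to-cell variability in the nuclear/cytosolic Mig1 ratio.  MigFlux
implements the computational side of this study: a deterministic
pathway model, a lognormal mixed-effect layer for cell-to-cell
variability, least-squares parameter estimation, a perturbation-based
ranking of variability sources, and a synthetic-data generator that
emulates the imaging experiments with known ground truth.

## The deterministic model

The model has 8 species, 12 reactions and 18 parameters, organised in
three modules.

**Glucose activity.**  Extracellular glucose `Gex` enters as
Michaelis–Menten uptake through up to three transporters, each gated
by a binary strain indicator, and intracellular glucose `Gin` is
consumed linearly by metabolism:

$$\frac{dG_{in}}{dt} = \mathrm{HXT1a}\,r_{1i} + \mathrm{HXT4a}\,r_{4i}
  + \mathrm{HXT7a}\,r_{7i} - r_4,$$

with $r_{ji} = v_{mj} G_{ex}/(k_{mj}+G_{ex})$ and $r_4 = k_{met}
G_{in}$.  `WT` carries (1,1,1), `HXT1` (1,0,0) and `HXT7` (0,0,1); a
zero indicator removes the transporter's uptake exactly, so its
$v_m/k_m$ parameters can have no influence on any output (this
exactness is asserted in the tests and used to mask heat-map rows).

**Snf1 activity.**  Cytosolic Snf1 is phosphorylated at a constant
rate ($r_6 = k_{sp}\,\mathrm{cSnf1}$) and dephosphorylated in a
glucose-flux-dependent way,

$$r_5 = V_{msi}\,\frac{G_{in}}{k_{g5}+G_{in}}\,\mathrm{cSnf1p},$$

the single point where glucose controls the pathway in this model
(standing in for the ADP/ATP-mediated regulation of the SNF1 complex).
Phosphorylated Snf1 shuttles between cytosol and nucleus with
first-order rates $k_{in7}, k_{out7}$.

**Mig1 activity.**  Mig1 cycles irreversibly through four states:
nuclear Mig1 is phosphorylated by nuclear Snf1p
($r_8 = k_8\,\mathrm{nSnf1p}\,\mathrm{nMig1}$), exported
($r_1 = k_{ex1}\,\mathrm{nMig1p}/(k_{ex2}+\mathrm{nMig1p})$),
dephosphorylated in the cytosol ($r_2 = V_{md}\,\mathrm{cMig1p}$) and
re-imported ($r_3 = k_{im1}\,\mathrm{cMig1}/(k_{im2}+\mathrm{cMig1})$).
The balance equations telescope, so total Mig1 and total Snf1 are
conserved exactly by construction and to integrator tolerance by the
solver; every simulation checks both totals to 1e-6 relative.

The observable is the nuclear/cytosolic ratio
$(\mathrm{nMig1}+\mathrm{nMig1p}+\varepsilon)/(\mathrm{cMig1}+
\mathrm{cMig1p}+\varepsilon)$ with floor $\varepsilon = 10^{-9}$,
matching how the imaging data are quantified (nuclear over cytosolic
fluorescence, compartments treated as unit volumes).

The twelve rate laws live in one internal function (the kinetics
ledger) so alternative kinetics can be swapped without touching the
balance equations.  The upstream study's own rate table and fitted
parameter values were published only in supplementary files that are
not available here; the shipped laws are the package's own minimal
choice constrained to the published structure (8 species, 12
reactions, 18 parameters, the named parameters $V_{msi}$, $V_{md}$,
$k_{ex1/2}$, $k_{im1/2}$, and the transporter indicators).

## Units and the default calibration

Time is in minutes, glucose in mM, and the conserved protein totals
are normalised to 1, so all protein species are dimensionless
fractions.  The default fixed effects (`defaultParameters()`, also
versioned as a YAML preset in `inst/extdata/`) encode the transporter
physiology directly — half-saturations $k_{m1} = 100$ mM,
$k_{m4} = 10$ mM, $k_{m7} = 1$ mM with capacities
$v_{m1} > v_{m4} > v_{m7}$ — and were calibrated once so that the
three strain backgrounds reproduce the qualitative phenotypes of the
imaging study:

* HXT1: final ratio strictly increasing over upshifts to
  2.75–220 mM (graded, flux-limited response);
* HXT7: final ratio varying by less than 10% over the same range
  (saturated uptake, $r_{7i}(220)/r_{7i}(2.75) < 1.4$);
* a population responder-fraction curve peaking about 1 minute after
  the upshift, as observed;
* a pre-shift baseline ratio near 1.25 (delocalised Mig1).

Two structural facts make this calibration well-behaved.  Scaling the
four Mig1-cycle rates ($k_8, k_{ex1}, V_{md}, k_{im1}$) by a common
factor leaves every steady state — hence all final ratios — invariant
and only changes the response speed; and scaling $k_{met}$ up while
scaling $k_{g5}$ down by the same factor leaves the steady-state Snf1
dephosphorylation activity invariant while speeding Gin turnover.  The
response-speed constraint was met through these two invariant
directions (fast Gin turnover, $k_{met} = 6$ min$^{-1}$; fast
shuttling, $k_{in7} = k_{out7} = 4$ min$^{-1}$), so the timescale and
steady-state calibrations are orthogonal.

The pre-shift state is obtained by relaxation rather than algebra:
the system is integrated for 100 min at the pre-shift glucose level
(default 0 mM, the ethanol-pregrowth condition) from a canonical
start, and the residual derivative norm must fall below 1e-8 (it
reaches ~1e-14 in practice).  Upshifts are integrated piecewise with
lsoda (rtol 1e-8, atol 1e-10), stopping and restarting at the step so
the discontinuity never passes through the adaptive integrator.  A
fixed-step RK4 oracle (step 1e-3 min) reproduces the adaptive
trajectories to better than 1e-5 relative on every protocol scenario.

## Cell-to-cell variability: the lognormal NLME layer

Individual cells draw their parameter vector from

$$\theta = \bar\theta \cdot e^{\eta}, \qquad \eta \sim N(0, \sigma),$$

elementwise, with $\bar\theta$ the 18 fixed effects and $\sigma$ an
18×18 log-scale covariance.  $\bar\theta$ is therefore the population
*median*.  The study never states the structure of $\sigma$; the
package defaults to a diagonal matrix with variance 0.04 per
parameter (about 20% cell-to-cell variation, consistent with
random-effect magnitudes displayed on a 0–2 colour scale), and accepts
arbitrary PSD matrices.  Sampling uses one deterministic RNG substream
per cell derived from the master seed, so populations are reproducible
and cell *j*'s draw does not depend on the population size or order.

The heat-map helper draws 50 random-effect vectors and displays
$|\eta|$ (parameters × individuals) — the absolute value is a display
convention matching the non-negative colour scale — with the rows of
inactive-transporter parameters masked as `NA`, since the indicator
argument makes them provably output-irrelevant.

## Parameter estimation

Estimation is weighted least squares on the observable: residuals are
the differences between the simulated and the cell-aggregated (mean)
observed ratio at each time point, on the linear scale by default
(log-scale residuals are available, since the traces are often
displayed logarithmically; the study's own objective is not
published).  The fit uses a multiple-shooting formulation: the time
span is partitioned into intervals (default 5 over the 17-min window)
whose junction states are free optimisation variables; continuity is
enforced by a quadratic penalty whose weight increases over stages
(1e2, 1e4, 1e6), and final junction defects are reported — below 1e-6
relative at any proper optimum.  Free parameters are optimised on the
log scale within box bounds (default: reference /10 to ×10) by
Levenberg–Marquardt (`minpack.lm`).  The finite-difference step for
the numerical Jacobian is set to 1e-6 — comfortably above the
adaptive-solver noise floor at rtol 1e-8 — because default
machine-epsilon steps stall the optimiser on ODE-generated residuals.

Fitting all 18 parameters from one mean trace is not identifiable;
the shipped presets fit small subsets (up to ~6).  The subset
{$V_{msi}$, $V_{md}$, $k_{ex1}$, $k_{im1}$} — one rate per pathway
module — is recovered from noise-free self-generated data to ~1e-7
relative from 1.5×-perturbed starts, and to within 5% under 5%
multiplicative noise (median over seeded replicates).  Per-cell refits
feed `estimateCovarianceDiagonal`, which returns the sample variance
of $\log(\hat\theta_i/\bar\theta_i)$ across cells — the empirical
diagonal of $\sigma$ (the study's own covariance-construction
procedure is in an unavailable supplement).

## Perturbation ranking of variability sources

Each fixed effect is multiplied in turn by $e^{s^2}$ and the mean
output change

$$e_i = \frac{\lVert \hat y(\bar\theta) - \hat y(\bar\theta_{per_i})
\rVert}{l}$$

is recorded, with $\hat y$ the noise-free ratio trace at the
population parameters on an $l$-point grid (default $s = 0.1$,
$l = 31$ over 0–15 min; both are reported in every report).  The norm
is Euclidean over time points.  The ratio is the only measured output
and therefore the default $\hat y$; per-species outputs are a switch.
Parameters with no influence (masked transporters, $s = 0$) give
exactly $e_i = 0$; ties in the descending ranking break by canonical
parameter order.  Under the shipped calibration the influential errors
span more than four orders of magnitude; the identity of the top-ranked
parameters depends on the calibration (here the nuclear Mig1
phosphorylation and Snf1p shuttling rates lead), so orderings should
be read per-calibration rather than as universal facts.

## The synthetic-data generator

`generateExperiment` emulates one microfluidics experiment: a step
from 0 mM to a protocol level at $t = 0$; per-experiment cell counts
drawn uniformly from 22–41 (`"paper-range"`, matching the imaging
experiments) or fixed; sampling every 0.5 min (the real imaging rate
is not published; 0.5 min resolves the ~1-min response) from −2 min
(so baseline-relative statistics are computable) to 15 min;
individual parameters from the NLME law; observed ratio = model ratio
× lognormal noise with CV 5% (multiplicative, because the observable
is a fluorescence *ratio* displayed on a log scale; the true noise
magnitude is not published).  Cell sizes are lognormal (30 ± 6
arbitrary units) and independent of the kinetics by default;
`sizeEffect` adds a standardized-log-size term to the random effect of
the nuclear-import capacity $k_{im1}$, planting a detectable
size-response association for power checks.  Every synthetic set
carries its design, seed, fixed effects, covariance and per-cell
$\theta,\eta$, so it can reproduce itself exactly.

What the generator does *not* emulate: photobleaching, segmentation
error, cell growth and division during the window, focal drift, or
non-stationary noise.  Passing tests on synthetic data therefore
validate the estimators and statistics against the stated generative
model, not against imaging artefacts.

## Trace statistics

Per cell, the baseline is the mean ratio over pre-shift samples; a
cell *responds* when its ratio exceeds baseline × 1.5 for at least 2
consecutive post-shift samples (the imaging study gives no numeric
criterion; the debounce guards against isolated noise spikes, and both
knobs are arguments); the response time is the first sample of the
first qualifying run; the final ratio is read at the last grid point
at or before 15 min after the shift.  The responder-fraction curve is
the pointwise fraction of cells above their own threshold, with the
first time its maximum is attained reported.  The CV over time uses
the sample (n−1) standard deviation.  The size-response association is
a Pearson correlation with its 95% interval; a null-consistency flag
records whether the interval covers 0.  All statistics are invariant
to cell order and to common rescaling of the traces.

## Numerical choices and degenerate inputs

* Integration: lsoda, rtol 1e-8 / atol 1e-10; tiny negative
  excursions (> −1e-9) from round-off are clipped to 0.
* Conservation is asserted (1e-6 relative) on every simulation; a
  violation raises an error rather than truncating output.
* Observable floor $\varepsilon = 10^{-9}$; empty-pool ratios are ~0
  or ~total/ε rather than NaN.
* $\sigma$ validation: symmetry to 1e-12, eigenvalues ≥ −1e-12, with
  the offending eigenvalue reported.
* Zero covariance, zero noise and n = 1 populations are exact
  degenerate cases, used as oracles in the tests.
* Solver failure inside a fit returns a finite large-penalty residual
  with a warning, so the optimiser can back away; failures elsewhere
  raise errors carrying the solver diagnostics and the cell id.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at desk scale, chosen
to give each check clear resolution: Monte-Carlo moment checks use
1e4–1e5 draws; population simulations use 15–300 cells; recovery fits
use one 35-point mean trace and 5 shooting intervals; the RK4
cross-check covers all 3 strains × 6 upshifts at step 1e-3 min.

## Known limitations

* The shipped rate laws and calibration are the package's own; the
  upstream study's exact kinetics and fitted values are unpublished,
  so quantitative outputs (e.g. which parameter tops the perturbation
  ranking) are calibration-dependent.  Structural results —
  conservation, masking exactness, the NLME law, the $1/l$ scaling of
  $e_i$ — are calibration-independent.
* WT is modelled as carrying all three transporters (1,1,1); no
  HXT4-only data set exists to constrain $v_{m4}/k_{m4}$ separately.
* Whether Mig1 dephosphorylation carries an explicit glucose
  dependence is left open upstream; here $r_2$ is glucose-independent
  and any flux dependence of $V_{md}$ must emerge from per-condition
  fits, mirroring how the study reports it.
* No spatial or volume modelling, no ADP/ATP submodel, no crosstalk
  with the Snf3/Rgt2 or PKA pathways, and no full NLME marginal
  likelihood (SAEM/FOCE): estimation follows the fixed-effect +
  perturbation route.
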