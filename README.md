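# MigFlux

Glucose-flux control of the yeast Snf1–Mig1 pathway, with cell-to-cell
variability.

When *Saccharomyces cerevisiae* is shifted from no glucose to glucose,
the repressor Mig1 is dephosphorylated and moves into the nucleus; the
single-cell readout is the nuclear/cytosolic Mig1-GFP fluorescence
ratio.  Strains importing glucose only through the low-affinity
transporter Hxt1 respond more strongly the higher the upshift, whereas
strains restricted to the high-affinity Hxt7 respond identically at
every upshift — evidence that glucose *flux*, not concentration,
controls the pathway.  MigFlux is for modellers and quantitative cell
biologists who want to simulate, fit and interrogate this system.

## What is inside

* **Pathway model** — an 8-species, 12-reaction, 18-parameter ODE
  model: Michaelis–Menten uptake through Hxt1/Hxt4/Hxt7 (switched per
  strain by binary indicators), linear glucose consumption,
  glucose-driven Snf1 dephosphorylation
  (r5 = Vmsi · Gin/(kg5+Gin) · cSnf1p), nuclear Snf1p shuttling, and
  the irreversible four-state Mig1 cycle (phosphorylation by nuclear
  Snf1p, export, cytosolic dephosphorylation, import).  Total Mig1 and
  Snf1 are conserved; the observable is the nuclear/cytosolic ratio.
* **NLME layer** — individual cells draw parameters from the
  lognormal law θ = θ̄ · exp(η), η ~ N(0, σ), with reproducible
  per-cell random streams, population simulation and the |η| heat-map
  construction (masked for inactive transporters).
* **Estimation** — weighted least squares on the aggregated ratio
  trace with a multiple-shooting formulation (junction states as free
  variables, annealed continuity penalty, Levenberg–Marquardt), plus
  empirical diagonal covariance from per-cell refits.
* **Perturbation ranking** — e_i = ‖ŷ(θ̄) − ŷ(θ̄_per_i)‖ / l with the
  i-th parameter multiplied by exp(s²); ranks parameters as sources of
  cell-to-cell variability.
* **Synthetic data** — seeded microfluidics-style experiments (22–41
  cells, −2 to 15 min at 0.5 min, upshifts 0/2.75/11/27.5/55/220 mM,
  multiplicative lognormal noise, optional planted size effects) with
  full ground-truth provenance, round-tripping through tidy CSV + JSON.
* **Trace statistics** — responder fractions and times, final ratios,
  CV over time, size-response correlation.

The central container is `TraceSet`, a `SummarizedExperiment` of
time-points × cells ratio matrices.

## Worked example

```r
library(MigFlux)

## one synthetic HXT1 experiment: 0 -> 55 mM upshift, 30 cells
ts <- generateExperiment(
  experimentDesign("HXT1", postLevel = 55, nCells = 30, seed = 7))
ts
#> TraceSet: 30 cells x 35 time points [-2, 15] min
#>   strain HXT1, glucose 0 -> 55 mM, synthetic (ground truth attached)

summarizeTraces(ts)
#> TraceSummary: 30 cells, responder fraction 1.00 (threshold 1.5x baseline, debounce 2)
#>   median response time 1 min; median final ratio 5.37

a <- sizeResponseAssociation(ts)
sprintf("r = %.3f, 95%% CI [%.3f, %.3f]", a$estimate,
        a$conf.int[1], a$conf.int[2])
#> "r = -0.012, 95% CI [-0.371, 0.350]"
```

Every cell responds (ratio above 1.5× its own pre-shift baseline for
two consecutive samples), typically within a minute of the upshift,
and settles around a five-fold nuclear enrichment; cell size carries
no information about the response under the default generator (the
interval covers 0), matching the experimental observation.

Ranking variability sources for wild type shifted to 220 mM:

```r
r <- rankParameters(defaultParameters(), s = 0.1,
                    strain = strainConfig("WT"),
                    profile = glucoseProfile(220))
head(r[order(r$rank), c("parameter", "error", "rank")], 5)
#>  parameter       error rank
#>         k8 0.011554948    1
#>      kout7 0.010628539    2
#>       kin7 0.010314488    3
#>       vmsi 0.009157169    4
#>        ksp 0.008919634    5
```

Errors of influential parameters span more than four orders of
magnitude; parameters of transporters absent from a strain score
exactly zero.  Which parameters lead depends on the calibration — see
the methods vignette (`vignettes/MigFlux-methods.Rmd`) for the model,
the default calibration and its rationale, and known limitations.

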