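Package: MigFlux
Title: Glucose-Flux Control of the Yeast Snf1-Mig1 Pathway with
    Cell-to-Cell Variability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic and nonlinear mixed-effect (NLME) modelling of
    glucose-flux control of the Snf1/AMPK-Mig1 glucose-repression pathway
    in Saccharomyces cerevisiae. Provides a strain-aware ordinary
    differential equation model of hexose uptake, Snf1
    de/phosphorylation and the irreversible four-state Mig1
    nucleocytoplasmic shuttling cycle; lognormal cell-to-cell parameter
    variation with population simulation; multiple-shooting least-squares
    parameter estimation; one-at-a-time parameter perturbation ranking of
    variability sources; a synthetic microfluidics-style single-cell
    trace generator with known ground truth; and the trace statistics
    (responder fractions, response times, coefficients of variation,
    size-response association) used to characterise single-cell Mig1
    localization experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, deSolve, MASS, minpack.lm,
    jsonlite, yaml, S4Vectors
Suggests: testthat (>= 3.0.0), ggplot2
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, SingleCell, TimeCourse,
    MathematicalBiology
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MigFlux-package.R'
    'parameters.R'
    'TraceSet.R'
    'pathway-model.R'
    'nlme.R'
    'estimation.R'
    'perturbation.R'
    'trace-analysis.R'
    'plots.R'
    'synthetic-data.R'
    'serialization.R'
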