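Package: gapCircuits
Title: Reverse Engineering of Gap Gene Circuits from Spatial Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reverse engineering spatial developmental gene
    regulatory networks with gene circuit models, applied to the Drosophila
    trunk gap gene system. Simulates a hybrid dynamical model of a row of
    dividing blastoderm nuclei (sigmoid-regulated synthesis, inter-nucleus
    diffusion with no-flux boundaries, linear decay, mitotic synthesis
    shut-off and an instantaneous nuclear division), builds model-fitting
    datasets from spline-quantified expression boundary annotations, fits
    circuit parameters by Lam adaptive simulated annealing under ordinary or
    weighted least squares, assesses practical parameter determinability via
    Jacobian-based dependent and independent confidence intervals, and
    classifies the inferred regulatory network and its dynamical mechanisms.
    Includes artificial external-input generators, reduced-data experiment
    harnesses, and a synthetic-data module for ground-truth parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
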