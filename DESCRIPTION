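Package: gcmature
Title: Coarse-Grained Population Dynamics of Affinity Maturation in Germinal Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the mutation-selection dynamics of B-cell populations
    during affinity maturation in germinal centers with a coarse-grained
    birth-death model: affinity-dependent growth with a Langmuir-motivated
    linear death rate, a discrete mutation-effect spectrum of binding
    free-energy changes, an exact analytic solution of the linear-growth
    mean-field equation as a product of per-mutation-class Poisson factors, a
    finite-population deterministic integrator with a one-cell bin cutoff,
    stochastic branching-process realizations for bottleneck-survival
    estimation, parameter-space sweeps over mutation load, initial binding
    level and selection strength, and the distribution of the strong-affinity
    fraction across asynchronously started germinal centers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectrum.R'
    'params.R'
    'simulate.R'
    'allornone.R'
    'analytic.R'
    'stochastic.R'
    'sweep.R'
    'config.R'
    'cli.R'
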