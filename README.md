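# gcmature

Coarse-grained population dynamics of antibody affinity maturation in
germinal centers (GCs).

During an immune response, B cells in germinal centers hypermutate their
immunoglobulin genes and compete for antigen; over one to two weeks this
mutation–selection loop improves antibody–antigen binding by roughly two
orders of magnitude. `gcmature` implements a deliberately coarse model of
this process for people who want to reason quantitatively about it:
immunology modelers exploring why the observed hypermutation rate
(~0.5 mutations per division) and selection pressure look the way they do,
and population geneticists interested in mutation–selection dynamics with a
population bottleneck.

## The model

B cells carry a binding free energy `X` (kcal/mol; lower = stronger
binding). The per-capita growth rate of the subpopulation at `X` is

    B(X) = min( -b (X - X*),  r - m_lethal )

where `r = 4 ln 2 ≈ 2.8/day` is the birth rate (4 divisions/day), the
Langmuir-motivated death rate is linear in `X` with selection strength `b`,
`X*` is the *neutral* affinity at which birth and death balance, and growth
saturates at the net replicative rate once binding is strong enough
(`X - X* < -(r - m_lethal)/b`). Mutations hit a fraction `p` of daughter
cells (Poisson load `mu = -ln(1-p)`, total rate `m_total = 4 mu` per day);
50% are silent, 30% lethal (an effective death rate `m_lethal`), and 20%
affinity-affecting. Those last move a cell by a step `delta` drawn from a
discrete spectrum `W(delta)` on a 0.5 kcal/mol lattice in which only 4.9% of
steps improve binding (1.4% by five-fold or more).

The package provides, over this one model:

* **exact analytic solution** of the linear-growth mean-field equation —
  the total population is the mutation-free exponential times a product of
  per-mutation-class Poisson factors `exp{ m_i [ (e^{g_i t}-1)/g_i - t ] }`
  with `g_i = -b delta_i` (`analyticSolution()`, `totalPopulation()`,
  `subpopulationSize()`);
* **finite-population deterministic integrator** on an affinity grid with
  the one-cell bin cutoff: bins holding less than one expected cell are
  frozen and only accumulate influx, which creates the population
  bottleneck, extinction, and finite wave speed that the infinite-population
  solution lacks (`simulateGC()`, `stepPopulation()`);
* **stochastic branching-process realizations** for bottleneck-survival
  probabilities (`simulateRealization()`, `survivalProbability()`);
* **parameter sweeps** over mutation load and initial binding level, with
  optimum finding and the pooled-spleen vs isolated-GC migration comparison
  (`sweepGrid()`, `findOptimum()`, `migrationComparison()`);
* the **all-or-none statistic**: the distribution of the strong-affinity
  fraction F across asynchronously started GCs (`strongFraction()`,
  `fractionDistribution()`).

## Worked example

A single isolated germinal center founded by 3000 cells whose germline
antibodies bind at half the neutral affinity level, with the observed
mutation load (half of daughters mutated):

```r
library(gcmature)

p <- modelParams(b = 0.7, pMutatedDaughter = 0.5,
                 XStarOffsetIn = -0.59 * log(0.5), N0 = 3000)
p
#> ModelParams
#>   r        = 2.773/day (4 divisions/day)
#>   b        = 0.7/day/(kcal/mol)   kT = 0.59 kcal/mol   h = 0.5 kcal/mol
#>   p        = 0.5 mutated daughters (mTotal = 2.77/day, mAff = 0.555/day)
#>   X_in-X*  = +0.409 kcal/mol (Ka_in/Ka* = 0.5)
#>   N0       = 3000 cells   tMax = 100 days

tr <- simulateGC(p, termination = "recovery_unbounded")
tr
#> Trajectory: recovered at t = 18.3 days (641 samples)
#>   N0 = 3000, bottleneck 48.32 cells at t = 8.74 days
#>   A improvement = 51.94-fold, terminal F = 0.899
```

Reading: the population first shrinks (germline binding is weaker than
neutral, so net growth is negative), bottoms out at 48 cells on day 8.7 —
the population bottleneck — and then regrows on the back of
affinity-improving mutants, recovering its founding size on day 18. At that
moment the summed association constant of the population (`A`) is 52 times
its initial value, and 89.9% of cells bind at or above the neutral level
(`F`). Tracking `F(t)` and asking how an ensemble of unsynchronized GCs
would look at a random instant gives the characteristic "all-or-none"
U-shape: `fractionDistribution(tr)`.

A command-line wrapper with subcommands (`simulate`, `sweep`, `survival`,
`allornone`, `spectrum`, `analytic`, `fixtures`) is installed at
`inst/scripts/gcmature`; it reads flat YAML/JSON configs and writes TSV
with provenance headers (see `?gcmatureMain`, `?parseConfig`).

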