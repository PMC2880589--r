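---
title: "A coarse-grained model of affinity maturation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of affinity maturation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmature)
```

# The model

Affinity maturation is treated as mutation–selection dynamics of a B-cell
population labeled by a single coordinate: the antibody–antigen binding
free energy `X` (kcal/mol, lower = stronger). All mechanism below the
coarse-grained level — antigen capture kinetics on follicular dendritic
cells, T-cell help, recycling between dark and light zones, distinct
centroblast/centrocyte phenotypes — is collapsed into one phenomenological
growth law:

$$B(X) \;=\; \min\big(-b\,(X - X^*),\; r - m_{lethal}\big).$$

The ingredients:

* **Birth.** Cells divide `divisionsPerDay` (default 4) times a day,
  giving the exponential birth rate $r = 4\ln 2 \approx 2.8$/day.
* **Death by selection.** The probability of surviving a round of
  antigen-driven selection follows a Langmuir isotherm in the association
  constant; expressed in free energy this produces a death rate *linear*
  in `X` with slope `b` (1/day per kcal/mol), saturating to zero death
  (survival probability 1) for sufficiently strong binding. The linear and
  saturated branches meet at the offset $-D = -(r - m_{lethal})/b$ below
  the neutral point.
* **Death by mutation.** A fraction `p` of daughter cells carries at least
  one mutation; the per-division mutation count is modeled as Poisson with
  mean $\mu = -\ln(1-p)$, so the total mutation rate is
  $m_{total} = 4\mu$ per day. Mutation classes: 50% silent (dropped
  entirely — they change nothing), 30% lethal (an effective death rate
  $m_{lethal} = 0.3\,m_{total}$), 20% affinity-affecting
  ($m_{aff} = 0.2\,m_{total}$). At `p = 0.5` this mapping gives
  $m_{total} = 2.77 \approx 2.8$/day and $m_{aff} = 0.55$/day/gene — both
  standard anchor values — which is why the Poisson load model was chosen
  over alternatives (e.g. "exactly one daughter mutated"), none of which
  reproduce both anchors simultaneously. Under this mapping the
  lethal-mutagenesis boundary ($m_{lethal} \ge r$, extinction at every
  affinity) sits near `p = 0.9`.
* **Neutral affinity.** $X^*$ is *defined* by $B(X^*) = 0$; all affinities
  in the package are offsets from it, and the association-constant ratio is
  $K_a/K_a^* = e^{-(X - X^*)/k_BT}$. Absolute antigen concentration and
  absolute $K_a^*$ are deliberately not modeled: the dynamics depend only
  on relative binding levels.
* **Mutation effects.** An affinity-affecting mutation moves a cell by a
  step $\delta$ drawn from a discrete spectrum $W(\delta)$ on the
  `h = 0.5` kcal/mol lattice, independent of the current `X`. Beneficial
  steps ($\delta < 0$) are rare.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `b` | 1/day/(kcal/mol) | 0.7 | selection strength; the optimum reported for this class of model, and the value all reference runs use |
| `pMutatedDaughter` | — | 0.5 | observed somatic hypermutation load (~half of daughters mutated) |
| `kT` | kcal/mol | 0.59 | the single value consistent with all three standard conversions: 0.5 kcal/mol ↔ 2.3-fold $K_a$, 1 kcal/mol ↔ $K_a$ ratio 0.18, and ln(450)·kT ≈ 3.6 kcal/mol |
| `h` | kcal/mol | 0.5 | spectrum/grid bin width, ~1 bin per 2.3-fold of $K_a$ |
| `XStarOffsetIn` | kcal/mol | +1.0 | germline binding one bin weaker than neutral ($K_{a,in}/K_a^* = 0.18$) |
| `N0` | cells | 1e5 | pooled spleen (hundreds of GCs, fast-migration limit); 3000 for an isolated GC |
| `tMax` | days | 100 | guard horizon for recovery-based termination |

`deriveRates()` exposes the derived scales: the saturation offset
`D = (r - m_lethal)/b` (≈2.77 kcal/mol at defaults) and the
recycling-round time scale `tau = 1/(b kT)` (≈2.4 days at `b = 0.7`).

# The packaged mutation spectrum

The published description of the mutation-effect distribution pins down
only a few facts: 4.9% of affinity-affecting mutations improve binding,
1.4% improve it strongly (≥5-fold, i.e. by at least
$k_BT \ln 5 = 0.95$ kcal/mol), and the deleterious side of the histogram
decays. The packaged `defaultSpectrum()` is a *synthetic reconstruction*
honoring exactly these constraints: offsets
(−1.0, −0.5, +0.5, …, +3.0) with weights
(0.014, 0.035, 0.300, 0.240, 0.170, 0.120, 0.070, 0.051); the deleterious
weights follow an exponential decay of scale 1 kcal/mol renormalized to
0.951. All eight weights are packaged constants, so every downstream number
is reproducible bit-for-bit.

Two caveats follow. First, results that depend on the *shape* of the
beneficial tail — above all the pooled-spleen optimum, where the speed of
the adaptive wave decides whether the population recovers inside the
14-day window — inherit the uncertainty of this reconstruction; this is
why the sweep-level checks carry wide tolerance bands, and why the
pooled-spleen maximum reproduces the published optimum only in order of
magnitude (the isolated-GC quantities, which are less wave-speed
sensitive, land much closer). Second, the often-quoted "typical
beneficial step ≈ 0.4 kcal/mol" cannot be represented exactly on an
`h = 0.5` lattice whose strong-beneficial mass is 1.4 of 4.9 points: the
packaged spectrum's mean beneficial step is 0.64 kcal/mol. The package
does not force that mean; the classic "3.6/0.4 ≈ 9 mutations" arithmetic
is reproduced as arithmetic, not as a spectrum property.

`spectrumFromDdg()` builds a spectrum from measured per-mutation binding
free-energy changes instead (headered TSV, column `ddG_kcal_per_mol`,
negative = improved binding). Values bin to the nearest lattice center;
exact half-way ties round away from zero (covered by a test).
`makeFixtures()` writes a 500-row synthetic ddG table sampled from the
packaged spectrum — its filename says synthetic because it is — plus the
three reference configurations.

# Analytic solution and its role as oracle

When the growth law stays on its linear branch the mean-field equation is
solvable in closed form. With per-class rates $m_i = m_{aff} w_i$ and
growth increments $g_i = -b\,\delta_i$,

$$N_{tot}(t) = N_0\, e^{B(X_{in})t} \prod_i
  \exp\Big\{ m_i \Big[ \frac{e^{g_i t} - 1}{g_i} - t \Big] \Big\},$$

implemented directly in this product form (`totalPopulation()`) rather
than through the Fourier-transform derivation — same solution, better
numerical behavior. Per-class subpopulation bookkeeping
(`subpopulationSize()`) is Poisson with the time-integrated intensity
$\lambda_i(t) = m_i (e^{g_i t}-1)/g_i$; the largest subpopulation is the
Poisson mode $\lfloor \lambda_i(t) \rfloor$ (`peakMutationCount()`), which
advances exponentially fast at long times. The reading of "largest
subpopulation" as the Poisson mode is a reconstruction and documented as
such.

Numerical details: $(e^{gt}-1)/g$ switches to its series
$t + g t^2/2$ for $|gt| < 10^{-6}$; evaluation warns when the
mean displacement $X_{in} + \sum_i \lambda_i \delta_i$ crosses the
saturation point $-D$, where the linear-growth assumption breaks down.

This closed form is the package's central oracle: the finite-population
integrator with the cutoff disabled, a refined step
(`dtFactor = 0.001`) and a wide grid must match it to better than 0.5%
relative error out to five days — one of the acceptance-level tests. The
wide grid matters: on a truncated grid, deleterious mutants pushed past
the upper edge are dropped rather than left to decay in place, which alone
produces ~2% discrepancy.

# Finite-population integrator

Real GC populations are integer-valued; a bin whose *expected* occupancy
is below one cell cannot seed super-exponential growth. The integrator
therefore applies, each step of length `dt = 0.01/(b h)`:

1. bins with ≥1 cell multiply by $e^{B(X)\,dt}$;
2. they emit mutants with Poisson step probabilities
   $q_k = e^{-m_{aff} dt} (m_{aff} dt)^k / k!$ for $k = 1..K_{max}$
   mutations ($K_{max} = 3$; the probability of more per step is below
   $10^{-10}$), the spectrum convolved $k$ times deciding the
   destination; the staying fraction is $1 - \sum_k q_k$, so the mutation
   operator conserves cells exactly when growth and lethality are off
   (tested to machine precision);
3. bins below one cell are **frozen** — no growth, no decay, no emission —
   and only accumulate influx until they reach one cell.

Freezing is the conservative reading of "sub-unity occupancy is an
accumulative probability to emerge": such a bin represents a cell that has
not appeared yet, and a nonexistent cell neither divides nor dies. The
alternative reading (sub-unity bins still decay) is available as
`subunityDecay = TRUE` for sensitivity checks; it only affects the
deleterious flank and not the adaptive front, so headline numbers barely
move. A third reading — letting sub-unity bins grow — was rejected: it
reinstates exactly the infinite-population artifact the cutoff exists to
remove, and it would let an "extinct" population (every bin below one
cell) regrow, contradicting the defining property of extinction at the
bottleneck. Wave-timing quantities are nevertheless sensitive to this
modeling choice at the tens-of-percent level, which is the main known
driver of disagreement with published pooled-spleen optima.

Termination modes: `fixed_window_14d` (stop at recovery to `N0` or day
14, whichever first — the pooled-spleen convention), `recovery_unbounded`
(stop at recovery whenever it happens, guarded by `tMax`), and
`horizon_only` (for oracle comparisons). Recovery requires
`t > bottleneckTime`, so a run starting at `N0` does not instantly
"recover". A state with every bin below one cell cannot evolve further
under the cutoff and is classified extinct. The affinity grid spans
offsets $[-6, +7]$ kcal/mol: $-6$ comfortably holds >1000-fold
improvements, and $+7$ keeps multi-step deleterious mutants on-grid so
edge loss stays dynamically negligible (tested: results invariant under
further widening; anything mutating off-grid is tallied in edge-loss
counters rather than silently dropped).

Step-size convergence is clean during the population decline (halving
`dt` moves the day-3 total by <0.5%) but slower after the bottleneck,
where the cutoff quantizes bin-activation times and exponential regrowth
amplifies them (a few percent on the day-14 improvement); the tests
assert the convergence actually attained.

# Stochastic realizations

`simulateRealization()` runs a tau-leaping branching process with
decoupled exponential clocks per cell: division ($r$, one cell → two),
lethal death ($m_{lethal}$), affinity jump ($m_{aff}$, step from the
spectrum), apoptosis ($d(X) = \max(0, b(X - X^*) + r - m_{lethal})$). This
construction makes the branching mean satisfy the mean-field equation
*exactly* — the calibration criterion that keeps the stochastic and
deterministic modules mutually consistent, verified by comparing 200
replicate means against the cutoff-free integrator within three standard
errors. A scheme with mutations coupled to division events (each daughter
drawing its own mutation count, dying if any is lethal) realizes a lethal
flux of $2r(1 - e^{-\nu f_{lethal}})$ instead of $m_{lethal}$ — at
realistic loads a ~0.06/day growth bias, enough to fail the mean-field
check — and was rejected for that reason. The leap step (0.005 days)
keeps the per-step linearization bias well below replicate noise.

**Survival.** The deterministic recovery rule (reach `N0` again) is
useless verbatim for a stochastic run *started at* `N0`: Poisson
fluctuation alone re-crosses the founding size within the first steps
with order-one probability even for doomed populations, and makes
"survival" decrease with `N0`. `survivalProbability()` therefore counts a
run as having survived the bottleneck when it reaches
`recoveryFactor * N0` (default 3): drift-dominated subcritical
populations essentially never do, while a genuinely recovered population
(net growth 1–2/day) does within a day. For founding sizes so small that
`3 N0` is itself a fluctuation scale (a handful of cells), judge
extinction by the horizon instead (`detectRecovery = FALSE`). Estimates
come with 95% Wilson intervals; per-replicate seeds derive from one base
seed, so survival maps are reproducible.

# Sweeps and the all-or-none statistic

`sweepGrid()` scans mutated-daughter fractions {0.1, …, 0.9} × 12
log-spaced binding levels $K_{a,in}/K_a^* \in [0.01, 1]$ — the ranges the
phenomenology lives in, at desk scale (108 deterministic runs, seconds).
Note the initial condition snaps to the affinity lattice, so neighboring
`ka` grid points can share a bin. `findOptimum()` breaks exact ties
toward smaller recovery time, then smaller mutation load (an artifact
convention, documented here). `migrationComparison()` divides the
pooled-spleen optimum by the isolated-GC optimum, each over its own grid
and termination convention. Selection strength is swept only on request;
the global optimum in `b` is left unasserted because published accounts
themselves flag it as possibly a discretization artifact, and the package
simply reports the profile.

For the all-or-none statistic, `F(t)` is the population fraction at
offsets ≤ 0 ("strong": at or beyond neutral binding). Observing many
identically parameterized GCs with random start times at one instant is
equivalent to observing one trajectory at a uniformly random time, so
$P(F) \propto dt/dF$. `fractionDistribution()` estimates this as time
spent per F-bin divided by total run time — the robust discrete
equivalent, exact for monotone `F(t)` and immune to the $dt/dF \to
\infty$ singularity where `F` plateaus. It is invariant under uniform
time rescaling and consistent under bin refinement (both tested). The
U-shape — most mass at low F and near the terminal F, little in between —
is asserted at the decile scale, which is robust to the (unstated) choice
of bin count; the terminal plateau can straddle a decile edge, so the
high arm is read off the top *visited* decile.

# What the synthetic inputs do and do not emulate

The generator-side components (packaged spectrum, fixture ddG table,
reference configs) emulate the *statistical constraints* of the published
mutation-effect data — beneficial fractions, lattice discretization,
decaying deleterious tail — under the stated study conditions (`b = 0.7`,
`p = 0.5`, $K_{a,in}/K_a^*$ = 0.18/0.5, `N0` = 1e5/3000). They do not
emulate: affinity-dependence of mutation effects (assumed independent of
current `X`, defensible over the 2–4 kcal/mol range the dynamics
traverse), sequence-level structure, antigen depletion (termination rules
stand in for it), spatial GC organization, or inter-GC migration as an
explicit process (only its two limits are compared). Passing tests
therefore certify the model's internal consistency and its agreement with
the published coarse-grained anchors — not fidelity to any particular
experimental GC.

# Problem sizes and limitations

The test suite and the acceptance script run, deterministically: two full
9×12 sweeps (≈15 s together), oracle comparisons at refined steps
(≈10 s), and one 200-replicate stochastic consistency check
(≈15 s) — sizes chosen because every headline quantity is already
converged at them. Known limitations, beyond those above:

* wave-timing observables (pooled-spleen optimum, recovery times) are
  sensitive to the sub-unity rule and to the spectrum's beneficial tail;
  treat their absolute values as order-of-magnitude;
* no exact event-by-event (Gillespie) mode; tau-leaping only;
* no adaptive time stepping; `dt` is fixed per run;
* extinct runs report improvement 0 and have no defined `F` — conventions,
  not measurements.
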