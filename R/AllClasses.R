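#' @import methods
NULL

#' Model parameters for germinal-center affinity maturation
#'
#' Container for all rate, selection, and thermodynamic constants of the
#' coarse-grained B-cell population model. Affinities are expressed as binding
#' free-energy offsets from the neutral level \eqn{X^*} (kcal/mol); a positive
#' offset means binding weaker than neutral, and the association-constant
#' ratio is \eqn{K_a/K_a^* = e^{-\Delta X / k_BT}}.
#'
#' @slot r per-capita exponential birth rate (1/day); defaults to
#'   `divisionsPerDay * log(2)`.
#' @slot divisionsPerDay integer number of divisions per day.
#' @slot kT thermal energy in kcal/mol.
#' @slot b selection strength: slope of the apoptosis rate with respect to
#'   binding free energy (1/day per kcal/mol).
#' @slot h affinity bin width (kcal/mol).
#' @slot pMutatedDaughter fraction of daughter cells carrying at least one
#'   mutation, in [0, 1).
#' @slot fSilent,fLethal,fAffinity mutation-class fractions; must sum to 1.
#' @slot XStarOffsetIn germline binding offset \eqn{\Delta X_{in} = X_{in} - X^*}
#'   (kcal/mol); positive = weaker than neutral.
#' @slot N0 initial B-cell count.
#' @slot tMax hard simulation horizon (days).
#'
#' @seealso [modelParams()] for the user-facing constructor, [deriveRates()].
#' @export
setClass("ModelParams",
  representation(
    r = "numeric",
    divisionsPerDay = "integer",
    kT = "numeric",
    b = "numeric",
    h = "numeric",
    pMutatedDaughter = "numeric",
    fSilent = "numeric",
    fLethal = "numeric",
    fAffinity = "numeric",
    XStarOffsetIn = "numeric",
    N0 = "numeric",
    tMax = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (object@b <= 0) msg <- c(msg, "selection strength 'b' must be > 0")
  if (object@h <= 0) msg <- c(msg, "bin width 'h' must be > 0")
  if (object@kT <= 0) msg <- c(msg, "'kT' must be > 0")
  if (object@N0 < 1) msg <- c(msg, "'N0' must be >= 1")
  if (object@r <= 0) msg <- c(msg, "'r' must be > 0")
  if (object@pMutatedDaughter < 0 || object@pMutatedDaughter >= 1)
    msg <- c(msg, "'pMutatedDaughter' must lie in [0, 1); p = 1 is a degenerate mutation load")
  s <- object@fSilent + object@fLethal + object@fAffinity
  if (abs(s - 1) > 1e-12)
    msg <- c(msg, sprintf("mutation-class fractions must sum to 1 (got %.15g)", s))
  if (min(object@fSilent, object@fLethal, object@fAffinity) < 0)
    msg <- c(msg, "mutation-class fractions must be non-negative")
  if (object@tMax <= 0) msg <- c(msg, "'tMax' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Rates derived from model parameters
#'
#' Per-division mutation load and the derived daily mutation rates, plus the
#' two derived scales of the model: the saturation offset `D` (distance below
#' the neutral affinity at which the death rate reaches zero) and the
#' recycling-round time scale `tau`.
#'
#' @slot mu mean mutations per daughter cell per division (Poisson mean).
#' @slot mTotal total mutation rate (1/day).
#' @slot mLethal lethal mutation rate (1/day); acts as an effective death rate.
#' @slot mAff affinity-affecting mutation rate (1/day).
#' @slot D saturation offset `(r - mLethal)/b` (kcal/mol).
#' @slot tau recycling-round time scale `1/(b*kT)` (days).
#'
#' @seealso [deriveRates()]
#' @export
setClass("DerivedRates",
  representation(
    mu = "numeric",
    mTotal = "numeric",
    mLethal = "numeric",
    mAff = "numeric",
    D = "numeric",
    tau = "numeric"
  )
)

setValidity("DerivedRates", function(object) {
  if (min(object@mu, object@mTotal, object@mLethal, object@mAff) < 0)
    return("all mutation rates must be >= 0")
  TRUE
})

#' Discrete mutation-effect spectrum
#'
#' The distribution \eqn{W(\delta)} of binding free-energy changes caused by a
#' single affinity-affecting point mutation, discretized on bin centers that
#' are integer multiples of the bin width `h`. Negative offsets improve
#' affinity. Bins with zero weight may be omitted, so gaps between consecutive
#' offsets are allowed (e.g. there is usually no mass at \eqn{\delta = 0},
#' which would be a silent mutation).
#'
#' @slot binWidth bin width `h` (kcal/mol).
#' @slot offsets ordered bin centers \eqn{\delta_i} (kcal/mol), strictly
#'   increasing, each an integer multiple of `binWidth`.
#' @slot weights probability per bin; non-negative, summing to 1.
#'
#' @seealso [defaultSpectrum()], [spectrumFromDdg()], [spectrumSummary()]
#' @export
setClass("MutationSpectrum",
  representation(
    binWidth = "numeric",
    offsets = "numeric",
    weights = "numeric"
  )
)

setValidity("MutationSpectrum", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "'binWidth' must be > 0")
  if (length(object@offsets) != length(object@weights))
    msg <- c(msg, "'offsets' and 'weights' must have equal length")
  if (length(object@offsets) < 1) msg <- c(msg, "spectrum must have at least one bin")
  if (any(diff(object@offsets) <= 0)) msg <- c(msg, "'offsets' must be strictly increasing")
  k <- object@offsets / object@binWidth
  if (any(abs(k - round(k)) > 1e-8))
    msg <- c(msg, "'offsets' must be integer multiples of 'binWidth'")
  if (any(object@weights < 0)) msg <- c(msg, "'weights' must be non-negative")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, sprintf("'weights' must sum to 1 (got %.12g)", sum(object@weights)))
  if (length(msg)) msg else TRUE
})

#' Analytic solution of the linear-growth mutation-selection equation
#'
#' Bundles parameters, derived rates, a mutation spectrum and an initial
#' condition for closed-form evaluation of the mean-field population. The
#' linear growth regime (no saturation cap) is assumed valid; evaluation
#' warns when the dominant subpopulation crosses below the cap point.
#'
#' @slot params a [ModelParams-class] object.
#' @slot rates a [DerivedRates-class] object.
#' @slot spectrum a [MutationSpectrum-class] object.
#' @slot icType `"delta"` (all mass at one affinity) or `"gaussian"`.
#' @slot Xin initial affinity offset from neutral (kcal/mol); the delta
#'   location, or the Gaussian mean.
#' @slot sigma Gaussian initial-condition width (kcal/mol); `NA` for delta.
#' @slot N0 initial cell count.
#'
#' @seealso [analyticSolution()], [totalPopulation()]
#' @export
setClass("AnalyticSolution",
  representation(
    params = "ModelParams",
    rates = "DerivedRates",
    spectrum = "MutationSpectrum",
    icType = "character",
    Xin = "numeric",
    sigma = "numeric",
    N0 = "numeric"
  )
)

setValidity("AnalyticSolution", function(object) {
  msg <- character()
  if (!object@icType %in% c("delta", "gaussian"))
    msg <- c(msg, "'icType' must be \"delta\" or \"gaussian\"")
  if (object@icType == "gaussian" && (is.na(object@sigma) || object@sigma <= 0))
    msg <- c(msg, "Gaussian initial condition requires sigma > 0")
  if (object@N0 <= 0) msg <- c(msg, "'N0' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binned population state
#'
#' The population distribution N(X) at one time point, on a fixed grid of
#' affinity offsets (bin centers, spacing `h`). Counts are non-negative reals;
#' a bin holding less than one cell is interpreted as an accumulative
#' probability for that subpopulation to emerge and is excluded from growth
#' and mutation emission by the finite-population integrator.
#'
#' @slot grid bin centers, offsets from the neutral affinity (kcal/mol).
#' @slot counts expected cell count per bin.
#' @slot time current time (days).
#' @slot edgeLoss length-2 numeric: cumulative mass mutated below the lowest /
#'   above the highest grid bin.
#'
#' @seealso [populationState()], [stepPopulation()]
#' @export
setClass("PopulationState",
  representation(
    grid = "numeric",
    counts = "numeric",
    time = "numeric",
    edgeLoss = "numeric"
  )
)

setValidity("PopulationState", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@counts))
    msg <- c(msg, "'grid' and 'counts' must have equal length")
  if (length(object@grid) > 1 && any(diff(object@grid) <= 0))
    msg <- c(msg, "'grid' must be strictly increasing")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "'counts' must be finite and non-negative")
  if (length(object@edgeLoss) != 2) msg <- c(msg, "'edgeLoss' must have length 2")
  if (length(msg)) msg else TRUE
})

#' Simulated germinal-center trajectory
#'
#' Time series of population summaries recorded by [simulateGC()]: total
#' population size, total affinity \eqn{A(t) = \sum_X N(X) K_a(X)/K_a^*},
#' strong-affinity fraction \eqn{F(t)} (mass at or below the neutral
#' affinity), bottleneck markers and termination status.
#'
#' @slot time sample times (days).
#' @slot Ntot total population at each sample time.
#' @slot A total affinity (sum of Ka/Ka* over cells) at each sample time.
#' @slot F strong-affinity fraction at each sample time.
#' @slot status one of `"recovered"`, `"extinct"`, `"timed_out"`.
#' @slot tEnd termination time (days).
#' @slot bottleneckTime,bottleneckDepth time and size of the population
#'   minimum.
#' @slot A0,N0 initial total affinity and population size.
#' @slot edgeLoss cumulative mass lost below/above the grid.
#' @slot finalState the [PopulationState-class] at termination.
#'
#' @seealso [simulateGC()], [improvement()], [strongFraction()]
#' @export
setClass("Trajectory",
  representation(
    time = "numeric",
    Ntot = "numeric",
    A = "numeric",
    F = "numeric",
    status = "character",
    tEnd = "numeric",
    bottleneckTime = "numeric",
    bottleneckDepth = "numeric",
    A0 = "numeric",
    N0 = "numeric",
    edgeLoss = "numeric",
    finalState = "PopulationState"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (!object@status %in% c("recovered", "extinct", "timed_out"))
    msg <- c(msg, "unknown trajectory status")
  n <- length(object@time)
  if (length(object@Ntot) != n || length(object@A) != n || length(object@F) != n)
    msg <- c(msg, "time, Ntot, A and F must have equal length")
  if (object@bottleneckDepth > object@N0 + 1e-9)
    msg <- c(msg, "bottleneck depth cannot exceed the initial population")
  if (length(msg)) msg else TRUE
})

#' Stochastic branching-process realization
#'
#' One realization of the tau-leaping branching process, with integer per-bin
#' counts. Given the same seed and parameters a run is reproducible
#' bit-for-bit.
#'
#' @slot seed integer seed used.
#' @slot time sample times (days).
#' @slot Ntot total (integer) population at each sample time.
#' @slot outcome `"survived"`, `"extinct"` or `"timed_out"`.
#' @slot tEnd termination time (days).
#' @slot finalCounts integer counts per bin at termination.
#' @slot grid bin centers (offsets, kcal/mol).
#'
#' @seealso [simulateRealization()], [survivalProbability()]
#' @export
setClass("StochasticRun",
  representation(
    seed = "integer",
    time = "numeric",
    Ntot = "numeric",
    outcome = "character",
    tEnd = "numeric",
    finalCounts = "numeric",
    grid = "numeric"
  )
)

setValidity("StochasticRun", function(object) {
  msg <- character()
  if (!object@outcome %in% c("survived", "extinct", "timed_out"))
    msg <- c(msg, "unknown outcome")
  if (any(object@finalCounts < 0) || any(object@finalCounts != round(object@finalCounts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Parameter-sweep result
#'
#' Grids of affinity improvement, survival and termination metadata over
#' mutation load (fraction of mutated daughter cells) and initial binding
#' level, at fixed selection strength.
#'
#' @slot pGrid mutated-daughter-fraction axis.
#' @slot kaGrid initial binding level axis (Ka_in/Ka*).
#' @slot b selection strength used.
#' @slot mode termination mode used per cell.
#' @slot improvement matrix (p x ka) of fold-improvements of total affinity;
#'   0 for extinct cells.
#' @slot survival matrix of survival probabilities in [0, 1].
#' @slot status character matrix of per-cell termination status.
#' @slot tEnd matrix of per-cell termination times (days).
#'
#' @seealso [sweepGrid()], [findOptimum()], [migrationComparison()]
#' @export
setClass("SweepResult",
  representation(
    pGrid = "numeric",
    kaGrid = "numeric",
    b = "numeric",
    mode = "character",
    improvement = "matrix",
    survival = "matrix",
    status = "matrix",
    tEnd = "matrix"
  )
)

setValidity("SweepResult", function(object) {
  msg <- character()
  dm <- c(length(object@pGrid), length(object@kaGrid))
  for (nm in c("improvement", "survival", "status", "tEnd"))
    if (!identical(dim(slot(object, nm)), dm))
      msg <- c(msg, sprintf("'%s' must be a %d x %d matrix", nm, dm[1], dm[2]))
  if (any(object@improvement < 0)) msg <- c(msg, "'improvement' must be >= 0")
  if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
    msg <- c(msg, "'survival' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Distribution of the strong-affinity fraction
#'
#' The probability P(F) of observing a given strong-affinity fraction F when
#' an ensemble of identically parameterized germinal centers with random
#' start times is inspected at one moment; estimated as time-in-bin along a
#' single trajectory.
#'
#' @slot breaks F-bin edges in [0, 1] (length nBins + 1).
#' @slot mass probability mass per bin; sums to 1.
#' @slot tEnd trajectory length the distribution was derived from (days).
#'
#' @seealso [fractionDistribution()]
#' @export
setClass("FractionDistribution",
  representation(
    breaks = "numeric",
    mass = "numeric",
    tEnd = "numeric"
  )
)

setValidity("FractionDistribution", function(object) {
  msg <- character()
  if (length(object@breaks) != length(object@mass) + 1)
    msg <- c(msg, "'breaks' must have length(mass) + 1")
  if (any(object@mass < 0)) msg <- c(msg, "'mass' must be non-negative")
  if (length(object@mass) && abs(sum(object@mass) - 1) > 1e-9)
    msg <- c(msg, "'mass' must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Run configuration
#'
#' A validated, defaults-filled run configuration as parsed from a YAML or
#' JSON file, together with a provenance record (tool version and config
#' hash) attached to all tabular outputs.
#'
#' @slot params a [ModelParams-class] object.
#' @slot spectrumSource `"default"` or a path to a ddG table (TSV).
#' @slot termination termination mode for [simulateGC()].
#' @slot pGrid,kaGrid sweep axes.
#' @slot nBins number of F-bins for the all-or-none distribution.
#' @slot replicates stochastic replicates per setting.
#' @slot seed top-level seed all randomness derives from.
#' @slot hash hash of the serialized configuration.
#'
#' @seealso [parseConfig()]
#' @export
setClass("RunConfig",
  representation(
    params = "ModelParams",
    spectrumSource = "character",
    termination = "character",
    pGrid = "numeric",
    kaGrid = "numeric",
    nBins = "integer",
    replicates = "integer",
    seed = "integer",
    hash = "character"
  )
)
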